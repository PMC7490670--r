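# Fixture builders and independent oracles used across the suite.

# small CtMatrix from a raw matrix, with balanced dummy groups
ctFromMatrix <- function(m, nGroups = 2L) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  groups <- rep(paste0("grp", seq_len(nGroups)), length.out = ncol(m))
  CtMatrix(m, data.frame(sample = colnames(m), group = sort(groups)))
}

# random Ct matrix: gene baselines + shared sample shift + iid noise
randomCtMatrix <- function(L = 5L, n = 12L, sd = 0.5, nGroups = 2L) {
  base <- runif(L, 16, 28)
  shift <- rnorm(n, 0, 0.5)
  m <- outer(base, rep(1, n)) + outer(rep(1, L), shift) +
    matrix(rnorm(L * n, 0, sd), L, n)
  ctFromMatrix(m, nGroups = nGroups)
}

# brute-force GeNorm M: direct all-pairs SD of log-ratios on the Ct
# scale, written independently of mValues()
oracleM <- function(ctMat, efficiency = 2) {
  L <- nrow(ctMat)
  sapply(seq_len(L), function(j) {
    mean(sapply(setdiff(seq_len(L), j), function(k) {
      sd((ctMat[k, ] - ctMat[j, ]) * log2(efficiency))
    }))
  })
}

# textbook Pearson correlation (no cor())
oraclePearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# per-group two-way least-squares fit oracle for the NormFinder
# intra-group variance: residuals from lm(y ~ gene + sample), then
# the spec'd bias correction
oracleIntraVar <- function(y) {
  L <- nrow(y); n <- ncol(y)
  df <- data.frame(y = as.vector(y),
                   gene = factor(rep(seq_len(L), times = n)),
                   sample = factor(rep(seq_len(n), each = L)))
  fit <- lm(y ~ gene + sample, data = df)
  res <- matrix(resid(fit), L, n)
  (L / (L - 1)) * rowSums(res^2) / (n - 1)
}

# full-enumeration null distribution of the Mann-Whitney U statistic
# (of the first sample) for tie-free data
oracleUdist <- function(n1, n2) {
  N <- n1 + n2
  subsets <- combn(N, n1)
  colSums(subsets) - n1 * (n1 + 1) / 2
}

# two-sided exact p from the enumeration: double the smaller tail of
# the symmetric U distribution, capped at 1
oracleExactP <- function(uA, n1, n2, udist = oracleUdist(n1, n2)) {
  uMin <- min(uA, n1 * n2 - uA)
  min(1, 2 * mean(udist <= uMin))
}
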