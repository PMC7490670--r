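# Internal helpers shared across modules.

# geometric mean of strictly positive values
.geomMean <- function(x) exp(mean(log(x)))

# fractional (average) ranks, ascending-is-better
.frank <- function(x) rank(x, ties.method = "average")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# ranks where NA scores sort after all defined scores, tie-broken by
# input order (used for undefined BestKeeper correlations)
.rankWithNA <- function(score) {
  r <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  r[ok] <- rank(score[ok], ties.method = "average")
  if (any(!ok)) r[!ok] <- sum(ok) + seq_len(sum(!ok))
  names(r) <- names(score)
  r
}

# run an expression under a fixed, named RNG so synthetic data are
# reproducible across platforms; previous RNG state is restored
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}
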