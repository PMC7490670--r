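#' Transform Ct values to relative quantities
#'
#' Converts a complete Ct matrix to relative quantities
#' \eqn{Q = E^{(\min Ct - Ct)}}, computed per gene against the gene's
#' minimum Ct so the highest expressor of each gene equals exactly 1.
#' \eqn{E} is the amplification efficiency (fold per PCR cycle); the
#' default 2 corresponds to perfect doubling. GeNorm's M value is
#' invariant to the per-gene scaling; normalization factors and the
#' pairwise-variation curve are invariant up to a constant factor that
#' cancels in log-ratios.
#'
#' @param ct a \linkS4class{CtMatrix}, complete over the panel
#' @param panel genes to transform; defaults to the candidate
#'   reference genes
#' @param efficiency amplification efficiency in [1.6, 2.2]
#' @return a \linkS4class{RelativeQuantityMatrix}
#' @examples
#' ct <- exampleCtMatrix()
#' rq <- relativeQuantities(ct)
#' apply(rq@Q, 1, max)   # all exactly 1
#' @export
relativeQuantities <- function(ct, panel = candidateGenes(ct),
                               efficiency = 2.0) {
  stopifnot(is(ct, "CtMatrix"))
  if (efficiency < 1.6 || efficiency > 2.2)
    .stopf("efficiency %.3g outside the plausible range [1.6, 2.2]",
           efficiency)
  miss <- setdiff(panel, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  vals <- ctValues(ct)[panel, , drop = FALSE]
  if (anyNA(vals))
    .stopf("missing Ct values in panel; apply completeCases() first")
  Q <- efficiency^(apply(vals, 1L, min) - vals)
  new("RelativeQuantityMatrix", Q = Q, efficiency = efficiency)
}

# log2 expression from relative quantities; with E = 2 this is
# (minCt - Ct), i.e. Ct differences up to per-gene constants
.log2Q <- function(rq) log2(rq@Q)

#' GeNorm per-gene M values on a panel
#'
#' For every gene j in the panel, \eqn{V_{jk}} is the standard
#' deviation over samples of \eqn{\log_2(Q_j/Q_k)} (with efficiency 2
#' this equals the SD of the Ct difference \eqn{Ct_k - Ct_j}), and the
#' stability value \eqn{M_j} is the mean of \eqn{V_{jk}} over all
#' partner genes \eqn{k \neq j}. Lower M means more stable expression.
#' Standard deviations use the n-1 denominator.
#'
#' @param rq a \linkS4class{RelativeQuantityMatrix}
#' @param panel genes to evaluate (default: all genes in \code{rq})
#' @return named numeric vector of M values
#' @export
mValues <- function(rq, panel = rownames(rq@Q)) {
  stopifnot(is(rq, "RelativeQuantityMatrix"))
  miss <- setdiff(panel, rownames(rq@Q))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  if (length(panel) < 2L) .stopf("panel needs at least 2 genes")
  if (ncol(rq@Q) < 3L) .stopf("at least 3 samples required")
  l <- .log2Q(rq)[panel, , drop = FALSE]
  L <- nrow(l)
  V <- matrix(0, L, L, dimnames = list(panel, panel))
  for (j in seq_len(L - 1L)) {
    for (k in (j + 1L):L) {
      V[j, k] <- V[k, j] <- stats::sd(l[j, ] - l[k, ])
    }
  }
  (rowSums(V)) / (L - 1L)
}

#' GeNorm stepwise-exclusion ranking
#'
#' Iteratively computes M on the surviving panel and removes the gene
#' with the largest M (ties broken by input order) until two genes
#' remain. Each gene's reported \code{M_final} is its M value at the
#' step it was excluded; the last two genes share the final M (their
#' pairwise log-ratio SD) and tie at the top of the ranking. The M
#' values of the full starting panel are also reported, since
#' published tables may show either variant.
#'
#' @param rq a \linkS4class{RelativeQuantityMatrix} with >= 3 genes
#'   (with exactly 2, no exclusion is possible: M values are returned
#'   with a warning)
#' @param homogeneous if TRUE the suitability threshold is M < 0.5
#'   (homogeneous sample panels); otherwise the standard heterogeneous
#'   threshold M < 1.5
#' @return a \linkS4class{GeNormResult}
#' @seealso [mValues()], [pairwiseVariation()], [flagSuitability()]
#' @export
geNorm <- function(rq, homogeneous = FALSE) {
  stopifnot(is(rq, "RelativeQuantityMatrix"))
  genes <- rownames(rq@Q)
  L <- length(genes)
  threshold <- if (homogeneous) 0.5 else 1.5
  if (L < 3L) {
    .warnf("fewer than 3 genes: no stepwise exclusion possible")
    M <- mValues(rq)
    return(new("GeNormResult", M_final = M, M_full_panel = M,
               removal_order = genes,
               ranking = structure(rep(1.5, 2L), names = genes),
               suitability = M < threshold, threshold_used = threshold,
               efficiency = rq@efficiency))
  }
  Mfull <- mValues(rq)
  surviving <- genes
  removed <- character(0)
  Mfinal <- numeric(0)
  while (length(surviving) > 2L) {
    M <- mValues(rq, surviving)
    worst <- surviving[which.max(M)]   # which.max: first max = input order
    removed <- c(removed, worst)
    Mfinal[worst] <- M[worst]
    surviving <- setdiff(surviving, worst)
  }
  Mpair <- mValues(rq, surviving)
  Mfinal[surviving] <- Mpair      # the final pair shares one M
  Mfinal <- Mfinal[genes]
  # exclusion-order ranking: final pair ties at the top (average rank),
  # then 3, 4, ... in reverse removal order
  pos <- structure(numeric(L), names = genes)
  pos[surviving] <- 1.5
  pos[rev(removed)] <- 2L + seq_along(removed)
  new("GeNormResult",
      M_final = Mfinal, M_full_panel = Mfull,
      removal_order = c(removed, surviving),
      ranking = pos,
      suitability = Mfinal < threshold,
      threshold_used = threshold,
      efficiency = rq@efficiency)
}

#' Flag reference-gene suitability against the GeNorm M threshold
#'
#' Genes with M below 1.5 are conventionally regarded as usable
#' references for heterogeneous sample panels; for homogeneous panels
#' the stricter threshold 0.5 applies.
#'
#' @param M named numeric vector of M values
#' @param homogeneous if TRUE use the 0.5 threshold, else 1.5
#' @return named logical vector; attribute \code{threshold} records the
#'   threshold applied
#' @export
flagSuitability <- function(M, homogeneous = FALSE) {
  threshold <- if (homogeneous) 0.5 else 1.5
  structure(M < threshold, threshold = threshold)
}

#' GeNorm pairwise-variation curve and optimal gene count
#'
#' Builds nested normalization factors \eqn{NF_n} (per-sample geometric
#' mean of the relative quantities of the n most stable genes, in the
#' supplied ranking order) and computes
#' \eqn{V_{n/n+1} = } SD over samples of \eqn{\log_2(NF_n/NF_{n+1})}
#' for n = 2..L-1. The optimal number of reference genes is the
#' smallest n whose V passes the cutoff (default 0.15, strict
#' comparison on unrounded values; set \code{cutoffInclusive} to also
#' accept V equal to the cutoff). If no n passes, the full panel size
#' is returned with a warning.
#'
#' @param rq a \linkS4class{RelativeQuantityMatrix} with >= 3 genes
#' @param ranking gene order, most stable first — typically
#'   \code{removalOrder} reversed, as stored in a
#'   \linkS4class{GeNormResult}; a \code{GeNormResult} may be passed
#'   directly
#' @param cutoff decision threshold on V
#' @param cutoffInclusive accept V equal to the cutoff
#' @return a \linkS4class{VCurve}
#' @export
pairwiseVariation <- function(rq, ranking, cutoff = 0.15,
                              cutoffInclusive = FALSE) {
  stopifnot(is(rq, "RelativeQuantityMatrix"))
  if (is(ranking, "GeNormResult"))
    ranking <- rev(ranking@removal_order)
  genes <- rownames(rq@Q)
  if (!setequal(ranking, genes) || length(ranking) != length(genes))
    .stopf("ranking must order exactly the genes of 'rq'")
  L <- length(genes)
  if (L < 3L) .stopf("pairwise variation needs at least 3 genes")
  l <- .log2Q(rq)[ranking, , drop = FALSE]
  # log2 NF_n per sample = mean of the top-n genes' log2 quantities
  logNF <- apply(l, 2L, cumsum) / seq_len(L)
  V <- vapply(2:(L - 1L), function(n) {
    stats::sd(logNF[n, ] - logNF[n + 1L, ])
  }, numeric(1))
  names(V) <- as.character(2:(L - 1L))
  pass <- if (cutoffInclusive) V <= cutoff else V < cutoff
  if (any(pass)) {
    optimal <- as.integer(names(V)[which(pass)[1L]])
    converged <- TRUE
  } else {
    optimal <- L
    converged <- FALSE
    .warnf("no V_n/n+1 passed the cutoff %.3g; using all %d genes",
           cutoff, L)
  }
  new("VCurve", V = V, cutoff = cutoff,
      cutoff_inclusive = cutoffInclusive,
      optimal_n = optimal, converged = converged,
      ranking_used = ranking)
}

#' @describeIn GeNormResult-class genes in exclusion order (first
#'   removed = least stable)
#' @param x a \code{GeNormResult}
#' @export
removalOrder <- function(x) {
  stopifnot(is(x, "GeNormResult"))
  x@removal_order
}

#' @describeIn VCurve-class the selected optimal number of reference
#'   genes
#' @param x a \code{VCurve}
#' @export
optimalN <- function(x) {
  stopifnot(is(x, "VCurve"))
  x@optimal_n
}

setMethod("show", "GeNormResult", function(object) {
  cat("GeNormResult (stepwise exclusion, efficiency",
      object@efficiency, ")\n")
  ord <- names(sort(object@ranking))
  df <- data.frame(gene = ord,
                   M_final = round(object@M_final[ord], 3),
                   M_full_panel = round(object@M_full_panel[ord], 3),
                   rank = object@ranking[ord],
                   suitable = object@suitability[ord],
                   row.names = NULL)
  print(df)
  cat("suitability threshold: M <", object@threshold_used, "\n")
  invisible(NULL)
})

setMethod("show", "VCurve", function(object) {
  cat("GeNorm pairwise variation (cutoff",
      ifelse(object@cutoff_inclusive, "<=", "<"), object@cutoff, ")\n")
  print(round(object@V, 4))
  cat("optimal number of reference genes:", object@optimal_n,
      if (!object@converged) "(no V passed the cutoff)" else "", "\n")
  invisible(NULL)
})
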