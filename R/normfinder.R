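# NormFinder-style model-based stability.
#
# Ct values are treated directly as log2-scale expression: every
# statistic below depends only on variances and centered deviations,
# which are invariant to the sign flip between Ct and log-expression.
#
# Grouped decomposition, per group g with n_g samples and L genes:
#   residual r_igj = y_igj - geneMean_ig - sampleMean_gj + groupMean_g
#   intra-group variance  s2_ig = [L/(L-1)] * sum_j r2_igj / (n_g - 1)
#   inter-group deviation d_ig  = geneMean_ig - groupMean_g
#   sampling variance     v_ig  = ((L-1)/L)^2 s2_ig/n_g
#                               + (1/L^2) sum_{i'!=i} s2_i'g / n_g
#   common inter-group variance gamma2 =
#       max(0, sum d2 / (G (L-1)) - mean v)      [method of moments;
#       G(L-1) effective df from the per-group sum-to-zero constraint]
#   shrinkage d~_ig = d_ig * gamma2 / (gamma2 + v_ig)
#   stability sv_i = mean_g [ |d~_ig| + sqrt(gamma2 v_ig/(gamma2+v_ig)) ]
# The L/(L-1) factor compensates the sum-to-zero constraint across
# genes; negative variance estimates are floored at 0.

.twoWayResiduals <- function(y) {
  geneMean <- rowMeans(y)
  sampleMean <- colMeans(y)
  grand <- mean(y)
  list(res = y - outer(geneMean, rep(1, ncol(y))) -
         outer(rep(1, nrow(y)), sampleMean) + grand,
       geneMean = geneMean, grand = grand)
}

#' NormFinder stability values
#'
#' Decomposes Ct variation into inter-group deviations and intra-group
#' variances per candidate gene, and combines them into a stability
#' value \code{sv} (lower = more stable). With a single group (or
#' \code{grouped = FALSE}) the stability value reduces to the gene's
#' residual standard deviation after removing gene and sample effects.
#'
#' If no inter-group signal is detected (the common inter-group
#' variance estimate is zero), all sv collapse to 0; the ranking then
#' falls back to the mean sampling standard deviation, with a warning.
#'
#' @param ct a \linkS4class{CtMatrix}, complete over the panel
#' @param panel genes to evaluate; defaults to the candidate
#'   reference genes (>= 3 required)
#' @param groupBy column of the sample metadata defining the groups
#' @param grouped use the grouped decomposition (requires >= 2 groups
#'   with >= 2 samples each); set FALSE for the single-group variant
#' @return a \linkS4class{NormFinderResult}
#' @seealso [interGroupVariation()]
#' @export
normFinder <- function(ct, panel = candidateGenes(ct),
                       groupBy = "group", grouped = TRUE) {
  stopifnot(is(ct, "CtMatrix"))
  miss <- setdiff(panel, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  if (length(panel) < 3L) .stopf("at least 3 genes required")
  y <- ctValues(ct)[panel, , drop = FALSE]
  if (anyNA(y))
    .stopf("missing Ct values in panel; apply completeCases() first")
  L <- nrow(y)
  if (!groupBy %in% colnames(colData(ct)))
    .stopf("no '%s' metadata present", groupBy)
  grp <- as.character(colData(ct)[[groupBy]])

  # center each gene by its grand mean over all samples
  y <- y - rowMeans(y)

  if (!grouped) {
    fit <- .twoWayResiduals(y)
    s2 <- pmax(0, (L / (L - 1)) * rowSums(fit$res^2) / (ncol(y) - 1L))
    sv <- sqrt(s2)
    names(sv) <- panel
    empty <- matrix(numeric(0), nrow = L, ncol = 0,
                    dimnames = list(panel, NULL))
    return(new("NormFinderResult", sv = sv,
               d_hat = empty, d_tilde = empty,
               sigma2 = matrix(s2, ncol = 1,
                               dimnames = list(panel, "all")),
               v = empty, gamma2 = 0, grouped = FALSE,
               ranking = .frank(sv)))
  }

  groups <- unique(grp)
  G <- length(groups)
  if (G < 2L)
    .stopf("grouped analysis needs >= 2 groups; use grouped = FALSE")
  ng <- table(grp)[groups]
  if (any(ng < 2L))
    .stopf("every group needs >= 2 samples (smallest has %d)", min(ng))

  d <- s2 <- matrix(NA_real_, L, G, dimnames = list(panel, groups))
  for (g in groups) {
    yg <- y[, grp == g, drop = FALSE]
    fit <- .twoWayResiduals(yg)
    s2[, g] <- pmax(0, (L / (L - 1)) *
                      rowSums(fit$res^2) / (ncol(yg) - 1L))
    d[, g] <- fit$geneMean - fit$grand
  }
  v <- matrix(NA_real_, L, G, dimnames = list(panel, groups))
  for (g in groups) {
    tot <- sum(s2[, g])
    v[, g] <- ((L - 1) / L)^2 * s2[, g] / ng[[g]] +
      (tot - s2[, g]) / (L^2 * ng[[g]])
  }
  gamma2 <- max(0, sum(d^2) / (G * (L - 1)) - mean(v))
  if (gamma2 == 0) {
    dt <- d * 0
    sv <- structure(numeric(L), names = panel)
    ranking <- .frank(rowMeans(sqrt(v)))
    .warnf(paste("no inter-group variance detected; all sv are 0 and",
                 "the ranking falls back to the mean sampling SD"))
  } else {
    dt <- d * gamma2 / (gamma2 + v)
    sv <- rowMeans(abs(dt) + sqrt(gamma2 * v / (gamma2 + v)))
    names(sv) <- panel
    ranking <- .frank(sv)
  }
  new("NormFinderResult", sv = sv, d_hat = d, d_tilde = dt,
      sigma2 = s2, v = v, gamma2 = gamma2, grouped = TRUE,
      ranking = ranking)
}

#' Inter- and intra-group variation table
#'
#' Exports the per-(gene, group) estimated inter-group deviation
#' (point) and intra-group standard deviation (spread) from the
#' NormFinder decomposition — the numbers behind the usual
#' inter-/intra-group variation diagnostic plot used to spot genes
#' dysregulated in specific experimental groups.
#'
#' @inheritParams normFinder
#' @return data.frame with columns gene, group, d_hat, intra_sd
#' @export
interGroupVariation <- function(ct, panel = candidateGenes(ct),
                                groupBy = "group") {
  nf <- normFinder(ct, panel = panel, groupBy = groupBy, grouped = TRUE)
  data.frame(
    gene = rep(rownames(nf@d_hat), times = ncol(nf@d_hat)),
    group = rep(colnames(nf@d_hat), each = nrow(nf@d_hat)),
    d_hat = as.vector(nf@d_hat),
    intra_sd = as.vector(sqrt(nf@sigma2)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn NormFinderResult-class per-gene stability values
#' @param x a \code{NormFinderResult}
#' @export
stabilityValues <- function(x) {
  stopifnot(is(x, "NormFinderResult"))
  x@sv
}

setMethod("show", "NormFinderResult", function(object) {
  cat("NormFinderResult (",
      if (object@grouped) "grouped" else "ungrouped", ")\n", sep = "")
  ord <- names(sort(object@ranking))
  print(data.frame(gene = ord, sv = round(object@sv[ord], 4),
                   rank = object@ranking[ord], row.names = NULL))
  if (object@grouped)
    cat("inter-group variance estimate:",
        signif(object@gamma2, 4), "\n")
  invisible(NULL)
})
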