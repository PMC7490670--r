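#' Delta-delta-Ct normalization of a target gene
#'
#' Computes, per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{ref}},
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}}
#' (centering on the arithmetic mean of the control group's
#' \eqn{\Delta Ct}) and the relative quantity
#' \eqn{rq = E^{-\Delta\Delta Ct}}. With several reference genes the
#' default aggregate is the arithmetic mean of the reference Ct values
#' — equivalently the geometric mean of the reference quantities at a
#' fixed efficiency — which makes the control group's geometric mean
#' rq exactly 1. The alternative \code{aggregate = "perReference"}
#' normalizes to each reference separately and averages the resulting
#' relative quantities arithmetically.
#'
#' Each non-control group is compared with the control group by a
#' two-sided Mann-Whitney U test on the relative quantities (see
#' [mannWhitneyU()]); no multiple-testing correction is applied by
#' default, matching the common per-group-vs-control convention at
#' p < 0.05, but Holm or Bonferroni adjustment can be switched on.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param target target gene
#' @param references one or more reference genes (must not include the
#'   target)
#' @param controlGroup label of the control group
#' @param efficiency amplification efficiency (fold per cycle)
#' @param aggregate \code{"meanCt"} (default) or \code{"perReference"}
#' @param pAdjust p-value adjustment across group comparisons:
#'   \code{"none"} (default), \code{"holm"} or \code{"bonferroni"}
#' @return a \linkS4class{NormalizedExpression}
#' @examples
#' d <- designPreset("neutral")
#' d <- addTarget(d, "Atf4", foldChanges = c(Fx = 2), noiseSd = 0.2)
#' ct <- generateCt(d, seed = 7)
#' normalizeDdct(ct, "Atf4", c("Hprt", "Gapdh"), "control")
#' @export
normalizeDdct <- function(ct, target, references, controlGroup,
                          efficiency = 2.0,
                          aggregate = c("meanCt", "perReference"),
                          pAdjust = c("none", "holm", "bonferroni")) {
  stopifnot(is(ct, "CtMatrix"))
  aggregate <- match.arg(aggregate)
  pAdjust <- match.arg(pAdjust)
  genes <- c(target, references)
  miss <- setdiff(genes, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  if (target %in% references)
    .stopf("target '%s' cannot be one of its references", target)
  ct <- completeCases(ct, genes = genes)
  grp <- sampleGroups(ct)
  if (!controlGroup %in% grp)
    .stopf("control group '%s' not present", controlGroup)
  vals <- ctValues(ct)
  tCt <- vals[target, ]
  refCt <- vals[references, , drop = FALSE]
  ctrl <- grp == controlGroup

  if (aggregate == "meanCt") {
    dct <- tCt - colMeans(refCt)
    ddct <- dct - mean(dct[ctrl])
    rq <- efficiency^(-ddct)
  } else {
    # normalize to each reference separately, then average the rq
    perRef <- vapply(references, function(r) {
      d <- tCt - refCt[r, ]
      efficiency^(-(d - mean(d[ctrl])))
    }, numeric(length(tCt)))
    rq <- rowMeans(perRef)
    dct <- tCt - colMeans(refCt)
    ddct <- -log(rq, base = efficiency)
  }

  samples <- data.frame(sample = colnames(ct), group = unname(grp),
                        delta_ct = unname(dct),
                        delta_delta_ct = unname(ddct),
                        rq = unname(rq), stringsAsFactors = FALSE)
  groups <- unique(grp)
  summary <- do.call(rbind, lapply(groups, function(g) {
    x <- rq[grp == g]
    data.frame(group = g, n = length(x), mean_rq = mean(x),
               sd_rq = stats::sd(x), stringsAsFactors = FALSE)
  }))
  others <- setdiff(groups, controlGroup)
  tests <- do.call(rbind, lapply(others, function(g) {
    mw <- mannWhitneyU(rq[grp == g], rq[ctrl])
    data.frame(group = g, U = mw$U, p = mw$p.value, exact = mw$exact,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tests))
    tests <- data.frame(group = character(0), U = numeric(0),
                        p = numeric(0), exact = logical(0))
  if (pAdjust != "none" && nrow(tests) > 0)
    tests$p <- stats::p.adjust(tests$p, method = pAdjust)
  new("NormalizedExpression", samples = samples, group_summary = summary,
      tests = tests, target = target, references = references,
      control_group = controlGroup, efficiency = efficiency,
      aggregate = aggregate)
}

#' Two-sided Mann-Whitney U test
#'
#' Reports \eqn{U = \min(U_a, U_b)} and a two-sided p-value: exact (by
#' enumeration of the rank-sum null distribution) when both samples
#' have at most 8 observations and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b numeric samples, each with >= 3 observations
#' @return list with elements \code{U}, \code{p.value} and
#'   \code{exact}
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    .stopf("each sample needs >= 3 observations")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  Ua <- unname(wt$statistic)
  list(U = min(Ua, length(a) * length(b) - Ua),
       p.value = wt$p.value, exact = exact)
}

#' Shapiro-Wilk normality gate
#'
#' Annotates a sample with the Shapiro-Wilk W statistic and p-value.
#' The analysis pipeline always proceeds nonparametrically; this gate
#' only documents whether a normality assumption would have held.
#' A constant (zero-variance) sample has an undefined W and is
#' returned flagged rather than as an error.
#'
#' @param values numeric sample with 3 <= n <= 5000
#' @param alpha significance level for the \code{is_normal} flag
#' @return list with elements \code{W}, \code{p.value},
#'   \code{is_normal} and \code{degenerate}
#' @export
shapiroWilkGate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    .stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p.value = NA_real_, is_normal = NA,
                degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p.value = sw$p.value,
       is_normal = sw$p.value >= alpha, degenerate = FALSE)
}

#' Contrast normalizations against several reference sets
#'
#' Normalizes the same target gene with each supplied reference set on
#' the identical samples, enabling the classic demonstration that a
#' dysregulated housekeeping gene manufactures spurious significance
#' (false positives) or masks true regulation (false negatives), while
#' validated stable references do not.
#'
#' @inheritParams normalizeDdct
#' @param refSets named list of reference-gene sets
#' @return named list of \linkS4class{NormalizedExpression}, one per
#'   reference set
#' @export
compareHousekeeping <- function(ct, target, refSets, controlGroup,
                                efficiency = 2.0) {
  stopifnot(is.list(refSets), length(refSets) >= 1L)
  if (is.null(names(refSets)))
    names(refSets) <- vapply(refSets, paste, "", collapse = "+")
  lapply(refSets, function(refs) {
    normalizeDdct(ct, target = target, references = refs,
                  controlGroup = controlGroup, efficiency = efficiency)
  })
}

setMethod("show", "NormalizedExpression", function(object) {
  cat("NormalizedExpression:", object@target, "vs",
      toString(object@references),
      sprintf("(control = %s, E = %g, %s)\n", object@control_group,
              object@efficiency, object@aggregate))
  s <- object@group_summary
  s$mean_rq <- round(s$mean_rq, 3); s$sd_rq <- round(s$sd_rq, 3)
  print(s, row.names = FALSE)
  if (nrow(object@tests)) {
    cat("Mann-Whitney U vs control:\n")
    t <- object@tests
    t$p <- signif(t$p, 3)
    print(t, row.names = FALSE)
  }
  invisible(NULL)
})
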