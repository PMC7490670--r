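#' BestKeeper index
#'
#' The BestKeeper index of a sample is the geometric mean of the
#' candidate reference genes' Ct values for that sample. Targets are
#' excluded by default: the index is defined over the candidate panel.
#'
#' @param ct a \linkS4class{CtMatrix}, complete over the panel
#' @param panel genes entering the index; defaults to the candidate
#'   reference genes
#' @return named numeric vector, one index value per sample (cycles)
#' @export
bestKeeperIndex <- function(ct, panel = candidateGenes(ct)) {
  stopifnot(is(ct, "CtMatrix"))
  miss <- setdiff(panel, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  vals <- ctValues(ct)[panel, , drop = FALSE]
  if (anyNA(vals))
    .stopf("missing Ct values in panel; apply completeCases() first")
  if (any(vals <= 0)) .stopf("Ct values must be strictly positive")
  apply(vals, 2L, .geomMean)
}

#' BestKeeper descriptive statistics
#'
#' Per candidate gene: geometric and arithmetic mean Ct, range,
#' dispersion (SD about the arithmetic mean with n-1 denominator, and
#' CV as a percentage of the arithmetic mean) and the Pearson
#' correlation r of the gene's Ct with the BestKeeper index, with a
#' two-sided p-value from the t distribution on n-2 degrees of
#' freedom. Genes with the highest r and lowest SD are the most
#' stable. A zero-variance gene has an undefined correlation: it is
#' flagged (\code{r = NA}) and ranked after all defined-r genes.
#'
#' The original spreadsheet's "SD [+/- Cp]" has also been
#' reimplemented elsewhere as the mean absolute deviation about the
#' geometric mean; \code{sdVariant = "mad-geomean"} selects that
#' variant for the sd/cv columns.
#'
#' @inheritParams bestKeeperIndex
#' @param sdVariant \code{"sd"} (default) or \code{"mad-geomean"}
#' @return a \linkS4class{BestKeeperResult}
#' @export
bestKeeper <- function(ct, panel = candidateGenes(ct),
                       sdVariant = c("sd", "mad-geomean")) {
  sdVariant <- match.arg(sdVariant)
  index <- bestKeeperIndex(ct, panel)
  vals <- ctValues(ct)[panel, , drop = FALSE]
  n <- ncol(vals)
  if (n < 4L) .warnf("fewer than 4 samples: p-values are unreliable")
  dispersion <- function(x) {
    if (sdVariant == "sd") stats::sd(x) else mean(abs(x - .geomMean(x)))
  }
  stats <- do.call(rbind, lapply(panel, function(g) {
    x <- vals[g, ]
    s <- dispersion(x)
    if (stats::sd(x) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      tst <- stats::cor.test(x, index, method = "pearson")
      r <- unname(tst$estimate); p <- tst$p.value
    }
    data.frame(gene = g, geo_mean = .geomMean(x), arith_mean = mean(x),
               min = min(x), max = max(x), sd = s,
               cv = 100 * s / mean(x), r = r, p = p,
               stringsAsFactors = FALSE)
  }))
  stats$rank_r <- .rankWithNA(structure(-stats$r, names = panel))
  stats$rank_sd <- .frank(stats$sd)
  rownames(stats) <- NULL
  new("BestKeeperResult", index = index, stats = stats,
      sd_variant = sdVariant)
}

setMethod("show", "BestKeeperResult", function(object) {
  cat("BestKeeperResult (dispersion:", object@sd_variant, ")\n")
  df <- object@stats
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 3))
  print(df)
  invisible(NULL)
})
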