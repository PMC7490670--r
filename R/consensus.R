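#' Comparative delta-Ct stability
#'
#' For each gene i in the panel, the stability score is the mean over
#' partner genes k of the standard deviation over samples of the Ct
#' difference \eqn{Ct_i - Ct_k}. Algebraically this is the GeNorm
#' full-panel M value at amplification efficiency 2.
#'
#' @param ct a \linkS4class{CtMatrix}, complete over the panel
#' @param panel genes to evaluate (>= 2); defaults to the candidate
#'   reference genes
#' @return a \linkS4class{DeltaCtStability}
#' @export
deltaCtStability <- function(ct, panel = candidateGenes(ct)) {
  stopifnot(is(ct, "CtMatrix"))
  miss <- setdiff(panel, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  if (length(panel) < 2L) .stopf("panel needs at least 2 genes")
  y <- ctValues(ct)[panel, , drop = FALSE]
  if (anyNA(y))
    .stopf("missing Ct values in panel; apply completeCases() first")
  L <- nrow(y)
  S <- matrix(0, L, L, dimnames = list(panel, panel))
  for (j in seq_len(L - 1L)) {
    for (k in (j + 1L):L) {
      S[j, k] <- S[k, j] <- stats::sd(y[j, ] - y[k, ])
    }
  }
  meanSd <- rowSums(S) / (L - 1L)
  new("DeltaCtStability", mean_sd = meanSd, ranking = .frank(meanSd))
}

#' Assemble the per-method rank table
#'
#' Collects the rankings of the four stability methods into one table
#' of fractional (average-on-ties) ranks per gene, ascending is
#' better. BestKeeper contributes its two printed statistics as
#' separate columns: rank by descending correlation
#' (\code{bestkeeper_r}) and rank by ascending dispersion
#' (\code{bestkeeper_sd}). The GeNorm column uses the
#' stepwise-exclusion ranking, with the final surviving pair tied.
#'
#' @param nf a \linkS4class{NormFinderResult}
#' @param gn a \linkS4class{GeNormResult}
#' @param bk a \linkS4class{BestKeeperResult}
#' @param dct a \linkS4class{DeltaCtStability}
#' @return data.frame of ranks with rownames = genes and columns
#'   normfinder, genorm, bestkeeper_r, bestkeeper_sd, delta_ct
#' @export
assembleRanks <- function(nf, gn, bk, dct) {
  stopifnot(is(nf, "NormFinderResult"), is(gn, "GeNormResult"),
            is(bk, "BestKeeperResult"), is(dct, "DeltaCtStability"))
  genes <- names(dct@mean_sd)
  same <- function(nm) setequal(nm, genes) && length(nm) == length(genes)
  if (!same(names(nf@sv)) || !same(names(gn@ranking)) ||
      !same(bk@stats$gene))
    .stopf("all method results must cover the same gene panel")
  bkRanks <- bk@stats
  rownames(bkRanks) <- bkRanks$gene
  data.frame(
    normfinder = unname(nf@ranking[genes]),
    genorm = unname(gn@ranking[genes]),
    bestkeeper_r = bkRanks[genes, "rank_r"],
    bestkeeper_sd = bkRanks[genes, "rank_sd"],
    delta_ct = unname(dct@ranking[genes]),
    row.names = genes)
}

#' Summed final rank
#'
#' Sums the selected per-method ranks into a final-rank score and
#' re-ranks it (fractional ranks, 1 = best). By default all four rank
#' columns from NormFinder, GeNorm and BestKeeper contribute,
#' BestKeeper with both its correlation and dispersion rankings.
#'
#' @param rankTable rank table from [assembleRanks()]
#' @param methods columns to sum
#' @return data.frame with columns score and rank, rownames = genes
#' @export
finalRank <- function(rankTable,
                      methods = c("normfinder", "genorm",
                                  "bestkeeper_r", "bestkeeper_sd")) {
  if (length(methods) == 0L) .stopf("at least one method required")
  miss <- setdiff(methods, colnames(rankTable))
  if (length(miss)) .stopf("unknown method column(s): %s", toString(miss))
  score <- rowSums(rankTable[, methods, drop = FALSE])
  data.frame(score = score, rank = .frank(score),
             row.names = rownames(rankTable))
}

#' RefFinder-style geometric-mean rank
#'
#' Aggregates the ranks of the comparative delta-Ct method,
#' NormFinder, GeNorm and BestKeeper into the geometric mean
#' \eqn{(r_{dct} \cdot r_{nf} \cdot r_{gn} \cdot r_{bk})^{1/4}} and
#' re-ranks it ascending. The web tool's internal conventions are
#' undocumented, so the BestKeeper column is configurable (dispersion
#' ranking by default) and results are labelled "RefFinder-style".
#'
#' @param rankTable rank table from [assembleRanks()]
#' @param bestkeeper which BestKeeper column represents the method
#' @return data.frame with columns score and rank, rownames = genes
#' @export
refFinderRank <- function(rankTable,
                          bestkeeper = c("bestkeeper_sd",
                                         "bestkeeper_r")) {
  bestkeeper <- match.arg(bestkeeper)
  cols <- c("delta_ct", "normfinder", "genorm", bestkeeper)
  miss <- setdiff(cols, colnames(rankTable))
  if (length(miss)) .stopf("unknown method column(s): %s", toString(miss))
  m <- as.matrix(rankTable[, cols])
  if (any(m <= 0)) .stopf("ranks must be strictly positive")
  score <- exp(rowMeans(log(m)))
  data.frame(score = score, rank = .frank(score),
             row.names = rownames(rankTable))
}

#' Build a consensus ranking
#'
#' Combines the four method results into the rank table, the summed
#' final rank and the RefFinder-style score.
#'
#' @inheritParams assembleRanks
#' @param finalRankMethods columns summed into the final rank
#' @param reffinderBestkeeper BestKeeper column used in the
#'   RefFinder-style geometric mean
#' @return a \linkS4class{ConsensusRanking} (with an empty
#'   \code{recommended} slot; see [recommendGenes()])
#' @export
consensusRanking <- function(nf, gn, bk, dct,
                             finalRankMethods = c("normfinder", "genorm",
                                                  "bestkeeper_r",
                                                  "bestkeeper_sd"),
                             reffinderBestkeeper = "bestkeeper_sd") {
  rt <- assembleRanks(nf, gn, bk, dct)
  fr <- finalRank(rt, methods = finalRankMethods)
  rf <- refFinderRank(rt, bestkeeper = reffinderBestkeeper)
  new("ConsensusRanking", rank_table = rt,
      final_rank_score = structure(fr$score, names = rownames(fr)),
      final_rank = structure(fr$rank, names = rownames(fr)),
      final_rank_methods = finalRankMethods,
      reffinder_score = structure(rf$score, names = rownames(rf)),
      reffinder_rank = structure(rf$rank, names = rownames(rf)),
      reffinder_bestkeeper = reffinderBestkeeper,
      recommended = character(0))
}

#' Recommend a reference-gene set
#'
#' Orders the genes by final rank (ties broken by the RefFinder-style
#' score, then by input order) and returns the top \code{optimal_n}
#' genes from the pairwise-variation curve. Recommended genes that
#' fail the GeNorm suitability threshold are reported with a warning
#' but not dropped, since published stability tables retain them.
#'
#' @param consensus a \linkS4class{ConsensusRanking}
#' @param vcurve a \linkS4class{VCurve} from the same dataset
#' @param suitability optional named logical vector of GeNorm
#'   suitability flags
#' @return ordered character vector of recommended reference genes
#' @export
recommendGenes <- function(consensus, vcurve, suitability = NULL) {
  stopifnot(is(consensus, "ConsensusRanking"), is(vcurve, "VCurve"))
  genes <- names(consensus@final_rank)
  ord <- order(consensus@final_rank[genes],
               consensus@reffinder_score[genes],
               seq_along(genes))
  rec <- genes[ord][seq_len(min(vcurve@optimal_n, length(genes)))]
  if (!is.null(suitability)) {
    bad <- rec[!suitability[rec]]
    if (length(bad))
      .warnf("recommended gene(s) failing the GeNorm threshold: %s",
             toString(bad))
  }
  rec
}

#' Run the full stability pipeline on a Ct dataset
#'
#' Orchestrates the complete evaluation of a candidate reference-gene
#' panel: complete-case restriction, relative quantities, GeNorm
#' stepwise exclusion and pairwise-variation curve, NormFinder
#' variance decomposition, BestKeeper statistics, the comparative
#' delta-Ct method, the consensus (summed final rank and
#' RefFinder-style score) and the recommended reference set of size
#' \code{optimal_n}.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param panel candidate genes; defaults to the genes flagged
#'   \code{candidate_reference}
#' @param efficiency amplification efficiency (fold per cycle)
#' @param cutoff pairwise-variation cutoff for the optimal gene count
#' @param cutoffInclusive accept V equal to the cutoff
#' @param homogeneous apply the homogeneous-panel M threshold (0.5)
#' @param grouped use grouped NormFinder (default: TRUE when the
#'   metadata contain >= 2 groups)
#' @param sdVariant BestKeeper dispersion variant
#' @param finalRankMethods rank columns summed into the final rank
#' @param reffinderBestkeeper BestKeeper column for the
#'   RefFinder-style score
#' @return a \linkS4class{StabilityEvaluation}
#' @examples
#' ct <- generateCt(designPreset("paper_d3_bone"), seed = 1)
#' ev <- evaluateStability(ct)
#' recommendedGenes(ev)
#' @export
evaluateStability <- function(ct, panel = candidateGenes(ct),
                              efficiency = 2.0, cutoff = 0.15,
                              cutoffInclusive = FALSE,
                              homogeneous = FALSE, grouped = NULL,
                              sdVariant = "sd",
                              finalRankMethods = c("normfinder", "genorm",
                                                   "bestkeeper_r",
                                                   "bestkeeper_sd"),
                              reffinderBestkeeper = "bestkeeper_sd") {
  stopifnot(is(ct, "CtMatrix"))
  if (length(panel) < 3L)
    .stopf("a stability evaluation needs >= 3 candidate genes")
  ct <- completeCases(ct, genes = panel)
  if (is.null(grouped))
    grouped <- length(unique(sampleGroups(ct))) >= 2L
  rq <- relativeQuantities(ct, panel = panel, efficiency = efficiency)
  gn <- geNorm(rq, homogeneous = homogeneous)
  vc <- pairwiseVariation(rq, gn, cutoff = cutoff,
                          cutoffInclusive = cutoffInclusive)
  nf <- normFinder(ct, panel = panel, grouped = grouped)
  bk <- bestKeeper(ct, panel = panel, sdVariant = sdVariant)
  dct <- deltaCtStability(ct, panel = panel)
  cons <- consensusRanking(nf, gn, bk, dct,
                           finalRankMethods = finalRankMethods,
                           reffinderBestkeeper = reffinderBestkeeper)
  cons@recommended <- recommendGenes(cons, vc,
                                     suitability = gn@suitability)
  new("StabilityEvaluation", genorm = gn, normfinder = nf,
      bestkeeper = bk, delta_ct = dct, vcurve = vc, consensus = cons,
      panel = panel,
      parameters = list(efficiency = efficiency, cutoff = cutoff,
                        cutoff_inclusive = cutoffInclusive,
                        homogeneous = homogeneous, grouped = grouped,
                        sd_variant = sdVariant,
                        final_rank_methods = finalRankMethods,
                        reffinder_bestkeeper = reffinderBestkeeper))
}

#' @describeIn evaluateStability The recommended reference-gene set of
#'   an evaluation.
#' @param x a \linkS4class{StabilityEvaluation}
#' @export
recommendedGenes <- function(x) {
  stopifnot(is(x, "StabilityEvaluation"))
  x@consensus@recommended
}

#' Combined per-gene summary of a stability evaluation
#'
#' One row per gene: the per-method scores and ranks, the summed
#' final-rank score and rank, and the RefFinder-style score and rank.
#'
#' @param x a \linkS4class{StabilityEvaluation}
#' @return data.frame, ordered by final rank
#' @export
stabilityTable <- function(x) {
  stopifnot(is(x, "StabilityEvaluation"))
  genes <- names(x@consensus@final_rank)
  bk <- x@bestkeeper@stats
  rownames(bk) <- bk$gene
  df <- data.frame(
    gene = genes,
    nf_sv = unname(x@normfinder@sv[genes]),
    genorm_M = unname(x@genorm@M_final[genes]),
    bk_r = bk[genes, "r"],
    bk_sd = bk[genes, "sd"],
    dct_mean_sd = unname(x@delta_ct@mean_sd[genes]),
    x@consensus@rank_table[genes, ],
    final_score = unname(x@consensus@final_rank_score[genes]),
    final_rank = unname(x@consensus@final_rank[genes]),
    reffinder_score = unname(x@consensus@reffinder_score[genes]),
    reffinder_rank = unname(x@consensus@reffinder_rank[genes]),
    row.names = NULL)
  df[order(df$final_rank), ]
}

setMethod("show", "DeltaCtStability", function(object) {
  cat("Comparative delta-Ct stability\n")
  ord <- names(sort(object@ranking))
  print(data.frame(gene = ord, mean_sd = round(object@mean_sd[ord], 4),
                   rank = object@ranking[ord], row.names = NULL))
  invisible(NULL)
})

setMethod("show", "ConsensusRanking", function(object) {
  cat("ConsensusRanking (final rank sums:",
      toString(object@final_rank_methods), ")\n")
  genes <- names(sort(object@final_rank))
  df <- data.frame(object@rank_table[genes, ],
                   final_score = object@final_rank_score[genes],
                   final_rank = object@final_rank[genes],
                   reffinder_score =
                     round(object@reffinder_score[genes], 3),
                   reffinder_rank = object@reffinder_rank[genes])
  print(df)
  if (length(object@recommended))
    cat("recommended:", toString(object@recommended), "\n")
  invisible(NULL)
})

setMethod("show", "StabilityEvaluation", function(object) {
  cat("StabilityEvaluation of", length(object@panel), "candidate genes\n")
  cat("optimal number of reference genes:", object@vcurve@optimal_n, "\n")
  cat("recommended:", toString(object@consensus@recommended), "\n")
  cat("\n")
  df <- stabilityTable(object)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(NULL)
})
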