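#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData colData<- rowData<-
NULL

#' CtMatrix: threshold-cycle values with sample metadata
#'
#' A \code{CtMatrix} holds one RT-qPCR threshold-cycle (Ct) value per
#' (gene, sample) in the \code{"ct"} assay of a
#' \linkS4class{SummarizedExperiment}, together with per-sample metadata
#' (\code{group}, optionally \code{tissue} and \code{timepoint}) in
#' \code{colData} and a per-gene \code{role} flag
#' (\code{"candidate_reference"} or \code{"target"}) in \code{rowData}.
#' Cp (crossing point) values are the same quantity and are stored
#' unchanged.
#'
#' Validity requires: all present Ct values finite and strictly between
#' 0 and 50 cycles; at least 2 genes and 3 samples; unique gene
#' identifiers; a non-empty \code{group} label for every sample.
#' Missing cells (\code{NA}) are allowed and preserved.
#'
#' @seealso [CtMatrix()] for construction, [readCtTable()] for file
#'   input, [validateCt()], [subsetCt()], [completeCases()]
#' @export
setClass("CtMatrix", contains = "SummarizedExperiment")

.validCtMatrix <- function(object) {
  msg <- character(0)
  if (!"ct" %in% assayNames(object))
    return("assay 'ct' is missing")
  ct <- assay(object, "ct")
  if (!is.numeric(ct))
    msg <- c(msg, "Ct assay must be numeric")
  vals <- ct[!is.na(ct)]
  if (any(!is.finite(vals)))
    msg <- c(msg, "Ct values must be finite")
  if (any(vals <= 0 | vals >= 50))
    msg <- c(msg, "Ct values must lie strictly between 0 and 50 cycles")
  if (nrow(object) < 2)
    msg <- c(msg, "at least 2 genes required")
  if (ncol(object) < 3)
    msg <- c(msg, "at least 3 samples required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- as.character(cd$group)
    if (any(is.na(grp) | !nzchar(grp)))
      msg <- c(msg, "every sample needs a non-empty group label")
  }
  rd <- rowData(object)
  if ("role" %in% colnames(rd)) {
    ok <- as.character(rd$role) %in% c("candidate_reference", "target")
    if (!all(ok))
      msg <- c(msg, "gene roles must be 'candidate_reference' or 'target'")
  } else {
    msg <- c(msg, "rowData must contain a 'role' column")
  }
  if (length(msg)) msg else TRUE
}

setValidity("CtMatrix", .validCtMatrix)

#' Relative quantities derived from Ct values
#'
#' Per-gene relative quantities \eqn{Q = E^{(\min Ct - Ct)}} with
#' amplification efficiency \eqn{E} (fold increase per PCR cycle,
#' ideally 2). Each gene's maximum over samples is exactly 1 (the
#' highest expressor). This is the conventional GeNorm input scale;
#' all downstream stability statistics work on \eqn{\log_2 Q}.
#'
#' @slot Q numeric matrix (genes x samples) of relative quantities in
#'   (0, 1]
#' @slot efficiency amplification efficiency used for the transform
#' @seealso [relativeQuantities()]
#' @export
setClass("RelativeQuantityMatrix",
  representation(Q = "matrix", efficiency = "numeric"),
  validity = function(object) {
    if (any(is.na(object@Q))) return("Q must be complete (no NA)")
    if (any(object@Q <= 0 | object@Q > 1 + 1e-12))
      return("Q values must lie in (0, 1]")
    if (length(object@efficiency) != 1L || object@efficiency <= 1)
      return("efficiency must be a single value > 1")
    TRUE
  })

#' GeNorm stability result
#'
#' Per-gene GeNorm expression-stability values M (mean pairwise
#' log-ratio standard deviation; lower is more stable) from the
#' stepwise-exclusion procedure.
#'
#' @slot M_final per-gene M at the step the gene was excluded; the two
#'   last-surviving genes share the final M
#' @slot M_full_panel per-gene M computed once on the full panel
#' @slot removal_order genes in exclusion order (first removed = least
#'   stable); the final surviving pair is appended last, in input order
#' @slot ranking fractional ranks from the exclusion order (the final
#'   pair ties at rank 1.5)
#' @slot suitability per-gene flag M_final < threshold
#' @slot threshold_used 0.5 (homogeneous panels) or 1.5 (heterogeneous)
#' @slot efficiency amplification efficiency of the underlying
#'   quantities
#' @seealso [geNorm()], [mValues()], [flagSuitability()]
#' @export
setClass("GeNormResult",
  representation(M_final = "numeric", M_full_panel = "numeric",
                 removal_order = "character", ranking = "numeric",
                 suitability = "logical", threshold_used = "numeric",
                 efficiency = "numeric"))

#' GeNorm pairwise-variation curve
#'
#' The values \eqn{V_{n/n+1}} = SD over samples of
#' \eqn{\log_2(NF_n/NF_{n+1})}, where \eqn{NF_n} is the per-sample
#' geometric mean of the \eqn{n} most stable genes' relative
#' quantities, for n = 2..L-1. The optimal reference-gene count is the
#' smallest n whose V passes the cutoff (default 0.15, strict
#' comparison), else the full panel size with a warning.
#'
#' @slot V named numeric, names "2", "3", ...: V_n/n+1 values
#' @slot cutoff decision threshold on V
#' @slot cutoff_inclusive if TRUE, V equal to the cutoff also passes
#' @slot optimal_n selected number of reference genes
#' @slot converged TRUE if some V passed the cutoff
#' @slot ranking_used gene order used to build nested normalization
#'   factors
#' @seealso [pairwiseVariation()]
#' @export
setClass("VCurve",
  representation(V = "numeric", cutoff = "numeric",
                 cutoff_inclusive = "logical", optimal_n = "integer",
                 converged = "logical", ranking_used = "character"))

#' NormFinder stability result
#'
#' Model-based decomposition of Ct variation into inter-group
#' (\code{d_hat}, shrunk to \code{d_tilde}) and intra-group
#' (\code{sigma2}) components, combined into a per-gene stability value
#' \code{sv} (lower is more stable).
#'
#' @slot sv per-gene stability value (cycles)
#' @slot d_hat genes x groups matrix of estimated inter-group
#'   deviations (cycles); sums to zero over genes within each group
#' @slot d_tilde shrunken deviations, |d_tilde| <= |d_hat|
#' @slot sigma2 genes x groups matrix of intra-group variance estimates
#'   (cycles^2)
#' @slot v genes x groups matrix of sampling variances of d_hat
#' @slot gamma2 common inter-group variance estimate (cycles^2)
#' @slot grouped TRUE if the grouped decomposition was used
#' @slot ranking fractional ranks ascending in sv
#' @seealso [normFinder()], [interGroupVariation()]
#' @export
setClass("NormFinderResult",
  representation(sv = "numeric", d_hat = "matrix", d_tilde = "matrix",
                 sigma2 = "matrix", v = "matrix", gamma2 = "numeric",
                 grouped = "logical", ranking = "numeric"))

#' BestKeeper descriptive stability result
#'
#' The BestKeeper index is the per-sample geometric mean of the
#' candidate genes' Ct values; candidates are judged by the Pearson
#' correlation (r) of their Ct with the index and by their Ct
#' dispersion (SD, CV).
#'
#' @slot index per-sample BestKeeper index (cycles)
#' @slot stats data.frame with per-gene columns gene, geo_mean,
#'   arith_mean, min, max, sd, cv, r, p, rank_r, rank_sd
#' @slot sd_variant "sd" (sample SD about the arithmetic mean) or
#'   "mad-geomean" (mean absolute deviation about the geometric mean)
#' @seealso [bestKeeper()], [bestKeeperIndex()]
#' @export
setClass("BestKeeperResult",
  representation(index = "numeric", stats = "data.frame",
                 sd_variant = "character"))

#' Comparative delta-Ct stability result
#'
#' For each gene, the mean over partner genes of the standard deviation
#' of pairwise Ct differences. At efficiency 2 this equals the GeNorm
#' full-panel M value.
#'
#' @slot mean_sd per-gene mean pairwise SD (cycles)
#' @slot ranking fractional ranks ascending in mean_sd
#' @seealso [deltaCtStability()]
#' @export
setClass("DeltaCtStability",
  representation(mean_sd = "numeric", ranking = "numeric"))

#' Consensus ranking across stability methods
#'
#' Assembles the per-method ranks, the summed "final rank" and the
#' RefFinder-style geometric-mean score, plus the recommended
#' reference-gene set.
#'
#' @slot rank_table data.frame of fractional ranks, columns
#'   normfinder, genorm, bestkeeper_r, bestkeeper_sd, delta_ct
#' @slot final_rank_score per-gene sum of the configured method ranks
#' @slot final_rank fractional re-ranking of that sum (1 = best)
#' @slot final_rank_methods columns contributing to the sum
#' @slot reffinder_score geometric mean of the four method ranks
#' @slot reffinder_rank fractional re-ranking of the score
#' @slot reffinder_bestkeeper which BestKeeper column fed the
#'   RefFinder-style score
#' @slot recommended ordered recommended reference-gene set (filled by
#'   [recommendGenes()] / [evaluateStability()])
#' @seealso [assembleRanks()], [finalRank()], [refFinderRank()]
#' @export
setClass("ConsensusRanking",
  representation(rank_table = "data.frame", final_rank_score = "numeric",
                 final_rank = "numeric", final_rank_methods = "character",
                 reffinder_score = "numeric", reffinder_rank = "numeric",
                 reffinder_bestkeeper = "character",
                 recommended = "character"))

#' Full stability evaluation of a candidate panel
#'
#' Container produced by [evaluateStability()]: all four per-method
#' results, the pairwise-variation curve and the consensus ranking for
#' one Ct dataset.
#'
#' @slot genorm \linkS4class{GeNormResult}
#' @slot normfinder \linkS4class{NormFinderResult}
#' @slot bestkeeper \linkS4class{BestKeeperResult}
#' @slot delta_ct \linkS4class{DeltaCtStability}
#' @slot vcurve \linkS4class{VCurve}
#' @slot consensus \linkS4class{ConsensusRanking}
#' @slot panel candidate genes analysed
#' @slot parameters list of run parameters (efficiency, cutoff, ...)
#' @export
setClass("StabilityEvaluation",
  representation(genorm = "GeNormResult", normfinder = "NormFinderResult",
                 bestkeeper = "BestKeeperResult",
                 delta_ct = "DeltaCtStability", vcurve = "VCurve",
                 consensus = "ConsensusRanking", panel = "character",
                 parameters = "list"))

#' Normalized target-gene expression
#'
#' Per-sample delta-Ct, delta-delta-Ct and relative quantity
#' \eqn{rq = E^{-\Delta\Delta Ct}} for one target gene against a
#' reference-gene set, with per-group summaries and Mann-Whitney U
#' tests of each non-control group against the control group.
#'
#' @slot samples data.frame with columns sample, group, delta_ct,
#'   delta_delta_ct, rq
#' @slot group_summary data.frame with columns group, n, mean_rq, sd_rq
#' @slot tests data.frame with columns group, U, p, exact
#' @slot target target gene
#' @slot references reference genes used
#' @slot control_group control group label
#' @slot efficiency amplification efficiency
#' @slot aggregate reference aggregation rule used
#' @seealso [normalizeDdct()], [compareHousekeeping()]
#' @export
setClass("NormalizedExpression",
  representation(samples = "data.frame", group_summary = "data.frame",
                 tests = "data.frame", target = "character",
                 references = "character", control_group = "character",
                 efficiency = "numeric", aggregate = "character"))

#' Specification of one simulated gene
#'
#' @slot name gene identifier
#' @slot baseline_ct baseline threshold cycle (cycles, typically 15-30)
#' @slot noise_sd gene-level Gaussian noise SD on the Ct scale (cycles)
#' @slot group_effects named numeric: per-group Ct shift in cycles
#'   (dysregulation; a fold change F corresponds to -log2(F) cycles)
#' @slot role "candidate_reference" or "target"
#' @seealso [geneSpec()], [syntheticDesign()]
#' @export
setClass("GeneSpec",
  representation(name = "character", baseline_ct = "numeric",
                 noise_sd = "numeric", group_effects = "numeric",
                 role = "character"),
  validity = function(object) {
    if (object@baseline_ct <= 0 || object@baseline_ct >= 50)
      return("baseline_ct must lie strictly between 0 and 50")
    if (object@noise_sd < 0) return("noise_sd must be >= 0")
    if (!object@role %in% c("candidate_reference", "target"))
      return("role must be 'candidate_reference' or 'target'")
    TRUE
  })

#' Design of a synthetic Ct dataset
#'
#' Encodes a multi-group RT-qPCR study design: ordered group labels with
#' per-group sample counts, gene specifications, a per-sample global
#' technical shift (shared across genes, emulating RNA-input and
#' technical variability that normalization must cancel), an optional
#' missing-at-random rate, and a seed.
#'
#' @slot groups named integer: per-group number of samples
#' @slot tissue tissue label for the metadata
#' @slot timepoint time-point label for the metadata
#' @slot genes list of \linkS4class{GeneSpec}
#' @slot technical_shift_sd SD (cycles) of the per-sample global shift
#' @slot missing_rate probability that a cell is masked as missing
#' @slot seed integer default seed for [generateCt()]
#' @seealso [syntheticDesign()], [designPreset()], [generateCt()]
#' @export
setClass("SyntheticDesign",
  representation(groups = "integer", tissue = "character",
                 timepoint = "character", genes = "list",
                 technical_shift_sd = "numeric", missing_rate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@groups) < 1L || is.null(names(object@groups)) ||
        any(!nzchar(names(object@groups))))
      return("groups must be a named vector of per-group sample counts")
    if (any(object@groups < 2L))
      return("each group needs n >= 2 samples")
    if (object@technical_shift_sd < 0)
      return("technical_shift_sd must be >= 0")
    if (object@missing_rate < 0 || object@missing_rate > 1)
      return("missing_rate must lie in [0, 1]")
    if (!all(vapply(object@genes, is, TRUE, class2 = "GeneSpec")))
      return("genes must be a list of GeneSpec objects")
    nm <- vapply(object@genes, function(g) g@name, "")
    if (anyDuplicated(nm)) return("gene names must be unique")
    TRUE
  })
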