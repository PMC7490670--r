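#' Construct a CtMatrix
#'
#' Builds a validated \linkS4class{CtMatrix} from a genes x samples
#' matrix of threshold-cycle values and a per-sample metadata table.
#'
#' @param ct numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids); \code{NA} marks a
#'   missing measurement
#' @param sampleData data.frame (or DataFrame) with one row per sample;
#'   must contain a \code{group} column; \code{tissue} and
#'   \code{timepoint} are carried along when present. Rows are matched
#'   to samples by a \code{sample} column or by rownames; plain
#'   positional order is accepted when neither is present.
#' @param roles per-gene role, \code{"candidate_reference"} (default)
#'   or \code{"target"}; recycled if length 1
#' @return a \linkS4class{CtMatrix}
#' @examples
#' ct <- matrix(c(20, 21, 22, 20.5, 21.5, 22.5), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("Actb", "B2m"), paste0("s", 1:3)))
#' meta <- data.frame(sample = paste0("s", 1:3),
#'                    group = c("control", "control", "Fx"))
#' CtMatrix(ct, meta)
#' @export
CtMatrix <- function(ct, sampleData, roles = "candidate_reference") {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  sampleData <- as.data.frame(sampleData)
  if ("sample" %in% colnames(sampleData)) {
    rownames(sampleData) <- as.character(sampleData$sample)
    sampleData$sample <- NULL
  }
  if (!is.null(colnames(ct)) && all(colnames(ct) %in% rownames(sampleData))) {
    sampleData <- sampleData[colnames(ct), , drop = FALSE]
  } else if (nrow(sampleData) == ncol(ct)) {
    rownames(sampleData) <- colnames(ct)
  } else {
    .stopf("sampleData does not match the samples of 'ct'")
  }
  roles <- rep_len(as.character(roles), nrow(ct))
  se <- SummarizedExperiment(
    assays = list(ct = ct),
    colData = DataFrame(sampleData),
    rowData = DataFrame(role = roles, row.names = rownames(ct)))
  new("CtMatrix", se)
}

#' @describeIn CtMatrix Extract the genes x samples Ct matrix.
#' @param x a \code{CtMatrix}
#' @export
ctValues <- function(x) {
  stopifnot(is(x, "CtMatrix"))
  assay(x, "ct")
}

#' @describeIn CtMatrix Per-sample metadata as a data.frame (sample id,
#'   group, and any further columns such as tissue and timepoint).
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "CtMatrix"))
  cd <- as.data.frame(colData(x))
  data.frame(sample = colnames(x), cd, row.names = NULL,
             check.names = FALSE)
}

#' @describeIn CtMatrix Per-sample group labels, named by sample id.
#' @export
sampleGroups <- function(x) {
  stopifnot(is(x, "CtMatrix"))
  structure(as.character(colData(x)$group), names = colnames(x))
}

#' @describeIn CtMatrix Per-gene roles, named by gene id.
#' @export
geneRoles <- function(x) {
  stopifnot(is(x, "CtMatrix"))
  structure(as.character(rowData(x)$role), names = rownames(x))
}

#' @describeIn CtMatrix Replace the per-gene roles (named or positional).
#' @param value replacement roles
#' @export
`geneRoles<-` <- function(x, value) {
  stopifnot(is(x, "CtMatrix"))
  if (!is.null(names(value))) {
    miss <- setdiff(names(value), rownames(x))
    if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
    roles <- geneRoles(x)
    roles[names(value)] <- value
  } else {
    roles <- rep_len(value, nrow(x))
  }
  rowData(x)$role <- unname(roles)
  validObject(x)
  x
}

#' @describeIn CtMatrix Genes flagged as candidate references.
#' @export
candidateGenes <- function(x) {
  names(which(geneRoles(x) == "candidate_reference"))
}

#' @describeIn CtMatrix Genes flagged as targets.
#' @export
targetGenes <- function(x) {
  names(which(geneRoles(x) == "target"))
}

#' Validate a CtMatrix
#'
#' Re-checks all \linkS4class{CtMatrix} invariants (Ct strictly inside
#' (0, 50) cycles, >= 2 genes, >= 3 samples, unique identifiers,
#' non-empty group labels) and warns about Ct values above 35 cycles,
#' the usual low-expression flag, without rejecting them. Idempotent.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @return \code{ct}, unchanged, if valid; otherwise an error
#' @export
validateCt <- function(ct) {
  stopifnot(is(ct, "CtMatrix"))
  validObject(ct)
  vals <- ctValues(ct)
  nHigh <- sum(vals > 35, na.rm = TRUE)
  if (nHigh > 0)
    .warnf("%d Ct value(s) exceed 35 cycles (low expression)", nHigh)
  ct
}

#' Subset a CtMatrix by genes and sample metadata
#'
#' Filters a \linkS4class{CtMatrix} by gene identifiers and/or by
#' sample metadata labels, preserving the original gene and sample
#' order. This is the entry point for per-condition re-evaluation
#' (e.g. re-running the stability analysis on a subset of experimental
#' groups or one tissue).
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param genes optional character vector of genes to keep
#' @param groups optional group labels to keep
#' @param tissue optional tissue labels to keep
#' @param timepoint optional time-point labels to keep
#' @return the filtered \linkS4class{CtMatrix}
#' @export
subsetCt <- function(ct, genes = NULL, groups = NULL, tissue = NULL,
                     timepoint = NULL) {
  stopifnot(is(ct, "CtMatrix"))
  keepGene <- rep(TRUE, nrow(ct))
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(ct))
    if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
    keepGene <- rownames(ct) %in% genes
  }
  keepSample <- rep(TRUE, ncol(ct))
  filterMeta <- function(keep, field, wanted) {
    if (is.null(wanted)) return(keep)
    if (!field %in% colnames(colData(ct)))
      .stopf("no '%s' metadata present", field)
    have <- as.character(colData(ct)[[field]])
    miss <- setdiff(wanted, have)
    if (length(miss)) .stopf("unknown %s label(s): %s", field, toString(miss))
    keep & have %in% wanted
  }
  keepSample <- filterMeta(keepSample, "group", groups)
  keepSample <- filterMeta(keepSample, "tissue", tissue)
  keepSample <- filterMeta(keepSample, "timepoint", timepoint)
  if (!any(keepGene) || !any(keepSample))
    .stopf("subset is empty")
  out <- ct[keepGene, keepSample]
  validObject(out)
  out
}

#' Restrict to complete cases over a gene panel
#'
#' Drops every sample that has a missing Ct for any of the named genes.
#' All stability statistics (the BestKeeper index and the GeNorm
#' normalization factors are sample-wise products) require complete
#' cases over the panel in use; pairwise-complete analysis would be
#' unsound.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param genes gene panel to require completeness over; defaults to
#'   the candidate reference genes
#' @return the \linkS4class{CtMatrix} restricted to complete samples;
#'   dropped sample ids are reported via \code{message()}
#' @export
completeCases <- function(ct, genes = candidateGenes(ct)) {
  stopifnot(is(ct, "CtMatrix"))
  miss <- setdiff(genes, rownames(ct))
  if (length(miss)) .stopf("unknown gene(s): %s", toString(miss))
  vals <- ctValues(ct)[genes, , drop = FALSE]
  keep <- colSums(is.na(vals)) == 0L
  if (sum(keep) < 3L)
    .stopf("fewer than 3 complete samples remain over panel {%s}",
           toString(genes))
  if (!all(keep))
    message("completeCases: dropped sample(s) ",
            toString(colnames(ct)[!keep]))
  if (all(keep)) return(ct)
  out <- ct[, keep]
  validObject(out)
  out
}

setMethod("show", "CtMatrix", function(object) {
  roles <- geneRoles(object)
  cat("CtMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  candidates:", sum(roles == "candidate_reference"),
      " targets:", sum(roles == "target"),
      " missing cells:", sum(is.na(ctValues(object))), "\n")
  grp <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp),
                         collapse = ", "), "\n")
  extra <- intersect(c("tissue", "timepoint"), colnames(colData(object)))
  for (f in extra)
    cat(sprintf("  %s: %s\n", f,
                toString(unique(as.character(colData(object)[[f]])))))
  invisible(NULL)
})
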