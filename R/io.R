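# Ct table file I/O. Two dialects:
#   long: one row per (sample, gene), columns sample,gene,ct[,group,tissue,timepoint]
#   wide: genes as rows (first column 'gene', remaining columns sample ids)
#         plus a mandatory metadata sidecar: sample,group[,tissue,timepoint]
# Delimiter is sniffed between comma and tab; decimal point only.

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

.readDelim <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.table(path, sep = .sniffSep(path), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", comment.char = "",
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

# shortest decimal string that re-parses to the identical double, so
# write -> read round-trips are bit-exact without 17-digit clutter
.formatCt <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:16) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# strict numeric parsing; empty and "NA" become missing, anything else
# non-numeric is an input error located by gene and sample
.parseCt <- function(values, gene, sample) {
  values <- trimws(values)
  blank <- is.na(values) | values == "" | values == "NA"
  parsed <- suppressWarnings(as.numeric(values))
  bad <- which(!blank & is.na(parsed))
  if (length(bad)) {
    i <- bad[1L]
    .stopf("unparseable Ct value '%s' (gene %s, sample %s)",
           values[i], gene[i], sample[i])
  }
  parsed[blank] <- NA_real_
  parsed
}

#' Read a Ct table from a delimited file
#'
#' Reads threshold-cycle data in either the long dialect (columns
#' \code{sample,gene,ct} plus optional \code{group,tissue,timepoint})
#' or the wide dialect (first column \code{gene}, remaining columns one
#' per sample) with a metadata sidecar file (columns
#' \code{sample,group} plus optional \code{tissue,timepoint}). The
#' delimiter is sniffed between comma and tab. Empty cells and
#' \code{"NA"} are preserved as missing values.
#'
#' @param path path to the Ct table
#' @param format \code{"long"} or \code{"wide"}
#' @param meta path to the metadata sidecar (required for wide; for
#'   long it overrides any metadata columns in the table)
#' @param roles optional named per-gene roles (see [CtMatrix()])
#' @return a validated \linkS4class{CtMatrix}
#' @seealso [writeCtTable()], [writeCtJSON()]
#' @export
readCtTable <- function(path, format = c("long", "wide"), meta = NULL,
                        roles = "candidate_reference") {
  format <- match.arg(format)
  tab <- .readDelim(path)
  metaTab <- if (!is.null(meta)) .readDelim(meta)
  if (format == "long") {
    need <- c("sample", "gene", "ct")
    if (!all(need %in% colnames(tab)))
      .stopf("long format needs columns %s", toString(need))
    dup <- duplicated(tab[c("sample", "gene")])
    if (any(dup))
      .stopf("duplicate (sample, gene) pair: (%s, %s)",
             tab$sample[dup][1L], tab$gene[dup][1L])
    genes <- unique(tab$gene)
    samples <- unique(tab$sample)
    ct <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    ct[cbind(tab$gene, tab$sample)] <-
      .parseCt(tab$ct, tab$gene, tab$sample)
    metaCols <- intersect(c("group", "tissue", "timepoint"), colnames(tab))
    sampleData <- if (!is.null(metaTab)) {
      metaTab
    } else {
      if (!"group" %in% metaCols)
        .stopf("long format without a metadata sidecar needs a 'group' column")
      unique(tab[c("sample", metaCols)])
    }
  } else {
    if (colnames(tab)[1L] != "gene")
      .stopf("wide format: first column must be 'gene'")
    if (is.null(metaTab))
      .stopf("wide format requires a metadata sidecar file")
    genes <- tab$gene
    samples <- colnames(tab)[-1L]
    ct <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    for (s in samples)
      ct[, s] <- .parseCt(tab[[s]], genes, rep(s, length(genes)))
    sampleData <- metaTab
  }
  if (!"group" %in% colnames(sampleData) ||
      anyNA(sampleData$group) || any(!nzchar(sampleData$group)))
    .stopf("every sample needs a non-empty group label")
  if (anyDuplicated(sampleData$sample))
    .stopf("duplicate sample id in metadata: %s",
           sampleData$sample[duplicated(sampleData$sample)][1L])
  if (!is.null(names(roles))) {
    r <- rep("candidate_reference", length(genes))
    names(r) <- genes
    r[intersect(names(roles), genes)] <-
      roles[intersect(names(roles), genes)]
    roles <- unname(r)
  }
  validateCt(CtMatrix(ct, sampleData, roles = roles))
}

#' Write a Ct table to a delimited file
#'
#' Inverse of [readCtTable()]: writes the long dialect in one file, or
#' the wide dialect plus a metadata sidecar. Read-write-read
#' round-trips are value-identical.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param path output path
#' @param format \code{"long"} or \code{"wide"}
#' @param meta sidecar path, required for wide format
#' @param sep field delimiter, tab by default
#' @return \code{path}, invisibly
#' @export
writeCtTable <- function(ct, path, format = c("long", "wide"),
                         meta = NULL, sep = "\t") {
  stopifnot(is(ct, "CtMatrix"))
  format <- match.arg(format)
  vals <- ctValues(ct)
  info <- sampleInfo(ct)
  metaCols <- intersect(c("sample", "group", "tissue", "timepoint"),
                        colnames(info))
  if (format == "long") {
    long <- data.frame(
      sample = rep(colnames(vals), each = nrow(vals)),
      gene = rep(rownames(vals), times = ncol(vals)),
      ct = as.vector(vals),
      stringsAsFactors = FALSE)
    long <- merge(long, info[metaCols], by = "sample", sort = FALSE)
    # keep deterministic sample-major order after merge
    long <- long[order(match(long$sample, colnames(vals)),
                       match(long$gene, rownames(vals))), ]
    long$ct <- .formatCt(long$ct)
    utils::write.table(long, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    if (is.null(meta))
      .stopf("wide format requires a 'meta' sidecar path")
    wide <- data.frame(gene = rownames(vals),
                       apply(vals, 2L, .formatCt),
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(wide, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(info[metaCols], meta, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Export a CtMatrix as JSON
#'
#' Serializes the full dataset (genes, roles, Ct values and sample
#' metadata) to a single JSON document.
#'
#' @param ct a \linkS4class{CtMatrix}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCtJSON <- function(ct, path) {
  stopifnot(is(ct, "CtMatrix"))
  obj <- list(
    genes = rownames(ct),
    roles = unname(geneRoles(ct)),
    samples = sampleInfo(ct),
    ct = lapply(seq_len(nrow(ct)),
                function(i) unname(ctValues(ct)[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
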