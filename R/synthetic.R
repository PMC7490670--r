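# Seeded synthetic Ct-data generator.
#
# Generative model per cell (gene i, sample s in group g):
#   Ct_is = baseline_i + shift_s + effect_ig + eps_is
#   shift_s ~ N(0, technical_shift_sd^2)    shared across genes
#   eps_is  ~ N(0, noise_sd_i^2)            independent
# then cells are masked completely at random at missing_rate. Noise is
# Gaussian on the Ct (log2 expression) scale, the homoscedastic
# log-scale assumption underlying all four stability methods. The
# shared per-sample shift emulates RNA-input / technical variability,
# the very structure reference-gene normalization must cancel.

#' Specify a simulated gene
#'
#' @param name gene identifier
#' @param baselineCt baseline threshold cycle in cycles (typical
#'   15-30; strong expression = low Ct)
#' @param noiseSd gene-level Gaussian noise SD on the Ct scale
#' @param groupEffects named numeric of per-group Ct shifts in cycles;
#'   a fold change F in expression corresponds to a shift of
#'   \code{-log2(F)} cycles
#' @param role \code{"candidate_reference"} or \code{"target"}
#' @return a \linkS4class{GeneSpec}
#' @export
geneSpec <- function(name, baselineCt, noiseSd = 0.2,
                     groupEffects = numeric(0),
                     role = "candidate_reference") {
  if (length(groupEffects) && is.null(names(groupEffects)))
    .stopf("groupEffects must be named by group")
  new("GeneSpec", name = name, baseline_ct = baselineCt,
      noise_sd = noiseSd, group_effects = groupEffects, role = role)
}

#' Specify a synthetic Ct study design
#'
#' @param genes list of \linkS4class{GeneSpec}
#' @param groups named integer vector: per-group sample count; the
#'   default is the four-arm trauma design (control, isolated
#'   fracture Fx, traumatic brain injury TBI, combined TBI+Fx) with
#'   n = 6 per group
#' @param tissue,timepoint metadata labels for the generated samples
#' @param technicalShiftSd SD (cycles) of the per-sample global
#'   technical shift shared across genes
#' @param missingRate probability that a cell is masked as missing
#' @param seed default seed used by [generateCt()]
#' @return a \linkS4class{SyntheticDesign}
#' @seealso [designPreset()] for ready-made designs
#' @export
syntheticDesign <- function(genes,
                            groups = c(control = 6L, Fx = 6L, TBI = 6L,
                                       `TBI+Fx` = 6L),
                            tissue = "bone", timepoint = "d3",
                            technicalShiftSd = 0.3, missingRate = 0,
                            seed = 1L) {
  new("SyntheticDesign", groups = structure(as.integer(groups),
                                            names = names(groups)),
      tissue = tissue, timepoint = timepoint, genes = genes,
      technical_shift_sd = technicalShiftSd,
      missing_rate = missingRate, seed = as.integer(seed))
}

#' Generate a synthetic CtMatrix from a design
#'
#' Draws one Ct dataset from the design's generative model. Given the
#' same seed the result is bit-identical across runs and platforms
#' (fixed Mersenne-Twister / inversion generator).
#'
#' @param design a \linkS4class{SyntheticDesign}
#' @param seed integer seed; defaults to the seed stored in the design
#' @return a \linkS4class{CtMatrix}
#' @export
generateCt <- function(design, seed = design@seed) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  groups <- names(design@groups)
  grpOfSample <- rep(groups, times = design@groups)
  n <- length(grpOfSample)
  sampleIds <- paste0(grpOfSample, "_",
                      unlist(lapply(design@groups, seq_len)))
  genes <- vapply(design@genes, function(g) g@name, "")
  L <- length(genes)
  if (L < 2L) .stopf("a design needs at least 2 genes")
  ct <- .withSeed(seed, {
    shift <- stats::rnorm(n, 0, design@technical_shift_sd)
    m <- matrix(NA_real_, L, n, dimnames = list(genes, sampleIds))
    for (i in seq_len(L)) {
      g <- design@genes[[i]]
      eff <- structure(numeric(length(groups)), names = groups)
      known <- intersect(names(g@group_effects), groups)
      eff[known] <- g@group_effects[known]
      m[i, ] <- g@baseline_ct + shift + eff[grpOfSample] +
        stats::rnorm(n, 0, g@noise_sd)
    }
    if (design@missing_rate > 0) {
      mask <- stats::runif(length(m)) < design@missing_rate
      m[mask] <- NA_real_
    }
    m
  })
  meta <- data.frame(sample = sampleIds, group = grpOfSample,
                     tissue = design@tissue,
                     timepoint = design@timepoint,
                     stringsAsFactors = FALSE)
  roles <- vapply(design@genes, function(g) g@role, "")
  CtMatrix(ct, meta, roles = roles)
}

#' Ready-made synthetic designs
#'
#' Four stylized designs emulating a four-arm murine trauma study
#' (groups control / Fx / TBI / TBI+Fx, n = 6 per group, time point
#' d3) with five to ten candidate reference genes:
#' \describe{
#'   \item{neutral}{5 candidates, no planted dysregulation, gene noise
#'     SD 0.1 cycles — a well-behaved panel where two reference genes
#'     suffice.}
#'   \item{paper_d3_bone}{5 candidates, noise SD 0.3; an *Actb*-like
#'     gene shifted by +1.5 cycles in the fracture-bearing groups (Fx
#'     and TBI+Fx), emulating strong cytoskeletal dysregulation in
#'     bone/callus after fracture.}
#'   \item{paper_d3_hypothalamus}{5 candidates, noise SD 0.2; a
#'     *B2m*-like gene shifted by +1.5 cycles in the TBI-bearing
#'     groups (TBI and TBI+Fx), emulating immune-related dysregulation
#'     in the injured hypothalamus.}
#'   \item{paper_wat}{10 candidates, noise SD 0.15; a *Gapdh*-like
#'     gene mildly shifted (+0.5 cycles) in all trauma groups with
#'     extra noise, emulating metabolic dysregulation in white adipose
#'     tissue.}
#' }
#' Baseline Ct values (15-30 cycles), noise (0.1-0.3 cycles), planted
#' shifts (0.5-1.5 cycles) and the per-sample technical shift (0.3
#' cycles) are stylized to the scale of typical rodent-tissue RT-qPCR
#' panels; they are not fitted to any particular dataset.
#'
#' @param name preset name
#' @return a \linkS4class{SyntheticDesign}
#' @export
designPreset <- function(name = c("neutral", "paper_d3_bone",
                                  "paper_d3_hypothalamus", "paper_wat")) {
  name <- match.arg(name)
  core <- function(noise, actbEff = numeric(0), b2mEff = numeric(0)) {
    list(geneSpec("Actb", 17, noise, groupEffects = actbEff),
         geneSpec("B2m", 20, noise, groupEffects = b2mEff),
         geneSpec("Gapdh", 19, noise),
         geneSpec("Hprt", 23, noise),
         geneSpec("Ppia", 18, noise))
  }
  switch(name,
    neutral = syntheticDesign(core(0.1), tissue = "bone"),
    paper_d3_bone = syntheticDesign(
      core(0.3, actbEff = c(Fx = 1.5, `TBI+Fx` = 1.5)),
      tissue = "bone"),
    paper_d3_hypothalamus = syntheticDesign(
      core(0.2, b2mEff = c(TBI = 1.5, `TBI+Fx` = 1.5)),
      tissue = "hypothalamus"),
    paper_wat = syntheticDesign(
      c(core(0.15)[-3],
        list(geneSpec("Gapdh", 19, 0.35,
                      groupEffects = c(Fx = 0.5, TBI = 0.5,
                                       `TBI+Fx` = 0.5)),
             geneSpec("Hmbs", 24, 0.15),
             geneSpec("Psmb2", 21, 0.15),
             geneSpec("Rplp0", 16, 0.15),
             geneSpec("Srsf4", 25, 0.15),
             geneSpec("Tbp", 27, 0.15))),
      tissue = "WAT"))
}

#' Append a target gene to a design
#'
#' Adds a \code{target}-role gene whose per-group fold changes are
#' encoded as Ct shifts of \code{-log2(fold)} cycles (a 2-fold
#' induction lowers Ct by one cycle).
#'
#' @param design a \linkS4class{SyntheticDesign}
#' @param name new gene name (must be unused)
#' @param foldChanges named numeric of per-group fold changes (> 0)
#' @param noiseSd gene-level noise SD in cycles
#' @param baselineCt baseline Ct of the target
#' @return the extended \linkS4class{SyntheticDesign}
#' @export
addTarget <- function(design, name, foldChanges = numeric(0),
                      noiseSd = 0.2, baselineCt = 25) {
  stopifnot(is(design, "SyntheticDesign"))
  existing <- vapply(design@genes, function(g) g@name, "")
  if (name %in% existing) .stopf("gene '%s' already in the design", name)
  if (length(foldChanges) && any(foldChanges <= 0))
    .stopf("fold changes must be strictly positive")
  design@genes <- c(design@genes,
                    list(geneSpec(name, baselineCt, noiseSd,
                                  groupEffects = -log2(foldChanges),
                                  role = "target")))
  validObject(design)
  design
}

#' A small deterministic example dataset
#'
#' Convenience wrapper used in documentation examples: the
#' \code{paper_d3_bone} preset generated at a fixed seed.
#'
#' @param seed integer seed
#' @return a \linkS4class{CtMatrix}
#' @export
exampleCtMatrix <- function(seed = 42L) {
  generateCt(designPreset("paper_d3_bone"), seed = seed)
}

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", length(object@genes), "genes,",
      sum(object@groups), "samples (",
      paste(sprintf("%s:%d", names(object@groups), object@groups),
            collapse = ", "), ")\n")
  cat("  tissue:", object@tissue, " timepoint:", object@timepoint,
      " technical shift SD:", object@technical_shift_sd,
      " missing rate:", object@missing_rate, "\n")
  for (g in object@genes) {
    eff <- if (length(g@group_effects))
      paste0(" effects: ", paste(sprintf("%s%+g", names(g@group_effects),
                                         g@group_effects),
                                 collapse = ", "))
    else ""
    cat(sprintf("  %s [%s] baseline %.3g, noise %.3g%s\n", g@name,
                g@role, g@baseline_ct, g@noise_sd, eff))
  }
  invisible(NULL)
})

setMethod("show", "GeneSpec", function(object) {
  cat(sprintf("GeneSpec %s [%s]: baseline %.3g cycles, noise SD %.3g\n",
              object@name, object@role, object@baseline_ct,
              object@noise_sd))
  if (length(object@group_effects))
    print(object@group_effects)
  invisible(NULL)
})
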