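# per-method results on one dataset, reused across blocks
evalParts <- function(ct) {
  rq <- relativeQuantities(ct)
  list(nf = normFinder(ct), gn = geNorm(rq), bk = bestKeeper(ct),
       dct = deltaCtStability(ct), rq = rq)
}

test_that("delta-Ct stability reproduces the hand computation", {
  m <- matrix(c(20, 21, 22,
                20, 21, 22,
                20, 22, 21), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:3)))
  dct <- deltaCtStability(ctFromMatrix(m))
  expect_equal(unname(dct@mean_sd), c(0.5, 0.5, 1.0), tolerance = 1e-12)

  m2 <- matrix(c(20, 21, 22, 23, 24, 25), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_equal(unname(deltaCtStability(ctFromMatrix(m2))@mean_sd),
               c(0, 0), tolerance = 1e-12)
})

test_that("delta-Ct stability equals the GeNorm full-panel M at E = 2", {
  set.seed(51)
  for (i in 1:20) {
    ct <- randomCtMatrix(L = sample(4:8, 1), n = sample(6:30, 1),
                         sd = runif(1, 0.1, 1))
    dct <- deltaCtStability(ct)
    M <- mValues(relativeQuantities(ct, efficiency = 2))
    expect_equal(dct@mean_sd, M, tolerance = 1e-12)
  }
})

test_that("rank assembly applies fractional ties and catches mismatches", {
  set.seed(52)
  ct <- generateCt(designPreset("paper_d3_bone"), seed = 77L)
  p <- evalParts(ct)
  rt <- assembleRanks(p$nf, p$gn, p$bk, p$dct)
  expect_setequal(rownames(rt), rownames(ct))
  # every column is a fractional ranking of the full gene set
  for (col in colnames(rt)) expect_equal(sum(rt[[col]]), sum(1:5))
  # the genorm column carries the tied final pair at rank 1.5
  expect_equal(sort(rt$genorm)[1:2], c(1.5, 1.5))

  sub <- subsetCt(ct, genes = rownames(ct)[1:4])
  expect_error(assembleRanks(normFinder(sub), p$gn, p$bk, p$dct),
               "same gene panel")
})

test_that("rank aggregation is invariant to gene input order", {
  ct <- generateCt(designPreset("paper_d3_bone"), seed = 78L)
  p <- evalParts(ct)
  rt <- assembleRanks(p$nf, p$gn, p$bk, p$dct)
  perm <- c("Hprt", "Actb", "Ppia", "B2m", "Gapdh")
  rqP <- relativeQuantities(ct, panel = perm)
  rtP <- assembleRanks(normFinder(ct, panel = perm), geNorm(rqP),
                       bestKeeper(ct, panel = perm),
                       deltaCtStability(ct, panel = perm))
  expect_equal(rtP[rownames(rt), ], rt, tolerance = 1e-12)
})

test_that("the summed final rank follows the configured methods", {
  rt <- data.frame(normfinder = c(1, 2), genorm = c(2, 1),
                   bestkeeper_r = c(1, 2), bestkeeper_sd = c(2, 1),
                   delta_ct = c(1, 2), row.names = c("a", "b"))
  fr <- finalRank(rt)
  expect_equal(fr["a", "score"], 6)
  expect_equal(unname(fr$rank), c(1.5, 1.5))   # equal sums tie

  one <- finalRank(rt, methods = "normfinder")
  expect_equal(one$rank, rt$normfinder)
  expect_error(finalRank(rt, methods = character(0)), "at least one")
})

test_that("the RefFinder-style score is the rank geometric mean", {
  rt <- data.frame(normfinder = 2, genorm = 1, bestkeeper_sd = 3,
                   bestkeeper_r = 4, delta_ct = 1, row.names = "a")
  rf <- refFinderRank(rt)
  expect_equal(rf["a", "score"], 6^(1 / 4), tolerance = 1e-12)

  rt2 <- data.frame(normfinder = c(1, 3), genorm = c(1, 3),
                    bestkeeper_sd = c(1, 3), bestkeeper_r = c(2, 2),
                    delta_ct = c(1, 3), row.names = c("a", "b"))
  rf2 <- refFinderRank(rt2)
  expect_equal(rf2["a", "score"], 1)          # rank 1 everywhere
  expect_equal(rf2["b", "score"], 3)          # idempotent on equal ranks
  expect_equal(unname(rf2$rank), c(1, 2))

  # geometric-mean bounds
  set.seed(53)
  ct <- randomCtMatrix(L = 6, n = 12)
  p <- evalParts(ct)
  rt3 <- assembleRanks(p$nf, p$gn, p$bk, p$dct)
  rf3 <- refFinderRank(rt3)
  four <- rt3[, c("delta_ct", "normfinder", "genorm", "bestkeeper_sd")]
  expect_true(all(rf3$score <= apply(four, 1, max) + 1e-12))
  expect_true(all(rf3$score >= apply(four, 1, min) - 1e-12))
  expect_true(all(rf3$score >= 1))
})

test_that("final rank and RefFinder-style rank agree on a unanimous worst", {
  rt <- data.frame(normfinder = c(2, 1, 3), genorm = c(1.5, 1.5, 3),
                   bestkeeper_r = c(1, 2, 3), bestkeeper_sd = c(2, 1, 3),
                   delta_ct = c(1, 2, 3),
                   row.names = c("a", "b", "c"))
  expect_equal(which.max(finalRank(rt)$rank), 3L)
  expect_equal(which.max(refFinderRank(rt)$rank), 3L)
})

test_that("recommendation takes the top optimal_n with tie-breaks", {
  ct <- generateCt(designPreset("paper_d3_bone"), seed = 80L)
  ev <- evaluateStability(ct)
  rec <- recommendedGenes(ev)
  expect_length(rec, optimalN(ev@vcurve))
  ord <- order(ev@consensus@final_rank, ev@consensus@reffinder_score)
  expect_equal(rec,
               names(ev@consensus@final_rank)[ord][seq_along(rec)])
  expect_false("Actb" %in% rec)   # the planted unstable gene

  # failing the suitability threshold warns but does not drop
  suit <- ev@genorm@suitability
  suit[rec[1]] <- FALSE
  expect_warning(rec2 <- recommendGenes(ev@consensus, ev@vcurve, suit),
                 "threshold")
  expect_equal(rec2, rec)
})

test_that("the full pipeline ranks a planted unstable gene last", {
  ct <- generateCt(designPreset("paper_d3_bone"), seed = 81L)
  ev <- evaluateStability(ct)
  fr <- ev@consensus@final_rank
  expect_equal(names(which.max(fr)), "Actb")
  expect_equal(names(which.max(ev@consensus@reffinder_rank)), "Actb")
})
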