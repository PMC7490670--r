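# noise-free fixture: stable references, target regulated in Fx
exactRegulationCt <- function(foldFx = 2) {
  groups <- rep(c("control", "Fx", "TBI", "TBI+Fx"), each = 3)
  n <- length(groups)
  shift <- seq(-0.5, 0.6, length.out = n)   # per-sample technical shift
  m <- rbind(Ref1 = 18 + shift, Ref2 = 22 + shift,
             Tgt = 25 + shift - log2(foldFx) * (groups == "Fx"))
  colnames(m) <- paste0("s", seq_len(n))
  ct <- CtMatrix(m, data.frame(sample = colnames(m), group = groups))
  geneRoles(ct) <- c(Tgt = "target")
  ct
}

test_that("a one-cycle drop doubles the relative quantity exactly", {
  ct <- exactRegulationCt(foldFx = 2)
  ne <- normalizeDdct(ct, "Tgt", c("Ref1", "Ref2"), "control")
  s <- ne@samples
  expect_equal(s$rq[s$group == "Fx"], rep(2, 3), tolerance = 1e-12)
  expect_equal(s$rq[s$group == "control"], rep(1, 3), tolerance = 1e-12)
  ctrlGeo <- exp(mean(log(s$rq[s$group == "control"])))
  expect_equal(ctrlGeo, 1, tolerance = 1e-12)
})

test_that("relative quantities cancel global per-sample shifts", {
  set.seed(61)
  d <- addTarget(designPreset("neutral"), "Tgt",
                 foldChanges = c(Fx = 1.7), noiseSd = 0.2)
  ct <- generateCt(d, seed = 17L)
  ne1 <- normalizeDdct(ct, "Tgt", c("Hprt", "Gapdh"), "control")
  m <- ctValues(ct) + outer(rep(1, nrow(ct)), rnorm(ncol(ct), 0, 2))
  ct2 <- CtMatrix(m, sampleInfo(ct), roles = unname(geneRoles(ct)))
  ne2 <- normalizeDdct(ct2, "Tgt", c("Hprt", "Gapdh"), "control")
  expect_equal(ne1@samples$rq, ne2@samples$rq, tolerance = 1e-9)
})

test_that("control-group geometric mean rq is exactly 1 on any input", {
  set.seed(62)
  for (i in 1:10) {
    ct <- randomCtMatrix(L = 4, n = 12, sd = runif(1, 0.2, 1))
    ne <- normalizeDdct(ct, "g1", c("g2", "g3"), "grp1")
    ctrl <- ne@samples$group == "grp1"
    expect_equal(exp(mean(log(ne@samples$rq[ctrl]))), 1,
                 tolerance = 1e-12)
  }
})

test_that("multi-reference aggregation equals a pseudo-reference gene", {
  set.seed(63)
  ct <- randomCtMatrix(L = 4, n = 12, sd = 0.5)
  ne <- normalizeDdct(ct, "g1", c("g2", "g3"), "grp1")
  m <- ctValues(ct)
  m2 <- rbind(m, pseudo = colMeans(m[c("g2", "g3"), ]))
  ct2 <- ctFromMatrix(m2)
  ne2 <- normalizeDdct(ct2, "g1", "pseudo", "grp1")
  expect_equal(ne@samples$rq, ne2@samples$rq, tolerance = 1e-12)
})

test_that("the target cannot appear among its references", {
  ct <- exactRegulationCt()
  expect_error(normalizeDdct(ct, "Tgt", c("Tgt", "Ref1"), "control"),
               "references")
  expect_error(normalizeDdct(ct, "Tgt", "Ref1", "nope"),
               "control group")
})

test_that("Mann-Whitney U matches hand enumeration on small samples", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)  # 2/20 arrangements
  expect_true(mw$exact)

  same <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p.value, 1)
  expect_false(same$exact)     # ties force the approximation

  expect_error(mannWhitneyU(c(1, 2), c(3, 4, 5)), ">= 3")
})

test_that("exact p equals the enumeration oracle for n1, n2 <= 4", {
  for (n1 in 3:4) {
    for (n2 in 3:4) {
      N <- n1 + n2
      udist <- oracleUdist(n1, n2)
      subsets <- combn(N, n1)
      for (j in seq_len(ncol(subsets))) {
        a <- subsets[, j]
        b <- setdiff(seq_len(N), a)
        mw <- mannWhitneyU(a, b)
        expect_equal(mw$p.value,
                     oracleExactP(sum(a) - n1 * (n1 + 1) / 2, n1, n2,
                                  udist),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exact and approximate p agree closely without ties", {
  set.seed(64)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    exact <- mannWhitneyU(a, b)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_lt(abs(exact$p.value - approx$p.value), 0.02)
    expect_true(exact$exact)
  }
})

test_that("the Shapiro-Wilk gate annotates normality sensibly", {
  # type-I error near the nominal 5% on normal data
  set.seed(65)
  rejections <- sum(vapply(1:500, function(i) {
    !shapiroWilkGate(rnorm(200))$is_normal
  }, logical(1)))
  expect_gt(rejections / 500, 0.03)
  expect_lt(rejections / 500, 0.07)

  # strong power against an exponential sample
  set.seed(66)
  caught <- sum(vapply(1:200, function(i) {
    !shapiroWilkGate(rexp(50))$is_normal
  }, logical(1)))
  expect_gte(caught / 200, 0.95)

  const <- shapiroWilkGate(rep(2, 10))
  expect_true(const$degenerate)
  expect_true(is.na(const$W))
  expect_error(shapiroWilkGate(c(1, 2)), "3 <= n")
})

test_that("housekeeping choice drives false positives and negatives", {
  # unregulated target; one reference dysregulated +1 cycle in Fx
  badFP <- goodFP <- 0L
  nSim <- 60L
  for (s in seq_len(nSim)) {
    d <- syntheticDesign(
      list(geneSpec("Bad", 19, 0.2, groupEffects = c(Fx = 1)),
           geneSpec("Ref1", 21, 0.2), geneSpec("Ref2", 23, 0.2)),
      technicalShiftSd = 0.3)
    d <- addTarget(d, "Tgt", foldChanges = numeric(0), noiseSd = 0.2)
    ct <- generateCt(d, seed = 7000L + s)
    res <- compareHousekeeping(ct, "Tgt",
                               list(bad = "Bad",
                                    good = c("Ref1", "Ref2")),
                               controlGroup = "control")
    pBad <- res$bad@tests$p[res$bad@tests$group == "Fx"]
    pGood <- res$good@tests$p[res$good@tests$group == "Fx"]
    badFP <- badFP + (pBad < 0.05)
    goodFP <- goodFP + (pGood < 0.05)
  }
  expect_gte(badFP / nSim, 0.8)    # spurious regulation manufactured
  expect_lte(goodFP / nSim, 0.1)   # stable references stay quiet

  # identical reference sets give identical results
  ct <- generateCt(addTarget(designPreset("neutral"), "Tgt",
                             c(Fx = 2), 0.2), seed = 5L)
  twin <- compareHousekeeping(ct, "Tgt",
                              list(a = c("Hprt", "Gapdh"),
                                   b = c("Hprt", "Gapdh")), "control")
  expect_equal(twin$a@samples, twin$b@samples)
  expect_equal(twin$a@tests, twin$b@tests)
})

test_that("per-reference averaging is an alternative aggregate", {
  ct <- exactRegulationCt(foldFx = 2)
  ne <- normalizeDdct(ct, "Tgt", c("Ref1", "Ref2"), "control",
                      aggregate = "perReference")
  s <- ne@samples
  # noise-free: both interpretations coincide
  expect_equal(s$rq[s$group == "Fx"], rep(2, 3), tolerance = 1e-12)
})
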