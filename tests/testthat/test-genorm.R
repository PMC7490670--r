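# hand-checkable 3-gene fixture: g1 = g2 shifted, g3 permuted
threeGeneCt <- function() {
  m <- matrix(c(20, 21, 22,
                20, 21, 22,
                20, 22, 21), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3")))
  ctFromMatrix(m, nGroups = 1L)
}

test_that("relative quantities follow Q = E^(minCt - Ct)", {
  m <- matrix(c(20, 21, 22, 25, 25, 25), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  rq <- relativeQuantities(ctFromMatrix(m))
  expect_equal(unname(rq@Q["a", ]), c(1, 0.5, 0.25))
  expect_equal(unname(rq@Q["b", ]), c(1, 1, 1))
  expect_error(relativeQuantities(ctFromMatrix(m), efficiency = 1),
               "efficiency")

  m[1, 2] <- NA
  expect_error(relativeQuantities(ctFromMatrix(m)), "completeCases")
})

test_that("M values match the hand-computed pairwise SDs", {
  rq <- relativeQuantities(threeGeneCt())
  M <- mValues(rq)
  # V12 = 0, V13 = V23 = sd(c(0,-1,1)) = 1
  expect_equal(unname(M), c(0.5, 0.5, 1.0), tolerance = 1e-12)
})

test_that("M is zero for constant-offset genes and shift-invariant", {
  m <- matrix(c(20, 21, 22, 23, 24, 25), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  M <- mValues(relativeQuantities(ctFromMatrix(m)))
  expect_equal(unname(M), c(0, 0), tolerance = 1e-12)

  set.seed(101)
  ct <- randomCtMatrix(L = 5, n = 10)
  M1 <- mValues(relativeQuantities(ct))
  shifted <- ctValues(ct) +
    outer(rep(1, 5), rnorm(10))   # arbitrary per-sample constants
  M2 <- mValues(relativeQuantities(ctFromMatrix(shifted)))
  expect_equal(M1, M2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("M agrees with the brute-force oracle on random panels", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(4:8, 1)
    n <- sample(6:30, 1)
    ct <- randomCtMatrix(L = L, n = n, sd = runif(1, 0.1, 1))
    M <- mValues(relativeQuantities(ct))
    expect_equal(unname(M), oracleM(ctValues(ct)), tolerance = 1e-12)
  }
})

test_that("stepwise exclusion removes the least stable gene first", {
  gn <- geNorm(relativeQuantities(threeGeneCt()))
  expect_equal(removalOrder(gn)[1], "g3")
  expect_equal(unname(gn@M_final[c("g1", "g2")]), c(0, 0))
  # final surviving pair shares its M and ties at the top
  expect_equal(gn@M_final[["g1"]], gn@M_final[["g2"]])
  expect_equal(unname(gn@ranking[c("g1", "g2")]), c(1.5, 1.5))
})

test_that("exclusion ties break by input order on identical genes", {
  m <- outer(c(20, 22, 24, 26), rep(1, 5)) +
    outer(rep(1, 4), c(0, 0.5, 1, 1.5, 2))
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:5))
  gn <- geNorm(relativeQuantities(ctFromMatrix(m)))
  expect_equal(unname(gn@M_final), rep(0, 4))
  expect_equal(removalOrder(gn), paste0("g", 1:4))
})

test_that("a strongly group-shifted gene is excluded first", {
  hits <- 0L
  for (s in 1:50) {
    d <- designPreset("paper_d3_bone")  # Actb shifted 1.5, sigma 0.3
    ct <- generateCt(d, seed = 1000L + s)
    gn <- geNorm(relativeQuantities(ct))
    hits <- hits + (removalOrder(gn)[1] == "Actb")
  }
  expect_gte(hits / 50, 0.95)
})

test_that("final-pair M equals their pairwise variation", {
  set.seed(13)
  ct <- randomCtMatrix(L = 6, n = 12)
  rq <- relativeQuantities(ct)
  gn <- geNorm(rq)
  pair <- tail(removalOrder(gn), 2)
  expect_equal(gn@M_final[[pair[1]]],
               sd(log2(rq@Q[pair[1], ] / rq@Q[pair[2], ])),
               tolerance = 1e-12)
})

test_that("pairwise variation selects the optimal gene count", {
  # near-identical genes: V well below the 0.15 cutoff, two suffice
  set.seed(21)
  base <- c(18, 20, 22, 24, 26)
  m <- outer(base, rep(1, 24)) + outer(rep(1, 5), rnorm(24, 0, 0.5)) +
    matrix(rnorm(5 * 24, 0, 0.05), 5, 24)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:24))
  rq <- relativeQuantities(ctFromMatrix(m))
  vc <- pairwiseVariation(rq, geNorm(rq))
  expect_lt(vc@V[["2"]], 0.15)
  expect_equal(optimalN(vc), 2L)
  expect_true(vc@converged)

  # very noisy independent genes: nothing passes, fall back to all L
  noisy <- matrix(rnorm(5 * 24, 22, 2), 5, 24,
                  dimnames = dimnames(m))
  rqN <- relativeQuantities(ctFromMatrix(noisy))
  expect_warning(vcN <- pairwiseVariation(rqN, geNorm(rqN)),
                 "cutoff")
  expect_equal(optimalN(vcN), 5L)
  expect_false(vcN@converged)

  # strict vs inclusive comparison at an exactly attained cutoff
  v2 <- vc@V[["2"]]
  inclusive <- pairwiseVariation(rq, geNorm(rq), cutoff = v2,
                                 cutoffInclusive = TRUE)
  expect_equal(optimalN(inclusive), 2L)
  strict <- pairwiseVariation(rq, geNorm(rq), cutoff = v2)
  expect_gt(optimalN(strict), 2L)
})

test_that("noise-free data give an all-zero V curve", {
  m <- outer(c(18, 20, 22, 24), rep(1, 6)) +
    outer(rep(1, 4), seq(0, 2.5, by = 0.5))
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:6))
  rq <- relativeQuantities(ctFromMatrix(m))
  vc <- pairwiseVariation(rq, geNorm(rq))
  expect_equal(unname(vc@V), c(0, 0), tolerance = 1e-12)
  expect_equal(optimalN(vc), 2L)
})

test_that("suitability thresholds follow the panel homogeneity", {
  M <- c(a = 0.509, b = 0.916, c = 0)
  het <- flagSuitability(M, homogeneous = FALSE)
  expect_true(het[["a"]])        # 0.509 accepted under M < 1.5
  expect_true(het[["b"]])
  hom <- flagSuitability(M, homogeneous = TRUE)
  expect_false(hom[["b"]])       # 0.916 fails M < 0.5
  expect_true(hom[["c"]])
  expect_equal(attr(hom, "threshold"), 0.5)
})

test_that("two-gene panels fall back to plain M values with a warning", {
  m <- matrix(c(20, 21, 22, 20.5, 21.4, 22.6), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  rq <- relativeQuantities(ctFromMatrix(m))
  expect_warning(gn <- geNorm(rq), "exclusion")
  expect_equal(gn@M_final, mValues(rq))
})
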