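test_that("the discrete grid is exactly .0025 + (i-1)*.005 and normalized", {
  s <- wilcoxonStats(c(5, 7, 9), c(1, 2, 3))
  p <- wilcoxonSmallPosterior(s, samples = 500, seed = 1)
  expect_identical(gridValues(p), .0025 + (0:199) * .005)
  expect_lt(abs(sum(gridProbs(p)) - 1), 1e-12)
  expect_true(all(gridProbs(p) >= 0))
  expect_equal(p@methodUsed, "small")
})

test_that("small-sample Wilcoxon posterior matches exact sign-enumeration", {
  # exact likelihood by dynamic programming over all 2^n sign assignments
  cases <- list(c(n = 3, t = 6), c(n = 9, t = 32), c(n = 12, t = 50),
                c(n = 9, t = 13))
  for (cs in cases) {
    s <- new("WilcoxonStats", tPlus = cs[["t"]],
             tMinus = cs[["n"]] * (cs[["n"]] + 1) / 2 - cs[["t"]],
             nBlocks = as.integer(cs[["n"]]))
    got <- wilcoxonSmallPosterior(s, samples = 1e5, seed = 17)
    exact <- exactWilcoxonGridPosterior(cs[["t"]], cs[["n"]])
    expect_lt(tvDist(gridProbs(got), exact), 0.01)
    expect_equal(got@postProbGtHalf,
                 sum(exact[gridValues(got) > 0.5]), tolerance = 0.01)
  }
})

test_that("Wilcoxon posterior is mirrored when T+ and T- swap", {
  a <- wilcoxonSmallPosterior(new("WilcoxonStats", tPlus = 32, tMinus = 13,
                                  nBlocks = 9L), samples = 3e4, seed = 5)
  b <- wilcoxonSmallPosterior(new("WilcoxonStats", tPlus = 13, tMinus = 32,
                                  nBlocks = 9L), samples = 3e4, seed = 6)
  expect_equal(a@postMean + b@postMean, 1, tolerance = 0.02)
  expect_equal(a@postProbGtHalf, 1 - b@postProbGtHalf, tolerance = 0.03)
  # exact mirror under the enumeration oracle
  ex <- exactWilcoxonGridPosterior(32, 9)
  exm <- exactWilcoxonGridPosterior(13, 9)
  expect_equal(ex, rev(exm), tolerance = 1e-12)
})

test_that("a balanced statistic with a symmetric prior centers on one half", {
  s <- new("WilcoxonStats", tPlus = 14, tMinus = 14, nBlocks = 7L)
  p <- wilcoxonSmallPosterior(s, samples = 3e4, seed = 8)
  expect_equal(p@postProbGtHalf, 0.5, tolerance = 0.03)
  m <- new("MannWhitneyStats", uE = 8, uC = 8, nE = 4L, nC = 4L)
  pm <- mannWhitneySmallPosterior(m, samples = 3e4, seed = 9)
  expect_equal(pm@postProbGtHalf, 0.5, tolerance = 0.03)
})

test_that("single-comparison Mann-Whitney posterior has the closed form", {
  # nE = nC = 1 and U_E = 1: likelihood P(U_E = 1 | Omega) = Omega exactly
  s <- new("MannWhitneyStats", uE = 1, uC = 0, nE = 1L, nC = 1L)
  p <- mannWhitneySmallPosterior(s, samples = 1e5, seed = 4)
  g <- gridValues(p)
  expect_lt(tvDist(gridProbs(p), g / sum(g)), 0.01)
})

test_that("Mann-Whitney posterior mirrors under group exchange", {
  a <- mannWhitneySmallPosterior(new("MannWhitneyStats", uE = 16, uC = 4,
                                     nE = 5L, nC = 4L),
                                 samples = 3e4, seed = 2)
  b <- mannWhitneySmallPosterior(new("MannWhitneyStats", uE = 4, uC = 16,
                                     nE = 4L, nC = 5L),
                                 samples = 3e4, seed = 3)
  expect_equal(a@postMean + b@postMean, 1, tolerance = 0.02)
  expect_equal(a@postProbGtHalf + b@postProbGtHalf, 1, tolerance = 0.03)
})

test_that("small-sample runs are reproducible and leave the RNG untouched", {
  s <- wilcoxonStats(c(5, 7, 9, 8), c(1, 2, 12, 3))
  a <- wilcoxonSmallPosterior(s, samples = 2000, seed = 77)
  b <- wilcoxonSmallPosterior(s, samples = 2000, seed = 77)
  expect_identical(gridProbs(a), gridProbs(b))
  set.seed(55)
  before <- .Random.seed
  invisible(wilcoxonSmallPosterior(s, samples = 500, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("an unreachable observed statistic raises an informative error", {
  s <- new("WilcoxonStats", tPlus = 50, tMinus = 0, nBlocks = 3L)
  expect_error(wilcoxonSmallPosterior(s, samples = 500, seed = 1),
               "never reproduced")
})

test_that("the beta approximation tracks the discrete posterior", {
  # balanced statistic: fitted beta centered at .5
  s <- new("WilcoxonStats", tPlus = 105, tMinus = 105, nBlocks = 20L)
  p <- rankLargePosterior(s)
  expect_equal(p@postMean, 0.5, tolerance = 0.005)
  expect_equal(p@methodUsed, "large")
  # quantile agreement with the small-sample algorithm at n = 20
  s2 <- new("WilcoxonStats", tPlus = 150, tMinus = 60, nBlocks = 20L)
  small <- wilcoxonSmallPosterior(s2, samples = 1e5, seed = 12)
  large <- rankLargePosterior(s2)
  fit <- large@betaApprox
  for (q in c(0.025, 0.5, 0.975)) {
    qSmall <- dfbayes:::.discreteQuantile(gridValues(small), gridProbs(small), q)
    expect_lt(abs(qbeta(q, shapeA(fit), shapeB(fit)) - qSmall), 0.02)
  }
  # Mann-Whitney branch: calibrated variance keeps the two methods close
  m <- new("MannWhitneyStats", uE = 16, uC = 4, nE = 5L, nC = 4L)
  smallM <- mannWhitneySmallPosterior(m, samples = 5e4, seed = 13)
  largeM <- rankLargePosterior(m)
  expect_equal(largeM@postMean, smallM@postMean, tolerance = 0.03)
  expect_equal(largeM@postProbGtHalf, smallM@postProbGtHalf, tolerance = 0.04)
})

test_that("posterior means recover the generating dominance parameter", {
  # data drawn with known Omega via the exponential construction; the
  # posterior mean should sit within 3 posterior SDs of truth nearly always
  set.seed(2024)
  misses <- 0L
  reps <- 150L
  for (r in seq_len(reps)) {
    omega <- sample(c(0.2, 0.5, 0.8), 1)
    e <- rexp(25, rate = 1 - omega)
    c_ <- rexp(25, rate = omega)
    p <- mannWhitneyTest(e, c_)   # harmonic mean 25 -> beta approximation
    fit <- p@betaApprox
    sd <- sqrt(shapeA(fit) * shapeB(fit) /
                 ((shapeA(fit) + shapeB(fit))^2 * (shapeA(fit) + shapeB(fit) + 1)))
    if (abs(p@postMean - omega) > 3 * sd) misses <- misses + 1L
  }
  expect_lte(misses / reps, 0.05)
})

test_that("automatic method selection follows the stated thresholds", {
  set.seed(9)
  y1 <- rnorm(26) + 2; y2 <- rnorm(26)
  expect_equal(wilcoxonTest(y1, y2)@methodUsed, "large")          # n = 26 > 24
  p <- wilcoxonTest(y1[1:10], y2[1:10], samples = 2000, seed = 1)
  expect_equal(p@methodUsed, "small")                             # n <= 24
  expect_equal(mannWhitneyTest(rnorm(30) + 2, rnorm(30))@methodUsed, "large")
  pm <- mannWhitneyTest(rnorm(8) + 3, rnorm(8), samples = 1000, seed = 2)
  expect_equal(pm@methodUsed, "small")  # harmonic mean 8 <= 19
  # explicit override wins
  expect_equal(wilcoxonTest(y1, y2, method = "small", samples = 500,
                            seed = 3)@methodUsed, "small")
})
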