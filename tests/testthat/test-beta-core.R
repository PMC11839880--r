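test_that("beta descriptives match closed forms and symmetry", {
  u <- betaDescriptive(betaParams(1, 1))
  expect_equal(u@mean, 0.5)
  expect_equal(u@median, 0.5)
  expect_equal(u@variance, 1 / 12)
  expect_equal(u@eqtailInterval, c(0.025, 0.975))
  expect_true(is.na(u@mode))       # flat density, no interior mode
  expect_true(anyNA(u@hdiInterval))  # both shapes at 1: HDI undefined

  s <- betaDescriptive(betaParams(20, 10))
  expect_equal(s@mean, 2 / 3)
  expect_equal(s@mode, 19 / 28)
  expect_equal(s@variance, 200 / (900 * 31))
  expect_equal(s@median, qbeta(0.5, 20, 10))
})

test_that("interval estimates carry the stated mass and bracket the median", {
  for (shapes in list(c(3, 7), c(20, 10), c(2, 15), c(5.5, 1.2))) {
    s <- betaDescriptive(betaParams(shapes[1], shapes[2]), 0.95)
    et <- s@eqtailInterval
    expect_equal(pbeta(et[2], shapes[1], shapes[2]) -
                   pbeta(et[1], shapes[1], shapes[2]), 0.95,
                 tolerance = 1e-6)
    hd <- s@hdiInterval
    expect_equal(pbeta(hd[2], shapes[1], shapes[2]) -
                   pbeta(hd[1], shapes[1], shapes[2]), 0.95,
                 tolerance = 1e-6)
    if (all(shapes > 1)) {
      # HDI no wider than equal-tail, both contain the median
      expect_lte(hd[2] - hd[1], et[2] - et[1] + 1e-10)
      expect_true(hd[1] <= s@median && s@median <= hd[2])
      expect_true(et[1] <= s@median && s@median <= et[2])
    }
  }
})

test_that("HDI agrees with a dense grid-search oracle", {
  for (shapes in list(c(2, 15), c(20, 10), c(3.5, 2.2))) {
    got <- betaDescriptive(betaParams(shapes[1], shapes[2]))@hdiInterval
    oracle <- gridHDIOracle(shapes[1], shapes[2])
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("one-sided and undefined HDI cases follow the density shape", {
  # a <= 1 < b: density decreasing, HDI anchored at 0
  s <- betaDescriptive(betaParams(1, 5))
  expect_equal(s@hdiInterval, c(0, qbeta(0.95, 1, 5)))
  # b <= 1 < a: increasing, anchored at 1
  s <- betaDescriptive(betaParams(5, 0.8))
  expect_equal(s@hdiInterval, c(qbeta(0.05, 5, 0.8), 1))
  # both <= 1: U-shaped, undefined
  expect_true(anyNA(betaDescriptive(betaParams(0.5, 0.5))@hdiInterval))
})

test_that("shape and probability validation rejects bad input", {
  expect_error(betaParams(0, 1), "positive")
  expect_error(betaParams(2, -3), "positive")
  expect_error(betaDescriptive(betaParams(2, 2), probInterval = 1), "inside")
  expect_error(binomialPosterior(-1, 2), "non-negative integer")
  expect_error(binomialPosterior(1.5, 2), "non-negative integer")
})

test_that("conjugate updating adds counts to the prior shapes", {
  p <- binomialPosterior(16, 2)
  expect_equal(c(shapeA(p), shapeB(p)), c(17, 3))
  p <- binomialPosterior(2, 21)
  expect_equal(c(shapeA(p), shapeB(p)), c(3, 22))
  pr <- betaParams(3.5, 0.5)
  p <- binomialPosterior(0, 0, pr)
  expect_equal(c(shapeA(p), shapeB(p)), c(3.5, 0.5))
})

test_that("interval Bayes factor reproduces the knot-tying analysis", {
  post <- binomialPosterior(16, 2)
  bf <- betaBayesFactor(post, method = "interval", h0 = c(0, 0.5))
  expect_equal(bf@postH0, 0.000364, tolerance = 2e-3)
  expect_equal(bf@bf10, 2743.963, tolerance = 1e-4)
  expect_equal(bf@bf10 * bf@bf01, 1, tolerance = 1e-12)
  expect_equal(bf@priorH0 + bf@priorH1, 1, tolerance = 1e-12)
  expect_equal(bf@postH0 + bf@postH1, 1, tolerance = 1e-12)
  # no data: odds unchanged
  null <- betaBayesFactor(betaParams(1, 1), method = "interval", h0 = c(0, 0.5))
  expect_equal(null@bf10, 1)
})

test_that("point Bayes factor is the Savage-Dickey density ratio", {
  post <- binomialPosterior(16, 2)
  bf <- betaBayesFactor(post, method = "point", h0 = 0.5)
  expect_equal(bf@bf01, 2907 * 2^-18)
  expect_equal(bf@bf10, 2^18 / 2907)
  expect_equal(bf@bf10, 90.18, tolerance = 1e-4)
})

test_that("interval masses agree with numeric integration of the prior times likelihood", {
  # conjugacy check: posterior mass from pbeta vs a 1e6-point Riemann sum
  a0 <- 2; b0 <- 3; n1 <- 5; n2 <- 4
  grid <- (seq_len(1e6) - 0.5) / 1e6
  w <- dbeta(grid, a0, b0) * grid^n1 * (1 - grid)^n2
  w <- w / sum(w)
  post <- binomialPosterior(n1, n2, betaParams(a0, b0))
  for (cut in c(0.3, 0.5, 0.62)) {
    expect_equal(sum(w[grid <= cut]), pbeta(cut, shapeA(post), shapeB(post)),
                 tolerance = 1e-6)
  }
})

test_that("mirrored data and hypotheses give identical Bayes factors", {
  for (counts in list(c(16, 2), c(3, 9), c(7, 7))) {
    bfA <- betaBayesFactor(binomialPosterior(counts[1], counts[2]),
                           method = "interval", h0 = c(0, 0.5))
    bfB <- betaBayesFactor(binomialPosterior(counts[2], counts[1]),
                           method = "interval", h0 = c(0.5, 1))
    expect_equal(bfA@bf10, bfB@bf10, tolerance = 1e-10)
  }
})

test_that("degenerate hypotheses are rejected and underflow yields Inf", {
  post <- binomialPosterior(5, 5)
  expect_error(betaBayesFactor(post, method = "interval", h0 = c(0.5, 0.5)),
               "absurd interval")
  expect_error(betaBayesFactor(post, method = "interval", h0 = c(0.7, 0.2)),
               "absurd interval")
  expect_error(betaBayesFactor(post, method = "interval", h0 = 0.5),
               "c\\(L, U\\)")
  expect_error(betaBayesFactor(post, method = "point", h0 = c(0.2, 0.5)),
               "single")
  big <- betaBayesFactor(betaParams(2000, 1), method = "interval",
                         h0 = c(0, 1e-12))
  expect_identical(big@bf10, Inf)
  expect_identical(big@bf01, 0)
})
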