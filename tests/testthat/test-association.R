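test_that("pair counts reproduce the two five-point worked examples", {
  x <- c(-5.6, -0.5, 2.1, 3.6, 4.1)
  y <- c(1.5, 4.7, 1.1, 6.2, 5.9)
  pc <- concordanceCounts(x, y)
  expect_equal(pc@nC, 7)
  expect_equal(pc@nD, 3)
  expect_equal(c(pc@tX, pc@tY, pc@tXY), c(0, 0, 0))
  expect_equal(tauA(pc), 0.4)

  x2 <- c(-5.6, 1.3, 1.3, 3.9, 3.9)
  y2 <- c(1.5, 4.7, 1.1, 6.1, 6.1)
  pc2 <- concordanceCounts(x2, y2)
  expect_equal(c(pc2@tX, pc2@tY, pc2@tXY), c(2, 1, 1))
  expect_equal(pc2@nC + pc2@nD, 8)   # 10 - 2 - 1 + 1
  expect_equal(tauA(pc2), 0.75)
})

test_that("tau-A is exact on the boundary and rejects fully tied data", {
  pc <- concordanceCounts(1:6, (1:6)^2)
  expect_equal(pc@nC, 15)
  expect_equal(tauA(pc), 1)
  expect_equal(tauA(concordanceCounts(1:5, 5:1)), -1)
  expect_error(tauA(concordanceCounts(rep(1, 4), rep(2, 4))),
               "no comparable pairs")
  # the fully-concordant ten-point configuration with ties from the
  # classic rank-correlation textbook: tau-A is 1, tau-B (flawed) is not
  nC <- 33; nD <- 0; tX <- 9; tY <- 4; tXY <- 1; n <- 10
  expect_equal(nC + nD, n * (n - 1) / 2 - tX - tY + tXY)
  pc2 <- new("PairCounts", nC = nC, nD = nD, tX = tX, tY = tY, tXY = tXY,
             nPoints = as.integer(n))
  expect_equal(tauA(pc2), 1)
  tauB <- (nC - nD) / (sqrt(n * (n - 1) / 2 - tX) * sqrt(n * (n - 1) / 2 - tY))
  expect_equal(tauB, 0.85896, tolerance = 1e-5)  # the documented bias
})

test_that("the tie-corrected comparison identity holds on fuzzed data", {
  set.seed(404)
  for (r in 1:300) {
    n <- sample(3:12, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties by construction
    y <- sample(1:4, n, replace = TRUE)
    pc <- concordanceCounts(x, y)         # validity enforces the identity
    bf <- bruteForcePairCounts(x, y)
    expect_equal(pc@nC, as.numeric(bf["nc"]))
    expect_equal(pc@nD, as.numeric(bf["nd"]))
    expect_equal(pc@nC + pc@nD,
                 n * (n - 1) / 2 - pc@tX - pc@tY + pc@tXY)
  }
})

test_that("raw values and ranks yield identical pair counts", {
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40)
  a <- concordanceCounts(x, y)
  b <- concordanceCounts(rank(x), rank(y))
  expect_equal(a@nC, b@nC)
  expect_equal(a@nD, b@nD)
})

test_that("concordance posterior updates phi_c and maps tau intervals", {
  set.seed(12)
  x <- rnorm(20); y <- x + rnorm(20, sd = 2)
  r <- bivariateConcordance(x, y)
  pc <- r@counts
  expect_equal(shapeA(posteriorParams(r)), 1 + pc@nC)
  expect_equal(shapeB(posteriorParams(r)), 1 + pc@nD)
  expect_equal(r@tauEqtailInterval, 2 * r@summary@eqtailInterval - 1)
  expect_equal(r@tauA, 2 * pc@nC / (pc@nC + pc@nD) - 1)
})

test_that("posterior tau median approaches the sample tau at large N", {
  set.seed(90)
  x <- rnorm(500)
  y <- x + rnorm(500, sd = 1.5)
  r <- bivariateConcordance(x, y)
  tauMedian <- 2 * r@summary@median - 1
  expect_lt(abs(tauMedian - r@tauA), 0.02)
})

test_that("goodness-of-fit adjustment penalizes the concordant count only", {
  set.seed(5)
  xs <- rnorm(12); ys <- xs + rnorm(12, sd = .4)
  r <- bivariateConcordance(xs, ys, fittingParameters = 2)
  pc <- r@counts
  expect_equal(r@nCStar, pc@nC - 12 * 2 + 3)
  expect_equal(shapeA(r@adjustedPosterior), 1 + r@nCStar)
  expect_equal(shapeB(r@adjustedPosterior), 1 + pc@nD)  # nD unadjusted
  expect_error(bivariateConcordance(xs, ys, fittingParameters = 11),
               "over-parameterized")
  # plain association leaves the adjusted record absent
  r0 <- bivariateConcordance(xs, ys)
  expect_true(is.na(r0@nCStar))
  expect_null(r0@adjustedPosterior)
})

test_that("gamma counts equal concordance counts on the expanded table", {
  t22 <- matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE)
  g <- gammaTable(t22)
  expect_equal(g@nS, 4)
  expect_equal(g@nD, 0)
  expect_equal(g@gammaStat, 1)
  g2 <- gammaTable(matrix(1, 2, 2))
  expect_equal(c(g2@nS, g2@nD), c(1, 1))
  expect_equal(g2@gammaStat, 0)

  # worked 3 x 4 table: quadruple sums vs pair expansion of 158 points
  m <- gammaExampleTable()
  expect_equal(rowSums(m), c(47, 49, 62))
  expect_equal(sum(m), 158)
  g3 <- gammaTable(m)
  ex <- expandTable(m)
  pc <- concordanceCounts(ex$x, ex$y)
  expect_equal(g3@nS, pc@nC)
  expect_equal(g3@nD, pc@nD)
  expect_equal(g3@gammaStat, tauA(pc))
  expect_equal(shapeA(posteriorParams(g3)), 1 + g3@nS)
})

test_that("gamma-concordance equivalence holds for random tables", {
  set.seed(73)
  for (r in 1:20) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- matrix(rpois(nr * nc, 3), nr, nc)
    if (sum(m) < 2 || all(rowSums(m) == 0) ) next
    g <- tryCatch(gammaTable(m), error = function(e) NULL)
    if (is.null(g)) next   # degenerate one-row/one-column mass
    ex <- expandTable(m)
    pc <- concordanceCounts(ex$x, ex$y)
    expect_equal(g@nS, pc@nC)
    expect_equal(g@nD, pc@nD)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(gammaTable(matrix(c(1, 2), 1, 2)), "at least 2 x 2")
  expect_error(gammaTable(matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE)),
               "one row or one column")
  expect_error(gammaTable(matrix(c(1, -1, 2, 3), 2, 2)), "non-negative")
})
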