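# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the Wilcoxon likelihood is computed by exact
# dynamic-programming enumeration rather than Monte Carlo, and the HDI
# oracle is a dense grid search rather than width minimization.

# exact P(T+ = t | phi) for ranks 1..n, all 2^n sign assignments, via
# convolution: T+ gains rank r with probability phi, 0 otherwise
exactTplusPmf <- function(n, phi) {
  pmf <- 1  # distribution of T+ over support 0:0
  for (r in seq_len(n)) {
    upper <- length(pmf) - 1L
    new <- numeric(upper + r + 1L)
    new[seq_len(upper + 1L)] <- pmf * (1 - phi)
    new[seq_len(upper + 1L) + r] <- new[seq_len(upper + 1L) + r] + pmf * phi
    pmf <- new
  }
  pmf  # index t+1 holds P(T+ = t)
}

# exact grid posterior for phi_w given observed T+ (uniform-density prior
# weights on the same 200-point grid as the package)
exactWilcoxonGridPosterior <- function(tPlus, n, a0 = 1, b0 = 1) {
  grid <- .0025 + (0:199) * .005
  lik <- vapply(grid, function(phi) exactTplusPmf(n, phi)[tPlus + 1L],
                numeric(1))
  w <- dbeta(grid, a0, b0)
  post <- lik * w
  post / sum(post)
}

# dense-grid HDI search: minimize width over lower-tail mass, step 1e-5
gridHDIOracle <- function(a, b, p = 0.95) {
  lowerMass <- seq(0, 1 - p, by = 1e-5)
  lo <- qbeta(lowerMass, a, b)
  hi <- qbeta(lowerMass + p, a, b)
  i <- which.min(hi - lo)
  c(lo[i], hi[i])
}

# total variation distance between two probability vectors
tvDist <- function(p, q) sum(abs(p - q)) / 2

# the ten paired observations used throughout for the signed-rank example
# (one block has a zero difference and is dropped)
signedRankExample <- function() {
  list(y1 = c(77.9, 89.2, 78.2, 50.0, 94.5, 73.1, 77.5, 70.6, 89.4, 77.6),
       y2 = c(77.2, 66.0, 69.2, 58.2, 74.0, 88.3, 77.5, 74.6, 78.4, 72.2))
}

# brute-force concordant/discordant classification over index pairs,
# written independently of the package's vectorized kernel
bruteForcePairCounts <- function(x, y) {
  n <- length(x)
  nc <- nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1L
      if (s < 0) nd <- nd + 1L
    }
  }
  c(nc = nc, nd = nd)
}

# expand an ordered contingency table into the bivariate rank point set
expandTable <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  list(x = rep(idx[, 1], m[m > 0]), y = rep(idx[, 2], m[m > 0]))
}

# 3 x 4 ordered contingency table used in the worked gamma example
gammaExampleTable <- function() {
  matrix(c(38, 4, 5, 0,
           6, 40, 1, 2,
           4, 8, 20, 30), nrow = 3, byrow = TRUE)
}
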