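# Discrete-grid and beta-approximation posteriors for the Wilcoxon
# sign-bias parameter phi_w and the Mann-Whitney dominance parameter
# Omega_E. Both parameters live on [0, 1]; the small-sample algorithm
# estimates the likelihood of the observed statistic at 200 candidate
# values (.0025 to .9975 in steps of .005) by Monte Carlo simulation and
# applies Bayes' rule on that grid.

# prior weights on the grid: the beta density evaluated at the grid points,
# normalized over the grid (the O(step^2) difference from bin integration
# is negligible at step .005)
.gridPrior <- function(prior) {
  g <- .phiGrid()
  w <- stats::dbeta(g, prior@a, prior@b)
  w / sum(w)
}

.rankPosteriorFromGrid <- function(statistic, stats, prior, lik, probInterval,
                                   samples, seed, methodName) {
  g <- .phiGrid()
  priorW <- .gridPrior(prior)
  num <- lik * priorW
  if (sum(num) <= 0)
    stop(paste("the observed statistic was never reproduced at any grid",
               "value (degenerate likelihood, e.g. heavy ties after",
               "rounding); consider method = \"large\""), call. = FALSE)
  probs <- num / sum(num)
  alpha <- (1 - probInterval) / 2
  postH1 <- sum(probs[g > 0.5])
  priorH1 <- sum(priorW[g > 0.5])
  new("RankPosterior",
      statistic = statistic, methodUsed = methodName, stats = stats,
      prior = prior,
      discrete = new("DiscretePosterior", grid = g, probs = probs),
      betaApprox = NULL,
      postMean = sum(g * probs),
      postProbGtHalf = postH1,
      priorProbGtHalf = priorH1,
      eqtailInterval = .discreteQuantile(g, probs, c(alpha, 1 - alpha)),
      bf10 = .oddsBF(postH1, 1 - postH1, priorH1, 1 - priorH1),
      probInterval = probInterval,
      samplesPerGridPoint = as.numeric(samples),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Small-sample discrete posterior for the Wilcoxon sign-bias parameter
#'
#' For each of the 200 candidate values \code{phi} the ranks 1..n are given
#' independent positive signs with probability \code{phi}; the proportion of
#' Monte Carlo replicates whose simulated \code{T+} equals the observed
#' \code{T+} estimates the likelihood at that candidate. Multiplying by the
#' grid prior and renormalizing yields the discrete posterior for
#' \code{phi_w}.
#'
#' Midranks can make an observed \code{T+} non-integer; it is rounded to
#' the nearest integer before matching, since the simulated statistic has
#' integer support.
#'
#' @param stats a [WilcoxonStats-class] object.
#' @param prior beta prior on \code{phi_w} (default uniform).
#' @param probInterval interval mass (default .95).
#' @param samples Monte Carlo replicates per grid point (default 30000).
#' @param seed optional integer seed (caller's RNG state is restored).
#' @param quiet suppress progress messages (default TRUE).
#' @return A [RankPosterior-class] with a [DiscretePosterior-class].
#' @examples
#' s <- wilcoxonStats(c(5, 7, 9, 8), c(1, 2, 12, 3))
#' wilcoxonSmallPosterior(s, samples = 2000, seed = 1)
#' @export
wilcoxonSmallPosterior <- function(stats, prior = betaParams(1, 1),
                                   probInterval = 0.95, samples = 30000,
                                   seed = NULL, quiet = TRUE) {
  stopifnot(is(stats, "WilcoxonStats"))
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  samples <- as.integer(samples)
  if (samples < 1L) stop("'samples' must be positive", call. = FALSE)
  n <- stats@nBlocks
  tObs <- round(stats@tPlus)
  g <- .phiGrid()
  ranks <- seq_len(n)
  lik <- .withSeed(seed, {
    out <- numeric(200)
    for (i in seq_len(200)) {
      signs <- matrix(stats::runif(n * samples) < g[i], nrow = n)
      tSim <- drop(crossprod(signs, ranks))
      out[i] <- mean(tSim == tObs)
      if (i %% 50L == 0L)
        .progress(quiet, "wilcoxon small-n grid: %d%% complete", i %/% 2L)
    }
    out
  })
  .rankPosteriorFromGrid("wilcoxon", stats, prior, lik, probInterval,
                         samples, seed, "small")
}

#' Small-sample discrete posterior for the Mann-Whitney Omega_E parameter
#'
#' For each candidate value \code{Omega} the likelihood of the observed
#' \code{U_E} is estimated by drawing \code{nE} experimental scores from an
#' exponential with rate \code{1 - Omega} and \code{nC} control scores from
#' an exponential with rate \code{Omega} — a pair of distributions whose
#' population dominance parameter is exactly \code{Omega}, which is all
#' that matters because \code{Omega_E} is distribution-free — and counting
#' the replicates whose simulated \code{U_E} matches \code{round(uE)}.
#'
#' @param stats a [MannWhitneyStats-class] object.
#' @inheritParams wilcoxonSmallPosterior
#' @return A [RankPosterior-class] with a [DiscretePosterior-class].
#' @examples
#' s <- mannWhitneyStats(c(2, 5, 7, 8, 9), c(1, 3, 4, 6))
#' mannWhitneySmallPosterior(s, samples = 1000, seed = 1)
#' @export
mannWhitneySmallPosterior <- function(stats, prior = betaParams(1, 1),
                                      probInterval = 0.95, samples = 30000,
                                      seed = NULL, quiet = TRUE) {
  stopifnot(is(stats, "MannWhitneyStats"))
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  samples <- as.integer(samples)
  if (samples < 1L) stop("'samples' must be positive", call. = FALSE)
  nE <- stats@nE; nC <- stats@nC
  uObs <- round(stats@uE)
  g <- .phiGrid()
  lik <- .withSeed(seed, {
    out <- numeric(200)
    for (i in seq_len(200)) {
      eDraw <- matrix(stats::rexp(nE * samples, rate = 1 - g[i]), nrow = nE)
      cDraw <- matrix(stats::rexp(nC * samples, rate = g[i]), nrow = nC)
      uSim <- integer(samples)
      for (a in seq_len(nE))
        for (b in seq_len(nC))
          uSim <- uSim + (eDraw[a, ] > cDraw[b, ])
      out[i] <- mean(uSim == uObs)
      if (i %% 50L == 0L)
        .progress(quiet, "mann-whitney small-n grid: %d%% complete", i %/% 2L)
    }
    out
  })
  .rankPosteriorFromGrid("mann_whitney", stats, prior, lik, probInterval,
                         samples, seed, "small")
}

#' Large-sample beta-approximation posterior for a rank-test parameter
#'
#' Builds a grid posterior from a normal approximation to the sampling
#' distribution of the observed statistic given the parameter, multiplies
#' by the prior on the 200-point grid, and fits a beta distribution to the
#' grid posterior by moment matching; all summaries then come from the
#' fitted beta. For the Wilcoxon statistic the approximation uses mean
#' \code{phi n(n+1)/2} and variance \code{phi(1-phi) n(n+1)(2n+1)/6}; for
#' the Mann-Whitney statistic the mean is \code{Omega nE nC} and the
#' variance is calibrated once per sample-size pair by a pilot run of the
#' exponential sampler at \code{Omega = .5}, scaled by
#' \code{Omega(1-Omega)/.25}.
#'
#' @param stats a [WilcoxonStats-class] or [MannWhitneyStats-class] object.
#' @param prior beta prior on the parameter (default uniform).
#' @param probInterval interval mass (default .95).
#' @param pilotSamples draws for the Mann-Whitney variance pilot
#'   (default 10000).
#' @param seed seed for the pilot draw (default 1; the Wilcoxon branch is
#'   deterministic and ignores it).
#' @return A [RankPosterior-class] with a fitted beta posterior.
#' @examples
#' s <- wilcoxonStats(1:30, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 1:20 * 0))
#' rankLargePosterior(s)
#' @export
rankLargePosterior <- function(stats, prior = betaParams(1, 1),
                               probInterval = 0.95, pilotSamples = 10000,
                               seed = 1) {
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  g <- .phiGrid()
  if (is(stats, "WilcoxonStats")) {
    statistic <- "wilcoxon"
    n <- stats@nBlocks
    obs <- stats@tPlus
    m <- g * n * (n + 1) / 2
    v <- g * (1 - g) * n * (n + 1) * (2 * n + 1) / 6
  } else if (is(stats, "MannWhitneyStats")) {
    statistic <- "mann_whitney"
    nE <- stats@nE; nC <- stats@nC
    obs <- stats@uE
    m <- g * nE * nC
    v0 <- .withSeed(seed, .mwPilotVariance(nE, nC, pilotSamples))
    v <- v0 * g * (1 - g) / 0.25
  } else {
    stop("'stats' must be a WilcoxonStats or MannWhitneyStats object",
         call. = FALSE)
  }
  lik <- stats::dnorm(obs, mean = m, sd = sqrt(v))
  priorW <- .gridPrior(prior)
  probs <- lik * priorW
  probs <- probs / sum(probs)
  mu <- sum(g * probs)
  s2 <- sum(g^2 * probs) - mu^2
  k <- mu * (1 - mu) / s2 - 1
  if (!is.finite(k) || k <= 0)
    stop("grid posterior too dispersed for a beta fit", call. = FALSE)
  fit <- betaParams(mu * k, (1 - mu) * k)
  alpha <- (1 - probInterval) / 2
  postH1 <- 1 - stats::pbeta(0.5, fit@a, fit@b)
  priorH1 <- 1 - stats::pbeta(0.5, prior@a, prior@b)
  new("RankPosterior",
      statistic = statistic, methodUsed = "large", stats = stats,
      prior = prior, discrete = NULL, betaApprox = fit,
      postMean = fit@a / (fit@a + fit@b),
      postProbGtHalf = postH1,
      priorProbGtHalf = priorH1,
      eqtailInterval = stats::qbeta(c(alpha, 1 - alpha), fit@a, fit@b),
      bf10 = .oddsBF(postH1, 1 - postH1, priorH1, 1 - priorH1),
      probInterval = probInterval,
      samplesPerGridPoint = NA_real_,
      seed = as.numeric(seed))
}

# sampling variance of U_E under the exponential construction at Omega = .5
# (equal unit rates); cached per (nE, nC, pilotSamples)
.mwPilotCache <- new.env(parent = emptyenv())

.mwPilotVariance <- function(nE, nC, pilotSamples) {
  key <- sprintf("%d_%d_%d", nE, nC, as.integer(pilotSamples))
  if (!is.null(.mwPilotCache[[key]])) return(.mwPilotCache[[key]])
  eDraw <- matrix(stats::rexp(nE * pilotSamples, rate = 0.5), nrow = nE)
  cDraw <- matrix(stats::rexp(nC * pilotSamples, rate = 0.5), nrow = nC)
  u <- integer(pilotSamples)
  for (a in seq_len(nE))
    for (b in seq_len(nC))
      u <- u + (eDraw[a, ] > cDraw[b, ])
  v <- stats::var(u)
  .mwPilotCache[[key]] <- v
  v
}

.autoMethod <- function(stats) {
  if (is(stats, "WilcoxonStats")) {
    if (stats@nBlocks > 24L) "large" else "small"
  } else {
    h <- 2 / (1 / stats@nE + 1 / stats@nC)
    if (h > 19) "large" else "small"
  }
}

#' Bayesian Wilcoxon signed-rank analysis
#'
#' Computes the signed-rank statistics for paired data and the posterior
#' distribution of the sign-bias parameter \code{phi_w}, choosing between
#' the discrete small-sample algorithm (n <= 24) and the large-sample beta
#' approximation (n > 24) unless \code{method} overrides the choice.
#'
#' @param y1,y2 equal-length paired response vectors.
#' @param a0,b0 prior beta shapes for \code{phi_w} (default uniform).
#' @param probInterval interval mass (default .95).
#' @param samples Monte Carlo replicates per grid point for the small
#'   method (default 30000).
#' @param method \code{NULL} for automatic selection, or \code{"small"} /
#'   \code{"large"} to force an algorithm.
#' @param seed optional integer seed.
#' @param quiet suppress progress messages (default TRUE).
#' @return A [RankPosterior-class] object.
#' @examples
#' wilcoxonTest(c(5, 7, 9, 8, 6), c(1, 2, 12, 3, 2), samples = 2000, seed = 1)
#' @export
wilcoxonTest <- function(y1, y2, a0 = 1, b0 = 1, probInterval = 0.95,
                         samples = 30000, method = NULL, seed = NULL,
                         quiet = TRUE) {
  stats <- wilcoxonStats(y1, y2)
  prior <- betaParams(a0, b0)
  method <- .resolveMethod(method, stats)
  if (method == "small")
    wilcoxonSmallPosterior(stats, prior, probInterval, samples, seed, quiet)
  else
    rankLargePosterior(stats, prior, probInterval)
}

#' Bayesian Mann-Whitney analysis
#'
#' Computes the U statistics for two independent groups and the posterior
#' distribution of the stochastic-dominance parameter \code{Omega_E},
#' choosing the discrete small-sample algorithm when the harmonic mean of
#' the group sizes is at most 19 and the beta approximation otherwise,
#' unless \code{method} overrides the choice.
#'
#' @param e,c numeric response vectors for the two groups.
#' @inheritParams wilcoxonTest
#' @return A [RankPosterior-class] object.
#' @examples
#' mannWhitneyTest(c(2, 5, 7, 8, 9), c(1, 3, 4, 6), samples = 1000, seed = 1)
#' @export
mannWhitneyTest <- function(e, c, a0 = 1, b0 = 1, probInterval = 0.95,
                            samples = 30000, method = NULL, seed = NULL,
                            quiet = TRUE) {
  stats <- mannWhitneyStats(e, c)
  prior <- betaParams(a0, b0)
  method <- .resolveMethod(method, stats)
  if (method == "small")
    mannWhitneySmallPosterior(stats, prior, probInterval, samples, seed, quiet)
  else
    rankLargePosterior(stats, prior, probInterval)
}

.resolveMethod <- function(method, stats) {
  if (is.null(method)) return(.autoMethod(stats))
  match.arg(method, c("small", "large"))
}
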