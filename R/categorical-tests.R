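# McNemar, sign and median tests: Bernoulli-count reductions followed by
# conjugate beta updating from beta-core.

.betaTestCore <- function(test, n1, n2, prior, probInterval, baseRate,
                          h0Description, details) {
  posterior <- binomialPosterior(n1, n2, prior)
  postProbH1 <- 1 - stats::pbeta(baseRate, posterior@a, posterior@b)
  priorProbH1 <- 1 - stats::pbeta(baseRate, prior@a, prior@b)
  bf10 <- .oddsBF(postProbH1, 1 - postProbH1, priorProbH1, 1 - priorProbH1)
  new("BetaTestResult", test = test, prior = prior, posterior = posterior,
      summary = betaDescriptive(posterior, probInterval),
      postProbH1 = postProbH1, priorProbH1 = priorProbH1, bf10 = bf10,
      h0Description = h0Description, details = details)
}

#' Bayesian McNemar change test
#'
#' Inference about the population response-switching rate \code{phi_rb}
#' among the change cases of a paired binary design: \code{n01} blocks
#' switched 0 to 1 (improvement) and \code{n10} switched 1 to 0. Only the
#' off-diagonal (change) cells are informative; the posterior is
#' \code{Beta(a0 + n01, b0 + n10)} and the alternative hypothesis is
#' \code{phi_rb > .5} (more improvement than decline). The classical
#' McNemar chi-square \code{(n01 - n10)^2 / (n01 + n10)} (no continuity
#' correction) is included in the details purely as a descriptive reference.
#'
#' @param n01,n10 non-negative switch counts.
#' @param prior beta prior on \code{phi_rb} (default uniform).
#' @param probInterval interval mass (default .95).
#' @return A [BetaTestResult-class]; details carry \code{n01}, \code{n10}
#'   and \code{chi2}.
#' @examples
#' mcnemarTest(2, 21)
#' @export
mcnemarTest <- function(n01, n10, prior = betaParams(1, 1),
                        probInterval = 0.95) {
  n01 <- .checkCount(n01, "n01")
  n10 <- .checkCount(n10, "n10")
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  chi2 <- if (n01 + n10 > 0) (n01 - n10)^2 / (n01 + n10) else NA_real_
  .betaTestCore("mcnemar", n01, n10, prior, probInterval, baseRate = 0.5,
                h0Description = "phi_rb <= .5 (no net improvement)",
                details = list(n01 = n01, n10 = n10, chi2 = chi2))
}

#' Bayesian sign test for paired data
#'
#' Differences \code{d_i = y1_i - y2_i} are reduced to their signs; blocks
#' with exactly zero difference are dropped (and counted). The posterior for
#' the population proportion phi of positive differences is
#' \code{Beta(a0 + nPos, b0 + nNeg)}, with the alternative \code{phi > .5}.
#'
#' Zeros are detected by exact comparison; data on a floating-point scale
#' where near-zero differences arise from rounding should be rounded
#' explicitly by the caller first.
#'
#' @param y1,y2 equal-length paired response vectors (index-aligned by
#'   block).
#' @param prior beta prior on phi (default uniform).
#' @param probInterval interval mass (default .95).
#' @return A [BetaTestResult-class]; details carry \code{nPos}, \code{nNeg}
#'   and \code{nZeroDropped}.
#' @examples
#' signTest(c(3, 5, 2, 6, 4), c(1, 2, 3, 1, 2))
#' @export
signTest <- function(y1, y2, prior = betaParams(1, 1), probInterval = 0.95) {
  if (!is.numeric(y1) || !is.numeric(y2) || anyNA(y1) || anyNA(y2))
    stop("'y1' and 'y2' must be numeric with no missing values", call. = FALSE)
  if (length(y1) != length(y2))
    stop("'y1' and 'y2' must have the same length", call. = FALSE)
  if (length(y1) < 1L) stop("need at least one block", call. = FALSE)
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  d <- y1 - y2
  nZero <- sum(d == 0)
  nPos <- sum(d > 0)
  nNeg <- sum(d < 0)
  if (nPos + nNeg == 0)
    stop("no informative blocks: all differences are zero", call. = FALSE)
  .betaTestCore("sign", nPos, nNeg, prior, probInterval, baseRate = 0.5,
                h0Description = "phi <= .5 (positive differences not dominant)",
                details = list(nPos = nPos, nNeg = nNeg, nZeroDropped = nZero))
}

#' Bayesian median test for two independent groups
#'
#' Pools the two groups, takes the combined median (midpoint of the two
#' central order statistics for an even pooled size), and counts the
#' observations from each group that fall strictly above it; scores at the
#' median count as at-or-below. With unequal group sizes the natural null is
#' not .5: under no group effect the probability that an above-median score
#' came from group E is the base rate \code{nE/(nE + nC)}. The posterior for
#' phi (the E-proportion among above-median scores) is
#' \code{Beta(a0 + aboveE, b0 + aboveC)} and the alternative is
#' \code{phi > nE/(nE + nC)}.
#'
#' @param e,c experimental and control response vectors (sizes may differ).
#' @param prior beta prior on phi (default uniform).
#' @param probInterval interval mass (default .95).
#' @return A [BetaTestResult-class]; details carry \code{combinedMedian},
#'   \code{aboveE}, \code{aboveC}, \code{nE}, \code{nC} and \code{baseRateE}.
#' @examples
#' medianTest(c(1, 2, 9), c(3, 8, 7, 10, 12, 11))
#' @export
medianTest <- function(e, c, prior = betaParams(1, 1), probInterval = 0.95) {
  if (!is.numeric(e) || !is.numeric(c) || anyNA(e) || anyNA(c))
    stop("'e' and 'c' must be numeric with no missing values", call. = FALSE)
  if (length(e) < 1L || length(c) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  prior <- .asBetaParams(prior)
  .checkProbInterval(probInterval)
  med <- stats::median(c(e, c))
  aboveE <- sum(e > med)
  aboveC <- sum(c > med)
  if (aboveE + aboveC == 0)
    stop("no observations above the combined median (degenerate data)",
         call. = FALSE)
  baseRate <- length(e) / (length(e) + length(c))
  .betaTestCore("median", aboveE, aboveC, prior, probInterval,
                baseRate = baseRate,
                h0Description = sprintf("phi <= %.6g (E base rate)", baseRate),
                details = list(combinedMedian = med, aboveE = aboveE,
                               aboveC = aboveC, nE = length(e),
                               nC = length(c), baseRateE = baseRate))
}
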