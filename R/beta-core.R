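#' Descriptive statistics for a beta distribution
#'
#' Computes the mean, median, mode, variance, equal-tail interval and
#' highest-density interval (HDI) of a beta distribution. The posterior of
#' every Bernoulli-type analysis in this package is a beta distribution, so
#' this summary doubles as the posterior report for those analyses.
#'
#' The median is the inverse regularized incomplete beta function at .5
#' (\code{qbeta}), not a sampled estimate. The mode \code{(a-1)/(a+b-2)} is
#' only defined when both shapes exceed 1; otherwise the density peaks on a
#' boundary and the mode is reported as \code{NA}. The HDI is found by
#' minimizing the interval width over the lower-tail mass using the quantile
#' function; when exactly one shape is at most 1 the density is monotone and
#' a one-sided interval \code{[0, q]} or \code{[q, 1]} is returned, and when
#' both shapes are at most 1 the density is U-shaped (or flat) and the HDI
#' is reported as \code{NA}.
#'
#' @param params a [BetaParams-class] object (or a length-2 numeric
#'   \code{c(a, b)}).
#' @param probInterval probability mass covered by the interval estimates
#'   (default .95).
#' @return A [BetaSummary-class] object.
#' @examples
#' betaDescriptive(betaParams(20, 10))
#' @export
betaDescriptive <- function(params, probInterval = 0.95) {
  params <- .asBetaParams(params)
  .checkProbInterval(probInterval)
  a <- params@a; b <- params@b
  alpha <- (1 - probInterval) / 2
  eqtail <- stats::qbeta(c(alpha, 1 - alpha), a, b)
  new("BetaSummary",
      params = params,
      mean = a / (a + b),
      median = stats::qbeta(0.5, a, b),
      mode = if (a > 1 && b > 1) (a - 1) / (a + b - 2) else NA_real_,
      variance = a * b / ((a + b)^2 * (a + b + 1)),
      eqtailInterval = eqtail,
      hdiInterval = .betaHDI(a, b, probInterval),
      probInterval = probInterval)
}

.asBetaParams <- function(x) {
  if (is(x, "BetaParams")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(betaParams(x[1], x[2]))
  stop("expected a BetaParams object or a numeric pair c(a, b)", call. = FALSE)
}

# narrowest interval holding mass p: width(alpha) = Q(alpha + p) - Q(alpha)
# is unimodal in the lower-tail mass alpha when both shapes exceed 1
.betaHDI <- function(a, b, p) {
  if (a <= 1 && b <= 1) return(c(NA_real_, NA_real_))
  if (a <= 1) return(c(0, stats::qbeta(p, a, b)))
  if (b <= 1) return(c(stats::qbeta(1 - p, a, b), 1))
  width <- function(alpha) stats::qbeta(alpha + p, a, b) - stats::qbeta(alpha, a, b)
  opt <- stats::optimize(width, interval = c(0, 1 - p), tol = 1e-10)
  stats::qbeta(c(opt$minimum, opt$minimum + p), a, b)
}

#' Conjugate beta update for Bernoulli counts
#'
#' A beta prior with shapes \code{(a0, b0)} observed together with \code{n1}
#' category-1 and \code{n2} category-2 outcomes yields the posterior beta
#' with shapes \code{(a0 + n1, b0 + n2)}. The binomial normalizing constant
#' cancels in Bayes' rule, so only the counts matter.
#'
#' @param n1,n2 non-negative integer counts for the two response categories.
#' @param prior a [BetaParams-class] prior (default uniform, \code{Beta(1,1)}).
#' @return The posterior [BetaParams-class].
#' @examples
#' binomialPosterior(16, 2)  # Beta(17, 3)
#' @export
binomialPosterior <- function(n1, n2, prior = betaParams(1, 1)) {
  n1 <- .checkCount(n1, "n1")
  n2 <- .checkCount(n2, "n2")
  prior <- .asBetaParams(prior)
  betaParams(prior@a + n1, prior@b + n2)
}

#' Bayes factor for hypotheses about a beta-distributed rate
#'
#' For \code{method = "interval"} the null is a sub-interval \code{[L, U]} of
#' \code{[0, 1]}; its prior and posterior probabilities are the beta masses
#' of the interval, and BF10 is the posterior odds of the alternative over
#' its prior odds. For \code{method = "point"} the null is a single value
#' and the Bayes factor is the Savage-Dickey density ratio: BF01 equals the
#' posterior density at the point divided by the prior density there.
#'
#' When a hypothesis probability underflows to zero the corresponding Bayes
#' factor is reported as \code{Inf} (and its reciprocal as 0).
#'
#' @param posterior,prior [BetaParams-class] objects.
#' @param method \code{"interval"} or \code{"point"}.
#' @param h0 the null hypothesis: \code{c(L, U)} with \code{0 <= L < U <= 1}
#'   for the interval method, a single value in (0, 1) for the point method.
#' @return A [BayesFactorResult-class] object.
#' @examples
#' betaBayesFactor(binomialPosterior(16, 2), method = "interval", h0 = c(0, .5))
#' @export
betaBayesFactor <- function(posterior, prior = betaParams(1, 1),
                            method = c("interval", "point"), h0) {
  posterior <- .asBetaParams(posterior)
  prior <- .asBetaParams(prior)
  method <- match.arg(method)
  if (method == "interval") {
    if (!is.numeric(h0) || length(h0) != 2L || anyNA(h0))
      stop("interval method requires h0 = c(L, U)", call. = FALSE)
    if (h0[1] < 0 || h0[2] > 1 || h0[1] >= h0[2])
      stop("absurd interval: need 0 <= L < U <= 1", call. = FALSE)
    priorH0 <- stats::pbeta(h0[2], prior@a, prior@b) -
      stats::pbeta(h0[1], prior@a, prior@b)
    postH0 <- stats::pbeta(h0[2], posterior@a, posterior@b) -
      stats::pbeta(h0[1], posterior@a, posterior@b)
    priorH1 <- 1 - priorH0
    postH1 <- 1 - postH0
    bf10 <- .oddsBF(postH1, postH0, priorH1, priorH0)
    bf01 <- .oddsBF(postH0, postH1, priorH0, priorH1)
    new("BayesFactorResult", bf10 = bf10, bf01 = bf01,
        priorH0 = priorH0, priorH1 = priorH1,
        postH0 = postH0, postH1 = postH1, method = method, h0 = h0)
  } else {
    if (!is.numeric(h0) || length(h0) != 1L || is.na(h0) || h0 <= 0 || h0 >= 1)
      stop("point method requires a single h0 value strictly inside (0, 1)",
           call. = FALSE)
    priorDens <- stats::dbeta(h0, prior@a, prior@b)
    postDens <- stats::dbeta(h0, posterior@a, posterior@b)
    if (priorDens <= 0)
      stop("prior density at the point null is zero; the Savage-Dickey ratio is undefined",
           call. = FALSE)
    bf01 <- postDens / priorDens
    bf10 <- if (bf01 == 0) Inf else 1 / bf01
    new("BayesFactorResult", bf10 = bf10, bf01 = bf01,
        priorH0 = NA_real_, priorH1 = NA_real_,
        postH0 = NA_real_, postH1 = NA_real_, method = method, h0 = h0)
  }
}
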