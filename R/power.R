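# Monte Carlo power comparison: Bayesian distribution-free rank tests
# versus the classical t test under nine data-generating models.

.simModels <- c("normal", "weibull", "cauchy", "lognormal", "chisquare",
                "logistic", "exponential", "gumbel", "pareto")

# one sample of size n from the named model with the given shape parameter.
# Parameterizations: normal sd = shape; weibull shape = shape, unit scale;
# cauchy scale = shape, location 0; lognormal sdlog = shape, meanlog 0;
# chisquare df = shape; logistic scale = shape, location 0; exponential
# rate = shape; gumbel scale = shape, location 0 (inverse CDF); pareto
# minimum 1, tail index = shape (inverse CDF).
.drawModel <- function(model, n, shape) {
  switch(model,
    normal = stats::rnorm(n, 0, shape),
    weibull = stats::rweibull(n, shape = shape, scale = 1),
    cauchy = stats::rcauchy(n, 0, shape),
    lognormal = stats::rlnorm(n, 0, shape),
    chisquare = stats::rchisq(n, df = shape),
    logistic = stats::rlogis(n, 0, shape),
    exponential = stats::rexp(n, rate = shape),
    gumbel = -shape * log(-log(stats::runif(n))),
    pareto = stats::runif(n)^(-1 / shape),
    stop(sprintf("unknown model '%s'; must be one of %s", model,
                 paste(.simModels, collapse = ", ")), call. = FALSE))
}

#' Simulate one two-condition data set and analyse it both ways
#'
#' Draws a control sample from \code{model(shape1)} and an experimental
#' sample from \code{model(shape2)} shifted by \code{+delta} (a pure
#' location offset for every model), optionally adds block effects, and
#' analyses the data with the Bayesian rank test appropriate to the design
#' (Wilcoxon for paired, Mann-Whitney for independent) and with the
#' classical t test (paired, or pooled-variance two-sample). The t test is
#' one-sided (experimental greater), matching the one-sided Bayesian
#' detection criterion P(parameter > .5) >= effectCrit, so the two power
#' estimates answer the same directional question at matched error rates.
#'
#' Block effects are drawn from Uniform(0, blockMax): one draw per block
#' added to both members of a pair under the paired design (so they cancel
#' exactly in the difference scores), and an independent draw per
#' observation under the independent design.
#'
#' @param model one of \code{"normal"}, \code{"weibull"}, \code{"cauchy"},
#'   \code{"lognormal"}, \code{"chisquare"}, \code{"logistic"},
#'   \code{"exponential"}, \code{"gumbel"}, \code{"pareto"}
#'   (case-sensitive).
#' @param design \code{"paired"} or \code{"independent"}.
#' @param delta non-negative location offset added to the experimental
#'   condition.
#' @param n per-condition sample size (>= 2).
#' @param shape1,shape2 model shape parameters for the control and
#'   experimental conditions (default 1).
#' @param blockMax range of the uniform block effect (default 0, none).
#' @param a0,b0 prior shapes for the rank-test parameter.
#' @param method posterior algorithm passed to the rank test: \code{NULL}
#'   for the automatic small/large rule, \code{"small"} or \code{"large"}.
#' @param samples Monte Carlo replicates per grid point when the small
#'   method is used.
#' @param seed optional integer seed.
#' @return A list with the two samples (\code{sampleC}, \code{sampleE}),
#'   \code{bayesPostProb} (posterior probability that \code{phi_w} or
#'   \code{Omega_E} exceeds .5) and \code{tPvalue}.
#' @examples
#' simData("normal", "independent", delta = .45, n = 30, seed = 1)
#' @export
simData <- function(model, design = c("paired", "independent"), delta,
                    n, shape1 = 1, shape2 = 1, blockMax = 0,
                    a0 = 1, b0 = 1, method = NULL, samples = 30000,
                    seed = NULL) {
  if (!is.character(model) || length(model) != 1L || !(model %in% .simModels))
    stop(sprintf("unknown model '%s'; must be one of %s",
                 as.character(model)[1], paste(.simModels, collapse = ", ")),
         call. = FALSE)
  design <- match.arg(design)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer sample size of at least 2", call. = FALSE)
  if (blockMax < 0) stop("'blockMax' must be non-negative", call. = FALSE)
  n <- as.integer(n)

  .withSeed(seed, {
    sampleC <- .drawModel(model, n, shape1)
    sampleE <- .drawModel(model, n, shape2) + delta
    if (design == "paired") {
      block <- stats::runif(n, 0, blockMax)
      sampleC <- sampleC + block
      sampleE <- sampleE + block
      post <- wilcoxonTest(sampleE, sampleC, a0 = a0, b0 = b0,
                           samples = samples, method = method)
      tP <- stats::t.test(sampleE, sampleC, paired = TRUE,
                          alternative = "greater")$p.value
    } else {
      sampleC <- sampleC + stats::runif(n, 0, blockMax)
      sampleE <- sampleE + stats::runif(n, 0, blockMax)
      post <- mannWhitneyTest(sampleE, sampleC, a0 = a0, b0 = b0,
                              samples = samples, method = method)
      tP <- stats::t.test(sampleE, sampleC, var.equal = TRUE,
                          alternative = "greater")$p.value
    }
    list(sampleC = sampleC, sampleE = sampleE,
         bayesPostProb = post@postProbGtHalf, tPvalue = tP)
  })
}

.powerCell <- function(model, design, delta, n, shape1, shape2, blockMax,
                       a0, b0, effectCrit, samples, cellSeed) {
  bayesHit <- logical(samples)
  tHit <- logical(samples)
  alpha <- 1 - effectCrit
  .withSeed(cellSeed, {
    for (r in seq_len(samples)) {
      out <- simData(model, design, delta, n, shape1, shape2, blockMax,
                     a0, b0, method = "large")
      bayesHit[r] <- out$bayesPostProb >= effectCrit
      tHit[r] <- out$tPvalue < alpha
    }
  })
  c(bayes = mean(bayesHit), t = mean(tHit))
}

.powerSweep <- function(axisName, axis, model, design, delta, n,
                        shape1, shape2, blockMax, a0, b0, effectCrit,
                        samples, seed, quiet) {
  if (!is.numeric(effectCrit) || effectCrit <= 0 || effectCrit >= 1)
    stop("'effectCrit' must lie strictly inside (0, 1)", call. = FALSE)
  bp <- numeric(length(axis))
  tp <- numeric(length(axis))
  for (i in seq_along(axis)) {
    cellSeed <- if (is.null(seed)) NULL else seed + i
    cell <- if (axisName == "n")
      .powerCell(model, design, delta, axis[i], shape1, shape2, blockMax,
                 a0, b0, effectCrit, samples, cellSeed)
    else
      .powerCell(model, design, axis[i], n, shape1, shape2, blockMax,
                 a0, b0, effectCrit, samples, cellSeed)
    bp[i] <- cell["bayes"]
    tp[i] <- cell["t"]
    .progress(quiet, "power sweep: cell %d of %d done (%s = %g)",
              i, length(axis), axisName, axis[i])
  }
  new("PowerTable", axisName = axisName, axis = as.numeric(axis),
      bayesPower = bp, tPower = tp, model = model, design = design,
      delta = as.numeric(delta), n = as.numeric(n),
      effectCrit = effectCrit, samples = as.numeric(samples),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Power versus sample size: Bayesian rank test against the t test
#'
#' For 11 per-condition sample sizes \code{nMin, nMin + 5, ..., nMin + 50},
#' runs \code{samples} replications of [simData()] and reports the
#' proportion of replications in which the Bayesian posterior probability
#' reaches \code{effectCrit} (Bayesian power) and in which the t-test p
#' value falls below \code{1 - effectCrit} (t power). The power drivers
#' evaluate the Bayesian posterior with the beta-approximation algorithm at
#' every sample size; see the package vignette for the rationale.
#'
#' Cells are seeded independently from the root seed by a counter, so a
#' table is reproducible and its cells are mutually independent.
#'
#' @inheritParams simData
#' @param nMin smallest per-condition sample size (default 20).
#' @param effectCrit Bayesian detection threshold; \code{1 - effectCrit} is
#'   the t-test alpha (default .95).
#' @param samples Monte Carlo replications per cell (default 1000).
#' @param quiet suppress per-cell progress messages (default TRUE).
#' @return A [PowerTable-class]; coerce with \code{as.data.frame}.
#' @examples
#' bayesVsTPower(.45, "normal", "independent", samples = 20, seed = 1)
#' @export
bayesVsTPower <- function(delta, model, design = c("paired", "independent"),
                          nMin = 20, a0 = 1, b0 = 1, effectCrit = 0.95,
                          shape1 = 1, shape2 = 1, samples = 1000,
                          blockMax = 0, seed = NULL, quiet = TRUE) {
  design <- match.arg(design)
  if (!is.numeric(nMin) || nMin < 2 || nMin != round(nMin))
    stop("'nMin' must be an integer of at least 2", call. = FALSE)
  axis <- seq(nMin, nMin + 50, by = 5)
  .powerSweep("n", axis, model, design, delta, NA_real_, shape1, shape2,
              blockMax, a0, b0, effectCrit, samples, seed, quiet)
}

#' Power versus separation: Bayesian rank test against the t test
#'
#' For 21 separations \code{0, deltaStep, ..., 20 * deltaStep} at a fixed
#' per-condition sample size \code{n}, estimates Bayesian and t power as in
#' [bayesVsTPower()].
#'
#' @inheritParams bayesVsTPower
#' @param n fixed per-condition sample size (default 20).
#' @param deltaStep separation increment (default .05).
#' @return A [PowerTable-class]; coerce with \code{as.data.frame}.
#' @examples
#' powerCurve("normal", "independent", n = 20, samples = 20, seed = 1)
#' @export
powerCurve <- function(model, design = c("paired", "independent"), n = 20,
                       deltaStep = 0.05, a0 = 1, b0 = 1, effectCrit = 0.95,
                       shape1 = 1, shape2 = 1, samples = 1000,
                       blockMax = 0, seed = NULL, quiet = TRUE) {
  design <- match.arg(design)
  if (!is.numeric(deltaStep) || deltaStep <= 0)
    stop("'deltaStep' must be positive", call. = FALSE)
  axis <- (0:20) * deltaStep
  .powerSweep("delta", axis, model, design, NA_real_, n, shape1, shape2,
              blockMax, a0, b0, effectCrit, samples, seed, quiet)
}

#' Extract the (axis, bayesPower, tPower) table from a power sweep
#'
#' @param x a [PowerTable-class].
#' @param row.names,optional,... ignored.
#' @return A data frame whose first column is named after the swept axis
#'   (\code{n} or \code{delta}).
#' @method as.data.frame PowerTable
#' @export
as.data.frame.PowerTable <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  df <- data.frame(axis = x@axis, bayesPower = x@bayesPower,
                   tPower = x@tPower)
  names(df)[1] <- x@axisName
  df
}
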