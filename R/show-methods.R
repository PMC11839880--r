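# show() methods and small accessor generics

#' @describeIn BetaParams-class shape parameter a.
#' @param object a \code{BetaParams}.
#' @export
setGeneric("shapeA", function(object) standardGeneric("shapeA"))

#' @describeIn BetaParams-class shape parameter b.
#' @export
setGeneric("shapeB", function(object) standardGeneric("shapeB"))

setMethod("shapeA", "BetaParams", function(object) object@a)
setMethod("shapeB", "BetaParams", function(object) object@b)

#' Bayes factor accessor
#'
#' Extracts BF10 from any result object that carries one.
#'
#' @param object a result object.
#' @export
setGeneric("bayesFactor10", function(object) standardGeneric("bayesFactor10"))

setMethod("bayesFactor10", "BayesFactorResult", function(object) object@bf10)
setMethod("bayesFactor10", "ContrastResult", function(object) object@bf10)
setMethod("bayesFactor10", "BetaTestResult", function(object) object@bf10)
setMethod("bayesFactor10", "RankPosterior", function(object) object@bf10)

#' Posterior accessor
#'
#' Extracts the posterior [BetaParams-class] (or the fitted beta
#' approximation for a large-sample rank posterior).
#'
#' @param object a result object.
#' @export
setGeneric("posteriorParams", function(object) standardGeneric("posteriorParams"))

setMethod("posteriorParams", "BetaTestResult", function(object) object@posterior)
setMethod("posteriorParams", "ConcordanceResult", function(object) object@posterior)
setMethod("posteriorParams", "GammaResult", function(object) object@posterior)
setMethod("posteriorParams", "RankPosterior", function(object) {
  if (is.null(object@betaApprox))
    stop("a small-sample rank posterior is a discrete grid; use gridProbs()",
         call. = FALSE)
  object@betaApprox
})

#' Discrete-posterior accessors
#'
#' @param object a [DiscretePosterior-class] or small-sample
#'   [RankPosterior-class].
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("gridProbs", function(object) standardGeneric("gridProbs"))

setMethod("gridValues", "DiscretePosterior", function(object) object@grid)
setMethod("gridProbs", "DiscretePosterior", function(object) object@probs)
setMethod("gridValues", "RankPosterior", function(object) {
  if (is.null(object@discrete))
    stop("no discrete grid: this posterior used the beta approximation",
         call. = FALSE)
  object@discrete@grid
})
setMethod("gridProbs", "RankPosterior", function(object) {
  if (is.null(object@discrete))
    stop("no discrete grid: this posterior used the beta approximation",
         call. = FALSE)
  object@discrete@probs
})

.fmtInterval <- function(x, p) {
  if (anyNA(x)) return("undefined")
  sprintf("[%.5f, %.5f] (%.0f%%)", x[1], x[2], 100 * p)
}

setMethod("show", "BetaParams", function(object) {
  cat(sprintf("Beta distribution with shapes a = %.6g, b = %.6g\n",
              object@a, object@b))
})

setMethod("show", "BetaSummary", function(object) {
  cat(sprintf("Beta(%.6g, %.6g) summary\n", object@params@a, object@params@b))
  cat(sprintf("  mean %.6f  median %.6f  mode %s  variance %.6g\n",
              object@mean, object@median,
              if (is.na(object@mode)) "undefined" else sprintf("%.6f", object@mode),
              object@variance))
  cat("  equal-tail:", .fmtInterval(object@eqtailInterval, object@probInterval), "\n")
  cat("  HDI:       ", .fmtInterval(object@hdiInterval, object@probInterval), "\n")
})

setMethod("show", "BayesFactorResult", function(object) {
  if (object@method == "interval") {
    cat(sprintf("Interval Bayes factor, H0: phi in [%.4g, %.4g]\n",
                object@h0[1], object@h0[2]))
    cat(sprintf("  prior P(H0) = %.6g, posterior P(H0) = %.6g\n",
                object@priorH0, object@postH0))
  } else {
    cat(sprintf("Point Bayes factor (Savage-Dickey), H0: phi = %.4g\n",
                object@h0))
  }
  cat(sprintf("  BF10 = %s, BF01 = %s\n", format(object@bf10, digits = 7),
              format(object@bf01, digits = 7)))
})

setMethod("show", "ContrastResult", function(object) {
  cat("Monte Carlo contrast of", length(object@weights), "binomial rates\n")
  cat(sprintf("  E(Delta) = %.6f (exact), MC mean = %.6f, V(Delta) = %.6g\n",
              object@meanDelta, object@mcMean, object@varDelta))
  cat(sprintf("  P(Delta > 0) = %.6f (SE %.2g)\n",
              object@probPositiveDelta, object@probPositiveSE))
  cat("  equal-tail:", .fmtInterval(object@eqtailInterval, object@probInterval), "\n")
  cat(sprintf("  BF10 (Delta > 0) = %s  [%g draws]\n",
              format(object@bf10, digits = 6), object@samples))
})

setMethod("show", "BetaTestResult", function(object) {
  label <- switch(object@test, mcnemar = "Bayesian McNemar change test",
                  sign = "Bayesian sign test", median = "Bayesian median test")
  cat(label, "\n")
  cat(sprintf("  posterior Beta(%.6g, %.6g); H0: %s\n",
              object@posterior@a, object@posterior@b, object@h0Description))
  cat(sprintf("  P(H1 | data) = %.6g, P(H1 prior) = %.6g, BF10 = %s\n",
              object@postProbH1, object@priorProbH1,
              format(object@bf10, digits = 6)))
  if (object@test == "mcnemar")
    cat(sprintf("  switches 0->1: %d, 1->0: %d, McNemar chi2 = %.4g\n",
                as.integer(object@details$n01), as.integer(object@details$n10),
                object@details$chi2))
  if (object@test == "sign")
    cat(sprintf("  positive: %d, negative: %d, zero (dropped): %d\n",
                as.integer(object@details$nPos), as.integer(object@details$nNeg),
                as.integer(object@details$nZeroDropped)))
  if (object@test == "median")
    cat(sprintf("  combined median %.6g; above-median E: %d, C: %d (base rate %.4g)\n",
                object@details$combinedMedian, as.integer(object@details$aboveE),
                as.integer(object@details$aboveC), object@details$baseRateE))
})

setMethod("show", "WilcoxonStats", function(object) {
  cat(sprintf("Wilcoxon signed-rank statistics: T+ = %g, T- = %g, n = %d\n",
              object@tPlus, object@tMinus, object@nBlocks))
})

setMethod("show", "MannWhitneyStats", function(object) {
  cat(sprintf("Mann-Whitney statistics: U_E = %g, U_C = %g (nE = %d, nC = %d)\n",
              object@uE, object@uC, object@nE, object@nC))
})

setMethod("show", "DiscretePosterior", function(object) {
  cat("Discrete posterior on 200 candidate proportions (.0025 ... .9975)\n")
  cat(sprintf("  mean %.6f, mass above .5: %.6f\n",
              sum(object@grid * object@probs),
              sum(object@probs[object@grid > 0.5])))
})

setMethod("show", "RankPosterior", function(object) {
  param <- if (object@statistic == "wilcoxon") "phi_w" else "Omega_E"
  cat(sprintf("Bayesian %s analysis (%s method)\n",
              sub("_", "-", object@statistic), object@methodUsed))
  show(object@stats)
  if (!is.null(object@betaApprox))
    cat(sprintf("  beta approximation: a = %.5g, b = %.5g\n",
                object@betaApprox@a, object@betaApprox@b))
  cat(sprintf("  posterior mean %s = %.6f\n", param, object@postMean))
  cat(sprintf("  P(%s > .5) = %.6f (prior %.6f), BF10 = %s\n", param,
              object@postProbGtHalf, object@priorProbGtHalf,
              format(object@bf10, digits = 6)))
  cat("  equal-tail:", .fmtInterval(object@eqtailInterval, object@probInterval), "\n")
})

setMethod("show", "PairCounts", function(object) {
  cat(sprintf("Pair counts over %d points: concordant %g, discordant %g\n",
              object@nPoints, object@nC, object@nD))
  cat(sprintf("  ties lost: T_X = %g, T_Y = %g, T_XY = %g\n",
              object@tX, object@tY, object@tXY))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat("Bayesian concordance analysis\n")
  show(object@counts)
  cat(sprintf("  sample tau_A = %.6f; posterior phi_c ~ Beta(%.6g, %.6g)\n",
              object@tauA, object@posterior@a, object@posterior@b))
  cat("  tau_A equal-tail:",
      .fmtInterval(object@tauEqtailInterval, object@summary@probInterval), "\n")
  if (object@fittingParameters > 0L)
    cat(sprintf("  GOF adjustment: m = %d, nC* = %g, phi_c* ~ Beta(%.6g, %.6g)\n",
                object@fittingParameters, object@nCStar,
                object@adjustedPosterior@a, object@adjustedPosterior@b))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("Goodman-Kruskal gamma for a %d x %d ordered table\n",
              nrow(object@table), ncol(object@table)))
  cat(sprintf("  N_s = %g, N_d = %g, G = %.6f\n",
              object@nS, object@nD, object@gammaStat))
  cat(sprintf("  posterior phi_c ~ Beta(%.6g, %.6g)\n",
              object@posterior@a, object@posterior@b))
})

setMethod("show", "PowerTable", function(object) {
  cat(sprintf("Power table (%s sweep), model %s, %s design\n",
              object@axisName, object@model, object@design))
  cat(sprintf("  effectCrit %.3g, %g replications per cell\n",
              object@effectCrit, object@samples))
  print(as.data.frame(object))
})
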