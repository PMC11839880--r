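#' @import methods
NULL

#' Beta distribution shape parameters
#'
#' A pair of positive shape parameters \code{(a, b)} defining a beta
#' distribution, used both for priors and for conjugate posteriors on a
#' Bernoulli rate parameter.
#'
#' @slot a positive shape parameter.
#' @slot b positive shape parameter.
#' @seealso [betaParams()], [binomialPosterior()], [betaDescriptive()]
#' @export
setClass("BetaParams", representation(a = "numeric", b = "numeric"))

setValidity("BetaParams", function(object) {
  if (length(object@a) != 1L || length(object@b) != 1L)
    return("a and b must be single numbers")
  if (!is.finite(object@a) || !is.finite(object@b))
    return("a and b must be finite")
  if (object@a <= 0 || object@b <= 0)
    return("beta shape parameters must be strictly positive")
  TRUE
})

#' Construct a BetaParams object
#'
#' @param a,b positive beta shape parameters.
#' @return A [BetaParams-class] object.
#' @examples
#' betaParams(17, 3)
#' @export
betaParams <- function(a, b) new("BetaParams", a = as.numeric(a), b = as.numeric(b))

#' Descriptive summary of a beta distribution
#'
#' @slot mean,median,variance central moments and the exact median.
#' @slot mode the interior mode \code{(a-1)/(a+b-2)} when both shapes exceed
#'   1, otherwise \code{NA} (the density peaks on the boundary).
#' @slot eqtailInterval equal-tail interval covering \code{probInterval} mass.
#' @slot hdiInterval highest-density interval; one-sided when exactly one
#'   shape is at most 1, \code{NA} when both are.
#' @slot probInterval the probability mass covered by each interval.
#' @slot params the summarised [BetaParams-class].
#' @export
setClass("BetaSummary",
  representation(params = "BetaParams", mean = "numeric", median = "numeric",
                 mode = "numeric", variance = "numeric",
                 eqtailInterval = "numeric", hdiInterval = "numeric",
                 probInterval = "numeric"))

setValidity("BetaSummary", function(object) {
  p <- object@probInterval
  if (length(p) != 1L || p <= 0 || p >= 1)
    return("probInterval must lie strictly inside (0, 1)")
  et <- object@eqtailInterval
  if (length(et) != 2L || any(et < 0) || any(et > 1) || et[1] > et[2])
    return("eqtailInterval must be an ordered pair inside [0, 1]")
  hd <- object@hdiInterval
  if (length(hd) != 2L)
    return("hdiInterval must have length 2 (possibly NA)")
  if (!anyNA(hd) && (any(hd < 0) || any(hd > 1) || hd[1] > hd[2]))
    return("hdiInterval must be an ordered pair inside [0, 1]")
  TRUE
})

#' Bayes factor between an alternative and a null hypothesis about a rate
#'
#' @slot bf10,bf01 the Bayes factors (either may be \code{Inf} when a
#'   hypothesis probability underflows to zero).
#' @slot priorH0,priorH1,postH0,postH1 prior and posterior hypothesis
#'   probabilities (interval method; for the point method the H0 entries are
#'   \code{NA} because a point null has zero mass under a continuous prior).
#' @slot method \code{"interval"} or \code{"point"}.
#' @slot h0 the null: an interval \code{c(L, U)} or a single point.
#' @export
setClass("BayesFactorResult",
  representation(bf10 = "numeric", bf01 = "numeric",
                 priorH0 = "numeric", priorH1 = "numeric",
                 postH0 = "numeric", postH1 = "numeric",
                 method = "character", h0 = "numeric"))

#' Monte Carlo posterior for a linear contrast of K binomial rates
#'
#' @slot weights the contrast weights psi.
#' @slot meanDelta,varDelta exact posterior mean and variance of the
#'   contrast from the closed forms for a linear combination of independent
#'   beta variates.
#' @slot mcMean mean of the sampled contrast values.
#' @slot probPositiveDelta Monte Carlo estimate of P(Delta > 0).
#' @slot probPositiveSE binomial standard error of that estimate.
#' @slot eqtailInterval equal-tail interval from empirical quantiles.
#' @slot priorProbPositive Monte Carlo P(Delta > 0) under the priors.
#' @slot bf10 posterior odds of Delta > 0 over prior odds.
#' @slot probInterval,samples,seed Monte Carlo settings.
#' @slot deltaSamples retained sample vector (possibly length 0).
#' @export
setClass("ContrastResult",
  representation(weights = "numeric", meanDelta = "numeric",
                 varDelta = "numeric", mcMean = "numeric",
                 probPositiveDelta = "numeric", probPositiveSE = "numeric",
                 eqtailInterval = "numeric", priorProbPositive = "numeric",
                 bf10 = "numeric", probInterval = "numeric",
                 samples = "numeric", seed = "numeric",
                 deltaSamples = "numeric"))

#' Result of a Bernoulli-reduction test (McNemar, sign, median)
#'
#' All three categorical tests reduce their data to two Bernoulli counts and
#' then apply conjugate beta updating; this class carries the shared output.
#'
#' @slot test one of \code{"mcnemar"}, \code{"sign"}, \code{"median"}.
#' @slot prior,posterior beta shapes before and after updating.
#' @slot summary a [BetaSummary-class] of the posterior.
#' @slot postProbH1,priorProbH1 probabilities of the alternative hypothesis.
#' @slot bf10 interval Bayes factor for the alternative.
#' @slot h0Description human-readable statement of the null.
#' @slot details test-specific numbers (counts, chi-square, median, ...).
#' @export
setClass("BetaTestResult",
  representation(test = "character", prior = "BetaParams",
                 posterior = "BetaParams", summary = "BetaSummary",
                 postProbH1 = "numeric", priorProbH1 = "numeric",
                 bf10 = "numeric", h0Description = "character",
                 details = "list"))

#' Wilcoxon signed-rank statistics
#'
#' @slot tPlus,tMinus sums of the ranks of |d| with positive / negative sign
#'   (midranks for tied |d|, zero differences dropped).
#' @slot nBlocks number of non-zero-difference blocks.
#' @export
setClass("WilcoxonStats",
  representation(tPlus = "numeric", tMinus = "numeric", nBlocks = "integer"))

setValidity("WilcoxonStats", function(object) {
  if (object@tPlus < 0 || object@tMinus < 0)
    return("rank sums must be non-negative")
  if (object@nBlocks < 1L) return("need at least one non-zero difference")
  TRUE
})

#' Mann-Whitney U statistics
#'
#' @slot uE,uC counts of cross-group pairs won strictly by the experimental /
#'   control group (ties count for neither).
#' @slot nE,nC group sizes.
#' @export
setClass("MannWhitneyStats",
  representation(uE = "numeric", uC = "numeric", nE = "integer", nC = "integer"))

setValidity("MannWhitneyStats", function(object) {
  if (object@nE < 1L || object@nC < 1L) return("both groups must be non-empty")
  if (object@uE < 0 || object@uC < 0) return("U statistics are non-negative")
  if (object@uE + object@uC > object@nE * object@nC + 1e-9)
    return("uE + uC cannot exceed nE * nC")
  TRUE
})

#' Discrete 200-point posterior over a proportion parameter
#'
#' The grid holds the 200 candidate values .0025, .0075, ..., .9975 (step
#' .005) used by the small-sample rank-test algorithms.
#'
#' @slot grid the 200 candidate proportions.
#' @slot probs 200 non-negative probabilities summing to one.
#' @export
setClass("DiscretePosterior",
  representation(grid = "numeric", probs = "numeric"))

setValidity("DiscretePosterior", function(object) {
  if (length(object@grid) != 200L || length(object@probs) != 200L)
    return("grid and probs must have length 200")
  if (!identical(object@grid, .phiGrid()))
    return("grid must be .0025 + (i-1)*.005 for i = 1..200")
  if (any(object@probs < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@probs) - 1) > 1e-12)
    return("probabilities must sum to 1 (tolerance 1e-12)")
  TRUE
})

setClassUnion("DiscretePosteriorOrNULL", c("DiscretePosterior", "NULL"))
setClassUnion("BetaParamsOrNULL", c("BetaParams", "NULL"))

#' Posterior for a rank-test proportion parameter (phi_w or Omega_E)
#'
#' @slot statistic \code{"wilcoxon"} or \code{"mann_whitney"}.
#' @slot methodUsed \code{"small"} (discrete grid) or \code{"large"}
#'   (beta approximation).
#' @slot stats the observed statistics object.
#' @slot prior beta prior on the proportion parameter.
#' @slot discrete the 200-point posterior (small method only).
#' @slot betaApprox the fitted beta posterior (large method only).
#' @slot postMean posterior mean of the parameter.
#' @slot postProbGtHalf,priorProbGtHalf P(parameter > .5) after / before data.
#' @slot eqtailInterval equal-tail interval for the parameter.
#' @slot bf10 Bayes factor for H1: parameter > .5 vs H0: parameter <= .5.
#' @slot probInterval interval mass.
#' @slot samplesPerGridPoint,seed Monte Carlo settings (small method).
#' @export
setClass("RankPosterior",
  representation(statistic = "character", methodUsed = "character",
                 stats = "ANY", prior = "BetaParams",
                 discrete = "DiscretePosteriorOrNULL",
                 betaApprox = "BetaParamsOrNULL",
                 postMean = "numeric", postProbGtHalf = "numeric",
                 priorProbGtHalf = "numeric", eqtailInterval = "numeric",
                 bf10 = "numeric", probInterval = "numeric",
                 samplesPerGridPoint = "numeric", seed = "numeric"))

#' Pairwise comparison counts with tie corrections
#'
#' @slot nC,nD concordant and discordant pair counts.
#' @slot tX,tY,tXY comparisons lost to ties on X, on Y, and on both
#'   simultaneously (the last is added back once in the identity
#'   \code{nC + nD = N(N-1)/2 - tX - tY + tXY}).
#' @slot nPoints number of bivariate points N.
#' @export
setClass("PairCounts",
  representation(nC = "numeric", nD = "numeric", tX = "numeric",
                 tY = "numeric", tXY = "numeric", nPoints = "integer"))

setValidity("PairCounts", function(object) {
  v <- c(object@nC, object@nD, object@tX, object@tY, object@tXY)
  if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
  n <- as.numeric(object@nPoints)
  if (object@nC + object@nD !=
      n * (n - 1) / 2 - object@tX - object@tY + object@tXY)
    return("tie-corrected comparison identity violated")
  TRUE
})

#' Bayesian concordance analysis result
#'
#' @slot counts the [PairCounts-class].
#' @slot tauA the sample Kendall tau-A, (nC - nD)/(nC + nD).
#' @slot prior,posterior beta shapes for the concordance proportion phi_c.
#' @slot summary posterior [BetaSummary-class] for phi_c.
#' @slot tauEqtailInterval the phi_c interval mapped through 2q - 1.
#' @slot fittingParameters number m of free model parameters (goodness-of-fit
#'   use); 0 for plain association.
#' @slot nCStar adjusted concordant count \code{nC - N m + m(m+1)/2}
#'   (\code{NA} when m = 0).
#' @slot adjustedPosterior posterior for the adjusted concordance phi_c*
#'   (\code{NULL} when m = 0).
#' @export
setClass("ConcordanceResult",
  representation(counts = "PairCounts", tauA = "numeric",
                 prior = "BetaParams", posterior = "BetaParams",
                 summary = "BetaSummary", tauEqtailInterval = "numeric",
                 fittingParameters = "integer", nCStar = "numeric",
                 adjustedPosterior = "BetaParamsOrNULL"))

#' Goodman-Kruskal gamma analysis of an ordered contingency table
#'
#' @slot table the R x C frequency table.
#' @slot nS,nD counts of order agreements and disagreements.
#' @slot gammaStat the sample G = (nS - nD)/(nS + nD).
#' @slot prior,posterior beta shapes for the concordance proportion.
#' @slot summary posterior [BetaSummary-class].
#' @export
setClass("GammaResult",
  representation(table = "matrix", nS = "numeric", nD = "numeric",
                 gammaStat = "numeric", prior = "BetaParams",
                 posterior = "BetaParams", summary = "BetaSummary"))

#' Power comparison table: Bayesian distribution-free test versus the t test
#'
#' @slot axisName \code{"n"} (sample-size sweep) or \code{"delta"}
#'   (separation sweep).
#' @slot axis the 11 sample sizes or 21 separations.
#' @slot bayesPower,tPower estimated detection proportions per axis value.
#' @slot model,design the generating model and design.
#' @slot delta,n the fixed factor (separation for a sample-size sweep, sample
#'   size for a separation sweep).
#' @slot effectCrit posterior threshold for a Bayesian detection; 1 -
#'   effectCrit is the t-test alpha.
#' @slot samples Monte Carlo replications per cell.
#' @slot seed root seed.
#' @export
setClass("PowerTable",
  representation(axisName = "character", axis = "numeric",
                 bayesPower = "numeric", tPower = "numeric",
                 model = "character", design = "character",
                 delta = "numeric", n = "numeric", effectCrit = "numeric",
                 samples = "numeric", seed = "numeric"))

setValidity("PowerTable", function(object) {
  k <- length(object@axis)
  if (!(k %in% c(11L, 21L))) return("axis must have 11 (n) or 21 (delta) values")
  if (length(object@bayesPower) != k || length(object@tPower) != k)
    return("power vectors must match the axis length")
  if (any(object@bayesPower < 0 | object@bayesPower > 1) ||
      any(object@tPower < 0 | object@tPower > 1))
    return("powers must be proportions")
  TRUE
})
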