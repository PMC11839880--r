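# Pairwise-comparison kernels: Kendall tau-A with full tie corrections,
# the concordance proportion phi_c, the goodness-of-fit adjusted phi_c*,
# and Goodman-Kruskal gamma on ordered contingency tables.

#' Concordant/discordant pair counts with tie corrections
#'
#' Exhaustively classifies the N(N-1)/2 unordered point pairs: a pair is
#' concordant when the two coordinate differences have the same strict
#' sign, discordant when strictly opposite. Sign comparisons on the raw
#' values equal sign comparisons on ranks, so ranks are never materialized.
#' The tie totals \code{tX}, \code{tY} and \code{tXY} are the comparisons
#' lost to ties on X, on Y, and on both simultaneously, computed from
#' cluster sizes as \code{sum(t(t-1)/2)}; they satisfy
#' \code{nC + nD = N(N-1)/2 - tX - tY + tXY} exactly.
#'
#' @param x,y equal-length numeric vectors (N >= 2).
#' @return A [PairCounts-class] object.
#' @examples
#' concordanceCounts(c(1, 2, 3), c(1, 3, 2))
#' @export
concordanceCounts <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop("'x' and 'y' must be numeric with no missing values", call. = FALSE)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have the same length", call. = FALSE)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  up <- upper.tri(matrix(0, n, n))
  sx <- sign(outer(x, x, "-"))[up]
  sy <- sign(outer(y, y, "-"))[up]
  prod <- sx * sy
  tieClusters <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  new("PairCounts",
      nC = sum(prod > 0), nD = sum(prod < 0),
      tX = tieClusters(x), tY = tieClusters(y),
      tXY = tieClusters(paste(x, y, sep = "\r")),
      nPoints = n)
}

#' Kendall tau-A from pair counts
#'
#' \code{tauA = (nC - nD)/(nC + nD)}; with the tie totals of
#' [concordanceCounts()] the denominator equals
#' \code{N(N-1)/2 - tX - tY + tXY}, which corrects the comparison count for
#' every tie pattern (unlike the common tau-B formula, which is biased when
#' points are tied on both variates).
#'
#' @param counts a [PairCounts-class] object.
#' @return The sample tau-A in [-1, 1].
#' @examples
#' tauA(concordanceCounts(1:5, c(2, 1, 3, 5, 4)))
#' @export
tauA <- function(counts) {
  stopifnot(is(counts, "PairCounts"))
  if (counts@nC + counts@nD < 1)
    stop("no comparable pairs: every pair is multiply tied", call. = FALSE)
  (counts@nC - counts@nD) / (counts@nC + counts@nD)
}

#' Bayesian concordance analysis (tau-A) with optional goodness-of-fit use
#'
#' Each comparable pair is a Bernoulli trial (concordant or discordant), so
#' a beta prior on the population concordance proportion \code{phi_c}
#' yields the posterior \code{Beta(a0 + nC, b0 + nD)}; the population
#' \code{tau_A = 2 phi_c - 1}, so tau intervals are the monotone transform
#' \code{2q - 1} of the phi_c quantiles.
#'
#' For goodness-of-fit testing, \code{x} is the observed measure and
#' \code{y} the model-based estimate, and \code{fittingParameters} is the
#' total number m of free parameters used across all fitted units. Each
#' parameter effectively removes one condition from comparison, so the
#' concordant count is penalized to
#' \code{nCStar = nC - N m + m(m+1)/2}; the discordant count is not
#' adjusted, and the adjusted posterior is \code{Beta(a0 + nCStar, b0 + nD)}.
#'
#' @param x,y equal-length numeric vectors.
#' @param a0,b0 prior beta shapes for phi_c (default uniform).
#' @param fittingParameters number m of free model parameters (default 0,
#'   plain association).
#' @param probInterval interval mass (default .95).
#' @return A [ConcordanceResult-class] object.
#' @examples
#' bivariateConcordance(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
bivariateConcordance <- function(x, y, a0 = 1, b0 = 1,
                                 fittingParameters = 0,
                                 probInterval = 0.95) {
  counts <- concordanceCounts(x, y)
  prior <- betaParams(a0, b0)
  .checkProbInterval(probInterval)
  m <- .checkCount(fittingParameters, "fittingParameters")
  posterior <- binomialPosterior(counts@nC, counts@nD, prior)
  summ <- betaDescriptive(posterior, probInterval)
  nCStar <- NA_real_
  adjusted <- NULL
  if (m > 0) {
    n <- as.numeric(counts@nPoints)
    nCStar <- counts@nC - n * m + m * (m + 1) / 2
    if (nCStar <= 0)
      stop("over-parameterized model: the adjusted concordant count is not positive",
           call. = FALSE)
    adjusted <- betaParams(prior@a + nCStar, prior@b + counts@nD)
  }
  new("ConcordanceResult",
      counts = counts, tauA = tauA(counts), prior = prior,
      posterior = posterior, summary = summ,
      tauEqtailInterval = 2 * summ@eqtailInterval - 1,
      fittingParameters = as.integer(m), nCStar = nCStar,
      adjustedPosterior = adjusted)
}

#' Goodman-Kruskal gamma for an ordered contingency table
#'
#' Rows are the ranks of X, columns the ranks of Y, and cell (i, j) holds
#' the frequency of points with those ranks. \code{nS} counts pairs of
#' observations whose orders agree (one cell strictly below and to the
#' right of the other) and \code{nD} pairs whose orders disagree (strictly
#' below and to the left); \code{G = (nS - nD)/(nS + nD)}. These counts
#' equal the concordant/discordant counts of [concordanceCounts()] on the
#' expanded point set, so G is the sample tau-A, and the posterior for the
#' concordance proportion is \code{Beta(a0 + nS, b0 + nD)}.
#'
#' @param table an R x C matrix of non-negative integer frequencies
#'   (R, C >= 2).
#' @param a0,b0 prior beta shapes (default uniform).
#' @param probInterval interval mass (default .95).
#' @return A [GammaResult-class] object.
#' @examples
#' gammaTable(matrix(c(20, 5, 5, 20), 2, 2))
#' @export
gammaTable <- function(table, a0 = 1, b0 = 1, probInterval = 0.95) {
  table <- as.matrix(table)
  if (!is.numeric(table) || anyNA(table) || any(table < 0) ||
      any(table != round(table)))
    stop("'table' must be a matrix of non-negative integer frequencies",
         call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("the contingency table must be at least 2 x 2", call. = FALSE)
  if (sum(table) < 1) stop("the table is empty", call. = FALSE)
  prior <- betaParams(a0, b0)
  .checkProbInterval(probInterval)
  R <- nrow(table); C <- ncol(table)
  nS <- 0; nD <- 0
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      if (table[i, j] == 0) next
      if (i < R && j < C)
        nS <- nS + table[i, j] * sum(table[(i + 1):R, (j + 1):C])
      if (i < R && j > 1)
        nD <- nD + table[i, j] * sum(table[(i + 1):R, 1:(j - 1)])
    }
  }
  if (nS + nD == 0)
    stop("no order-comparable pairs: all mass lies in one row or one column",
         call. = FALSE)
  posterior <- binomialPosterior(nS, nD, prior)
  new("GammaResult", table = table, nS = nS, nD = nD,
      gammaStat = (nS - nD) / (nS + nD), prior = prior,
      posterior = posterior,
      summary = betaDescriptive(posterior, probInterval))
}
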