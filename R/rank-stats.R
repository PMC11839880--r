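#' Wilcoxon signed-rank statistics
#'
#' Zero differences are dropped; the absolute differences of the remaining
#' blocks are ranked ascending with midranks for ties, and \code{T+} /
#' \code{T-} are the sums of the ranks attached to positive / negative
#' differences. With no tied |d|, \code{T+ + T- = n(n+1)/2} exactly.
#'
#' @param y1,y2 equal-length paired response vectors.
#' @return A [WilcoxonStats-class] object.
#' @examples
#' wilcoxonStats(c(5, 7, 9), c(1, 2, 12))
#' @export
wilcoxonStats <- function(y1, y2) {
  if (!is.numeric(y1) || !is.numeric(y2) || anyNA(y1) || anyNA(y2))
    stop("'y1' and 'y2' must be numeric with no missing values", call. = FALSE)
  if (length(y1) != length(y2))
    stop("'y1' and 'y2' must have the same length", call. = FALSE)
  d <- y1 - y2
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("no informative blocks: all differences are zero", call. = FALSE)
  r <- rank(abs(d), ties.method = "average")
  new("WilcoxonStats",
      tPlus = sum(r[d > 0]), tMinus = sum(r[d < 0]),
      nBlocks = length(d))
}

#' Mann-Whitney U statistics
#'
#' Counts, over all nE x nC cross-group pairs, the pairs won strictly by
#' the experimental group (\code{uE}) and strictly by the control group
#' (\code{uC}); tied pairs contribute to neither, so \code{uE + uC} can fall
#' short of \code{nE * nC} when cross-group ties exist.
#'
#' @param e,c numeric response vectors for the experimental and control
#'   groups.
#' @return A [MannWhitneyStats-class] object.
#' @examples
#' mannWhitneyStats(c(2, 5, 7, 8, 9), c(1, 3, 4, 6))  # uE = 16, uC = 4
#' @export
mannWhitneyStats <- function(e, c) {
  if (!is.numeric(e) || !is.numeric(c) || anyNA(e) || anyNA(c))
    stop("'e' and 'c' must be numeric with no missing values", call. = FALSE)
  if (length(e) < 1L || length(c) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  cmp <- outer(e, c, "-")
  new("MannWhitneyStats",
      uE = as.numeric(sum(cmp > 0)), uC = as.numeric(sum(cmp < 0)),
      nE = length(e), nC = length(c))
}

#' Collapse K within-block conditions to a weighted pair for a contrast
#'
#' For a blocks-by-K matrix of within-block measurements and a contrast
#' weight vector, forms \code{y1} as the weighted sum of the
#' positive-weight columns and \code{y2} as the (absolute-)weighted sum of
#' the negative-weight columns, so that a paired analysis of
#' \code{(y1, y2)} addresses the contrast.
#'
#' @param dataMatrix numeric matrix, one row per block, one column per
#'   condition.
#' @param weights contrast weights (sum 0; positive part sums to 1,
#'   negative part to -1).
#' @return A list with components \code{y1} and \code{y2}.
#' @examples
#' m <- matrix(rnorm(24), ncol = 4)
#' compositePair(m, c(-1/3, -1/3, -1/3, 1))
#' @export
compositePair <- function(dataMatrix, weights) {
  dataMatrix <- as.matrix(dataMatrix)
  if (!is.numeric(dataMatrix) || anyNA(dataMatrix))
    stop("'dataMatrix' must be numeric with no missing values", call. = FALSE)
  weights <- .checkWeights(weights, ncol(dataMatrix))
  pos <- weights > 0
  neg <- weights < 0
  list(y1 = drop(dataMatrix[, pos, drop = FALSE] %*% weights[pos]),
       y2 = drop(dataMatrix[, neg, drop = FALSE] %*% abs(weights[neg])))
}

#' Pool K independent groups into two sides of a contrast
#'
#' Concatenates the columns carrying positive weights into an experimental
#' pool and those carrying negative weights into a control pool, for a
#' two-group (Mann-Whitney) analysis of a K-condition contrast. Only the
#' signs of the weights matter here; the U statistics are invariant to the
#' concatenation order.
#'
#' @param columns a list of numeric vectors, one per condition (lengths may
#'   differ).
#' @param weights contrast weights; each side must be non-empty.
#' @return A list with components \code{e} and \code{c}.
#' @examples
#' poolGroups(list(rnorm(5), rnorm(5), rnorm(5)), c(-0.5, -0.5, 1))
#' @export
poolGroups <- function(columns, weights) {
  if (!is.list(columns) || !all(vapply(columns, is.numeric, logical(1))))
    stop("'columns' must be a list of numeric vectors", call. = FALSE)
  weights <- .checkWeights(weights, length(columns))
  pos <- weights > 0
  neg <- weights < 0
  if (!any(pos) || !any(neg))
    stop("each side of the contrast needs at least one condition", call. = FALSE)
  list(e = unlist(columns[pos], use.names = FALSE),
       c = unlist(columns[neg], use.names = FALSE))
}
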