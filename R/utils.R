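# internal helpers shared across modules

# the 200 candidate proportions used by the discrete rank-test posteriors
.phiGrid <- function() .0025 + (0:199) * .005

.checkProbInterval <- function(probInterval) {
  if (!is.numeric(probInterval) || length(probInterval) != 1L ||
      is.na(probInterval) || probInterval <= 0 || probInterval >= 1)
    stop("'probInterval' must be a single number strictly inside (0, 1)",
         call. = FALSE)
  probInterval
}

.checkCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.numeric(x)
}

.checkCountVec <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x < 0) || any(x != round(x)))
    stop(sprintf("'%s' must be a vector of non-negative integers", name),
         call. = FALSE)
  as.numeric(x)
}

# contrast weights: sum zero, positive part sums to +1, negative part to -1
.checkWeights <- function(weights, k = NULL, tol = 1e-10) {
  if (!is.numeric(weights) || anyNA(weights))
    stop("contrast weights must be numeric and free of NA", call. = FALSE)
  if (!is.null(k) && length(weights) != k)
    stop("contrast weights must have one entry per condition", call. = FALSE)
  if (length(weights) < 2L)
    stop("a contrast needs at least two conditions", call. = FALSE)
  if (abs(sum(weights)) > tol ||
      abs(sum(weights[weights > 0]) - 1) > tol ||
      abs(sum(weights[weights < 0]) + 1) > tol)
    stop(paste("invalid contrast weights: they must sum to 0 with the",
               "positive weights summing to 1 and the negative weights to -1"),
         call. = FALSE)
  weights
}

# evaluate expr under a temporary seed, restoring the caller's RNG state;
# a NULL seed leaves the ambient RNG stream untouched
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# odds-ratio Bayes factor with underflow -> Inf handling
.oddsBF <- function(postH1, postH0, priorH1, priorH0) {
  if (priorH1 <= 0) return(0)
  if (postH0 <= 0 || priorH0 <= 0) {
    if (postH1 <= 0) return(NaN)
    return(Inf)
  }
  (postH1 / postH0) / (priorH1 / priorH0)
}

# quantiles of a discrete distribution on an increasing grid, linearly
# interpolating the step CDF between adjacent grid points
.discreteQuantile <- function(grid, probs, p) {
  cdf <- cumsum(probs)
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(x = cdf[keep], y = grid[keep], xout = p, rule = 2,
                ties = "ordered")$y
}

.progress <- function(quiet, fmt, ...) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
  invisible(NULL)
}
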