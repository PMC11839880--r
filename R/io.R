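# Plain-text readers and the seeded fixture generator.

#' Read a numeric column from a CSV/TSV file
#'
#' Order-preserving; any missing or non-numeric cell is rejected with the
#' offending row named in the error message.
#'
#' @param path path to a delimited text file.
#' @param column column to extract, by position or name (default 1).
#' @param header does the file carry a header row (default FALSE)?
#' @param sep field separator; \code{""} (default) auto-detects a comma or
#'   tab from the first line.
#' @return A numeric vector.
#' @export
readVector <- function(path, column = 1, header = FALSE, sep = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (sep == "") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (is.character(column) && !(column %in% names(df)))
    stop(sprintf("no column named '%s' in %s", column, path), call. = FALSE)
  if (is.numeric(column) && (column < 1 || column > ncol(df)))
    stop(sprintf("file %s has %d column(s); cannot take column %d",
                 path, ncol(df), column), call. = FALSE)
  raw <- df[[column]]
  if (length(raw) == 0L) stop(sprintf("empty column in %s", path), call. = FALSE)
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) | raw %in% c("", "NA"))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric or missing value at row %d of %s",
                 bad[1], path), call. = FALSE)
  val
}

#' Read an ordered contingency table from a CSV/TSV file
#'
#' Expects a rectangular grid of non-negative integers, one table row per
#' line; at least 2 rows and 2 columns.
#'
#' @inheritParams readVector
#' @return An integer matrix suitable for [gammaTable()].
#' @export
readContingency <- function(path, header = FALSE, sep = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (sep == "") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  lines <- strsplit(readLines(path), sep, fixed = TRUE)
  if (header) lines <- lines[-1]
  lines <- lines[vapply(lines, length, integer(1)) > 0L]
  widths <- unique(vapply(lines, length, integer(1)))
  if (length(widths) != 1L)
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(widths, collapse = ", ")), call. = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(lines))), nrow = length(lines),
           byrow = TRUE))
  if (anyNA(m)) stop(sprintf("non-numeric cell in %s", path), call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop(sprintf("entries in %s must be non-negative integers", path),
         call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("the contingency table must be at least 2 x 2", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Generate a seeded synthetic data fixture on disk
#'
#' Draws one two-condition data set with the generators of [simData()] and
#' writes it as a CSV (two aligned columns \code{y1, y2} for a paired
#' design; stacked \code{group, value} rows for an independent design)
#' plus a JSON sidecar recording the generating specification and, where a
#' closed form exists, the implied true parameter (normal location shift:
#' \code{Omega_E = pnorm(delta / (shape * sqrt(2)))}, equal shapes).
#'
#' @inheritParams simData
#' @param path output CSV path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @param seed integer seed (required, so fixtures are reproducible).
#' @return Invisibly, a list with the data and the sidecar record.
#' @export
generateFixture <- function(model, design = c("paired", "independent"),
                            delta, n, path, seed, shape1 = 1, shape2 = 1,
                            blockMax = 0) {
  design <- match.arg(design)
  if (missing(seed)) stop("'seed' is required for a fixture", call. = FALSE)
  sim <- simData(model, design, delta, n, shape1, shape2, blockMax,
                 method = "large", seed = seed)
  trueOmega <- if (model == "normal" && shape1 == shape2)
    stats::pnorm(delta / (shape1 * sqrt(2))) else NA_real_
  if (design == "paired") {
    df <- data.frame(y1 = sim$sampleE, y2 = sim$sampleC)
  } else {
    df <- data.frame(group = rep(c("E", "C"), each = n),
                     value = c(sim$sampleE, sim$sampleC))
  }
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(model = model, design = design, delta = delta, n = n,
                  shape1 = shape1, shape2 = shape2, blockMax = blockMax,
                  seed = seed, trueOmegaE = trueOmega)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(data = df, sidecar = sidecar))
}
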