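# Age-dependent background (other-cause) mortality.

#' Construct a life table
#'
#' @param age integer ages (years), contiguous.
#' @param qx annual probability of death at each age, in \[0, 1\].
#' @return a `cea_lifetable` data frame with columns `age`, `qx`.
#' @export
cea_lifetable <- function(age, qx) {
  df <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  validate_lifetable(df)
  class(df) <- c("cea_lifetable", "data.frame")
  df
}

#' Validate a life table
#'
#' Requires contiguous integer age coverage and all `qx` in \[0, 1\].
#'
#' @param table a life-table data frame.
#' @return `TRUE`, invisibly.
#' @export
validate_lifetable <- function(table) {
  if (!all(c("age", "qx") %in% names(table)))
    stop("life table must have columns 'age' and 'qx'")
  if (nrow(table) < 1) stop("life table is empty")
  if (is.unsorted(table$age, strictly = TRUE))
    stop("life-table ages must be strictly increasing")
  gaps <- which(diff(table$age) != 1L)
  if (length(gaps))
    stop("life table has a gap: age ", table$age[gaps[1]] + 1L, " is missing")
  bad <- which(table$qx < 0 | table$qx > 1 | !is.finite(table$qx))
  if (length(bad))
    stop("life-table qx out of [0, 1] at age ", table$age[bad[1]],
         " (qx = ", table$qx[bad[1]], ")")
  invisible(TRUE)
}

#' Annual background mortality at a given age
#'
#' Ages beyond the oldest covered age return 1 (forced terminal mortality, so
#' a long model horizon cannot outlive the table); ages below the youngest
#' covered age are an error.
#'
#' @param table a `cea_lifetable`.
#' @param age age in years (fractional ages use the containing integer year).
#' @return the annual death probability q(age).
#' @export
annual_mortality <- function(table, age) {
  a <- floor(age)
  lo <- table$age[1]; hi <- table$age[nrow(table)]
  if (any(a < lo))
    stop("age ", min(a), " is below the life table's range (starts at ", lo, ")")
  q <- ifelse(a > hi, 1, table$qx[pmin(pmax(a, lo), hi) - lo + 1L])
  unname(q)
}

#' Load a life table from CSV
#'
#' Expects a header `age,qx` and one row per integer age; lines starting with
#' `#` are treated as comments. `write_lifetable()` then `load_lifetable()` is
#' the identity.
#'
#' @param path CSV file path.
#' @return a validated `cea_lifetable`.
#' @export
load_lifetable <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "qx") %in% names(df)))
    stop("life-table CSV must have columns 'age' and 'qx': ", path)
  cea_lifetable(df$age, df$qx)
}

#' Write a life table to CSV
#'
#' @param table a `cea_lifetable`.
#' @param path output path.
#' @param header optional comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines("age,qx", con)
  writeLines(paste(table$age, format(table$qx, digits = 15, scientific = FALSE,
                                     trim = TRUE), sep = ","), con)
  invisible(path)
}

#' The bundled background-mortality life table
#'
#' Annual all-population mortality for ages 65-100. The bundled file is a
#' synthetic Gompertz-style emulation of a recent US period life table
#' (matching its order of magnitude at the range endpoints), not a transcription
#' of published values; see the file header and the methods vignette.
#'
#' @return a `cea_lifetable` for ages 65-100.
#' @export
builtin_lifetable <- function() {
  path <- system.file("extdata", "lifetable_us2015_synthetic.csv",
                      package = "crlmcea")
  if (path == "") stop("bundled life table not found")
  load_lifetable(path)
}
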