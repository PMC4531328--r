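# CSV table I/O.  Every table the package reads or writes is a headed CSV
# with a documented column schema; cells must be plain numerics (decimal
# point, no locale).  Validation reports the offending row and column.

read_numeric_csv <- function(path, columns, optional = character(0)) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols)) {
    stop_validation(sprintf("%s: missing required column(s): %s",
                            path, paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), c(columns, optional))
  if (length(extra)) {
    stop_validation(sprintf("%s: unexpected column(s): %s",
                            path, paste(extra, collapse = ", ")))
  }
  keep <- c(columns, intersect(optional, names(raw)))
  out <- raw[keep]
  for (col in keep) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !(out[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stop_validation(sprintf("%s: non-numeric cell at row %d, column '%s': \"%s\"",
                              path, bad[1], col, raw[[col]][bad[1]]))
    }
    out[[col]] <- vals
  }
  out
}

#' Read a calibration table
#'
#' Generic (x, y) calibration pairs -- e.g. (Z, LET_U) or
#' (alpha_L, alpha_H) -- from a CSV with columns `x`, `y` and an optional
#' nonnegative `weight`.
#'
#' @param path CSV file path.
#' @return A data frame with numeric columns `x`, `y` (and `weight` when
#'   present).  An empty data section yields zero rows without error.
#' @export
read_calibration_table <- function(path) {
  out <- read_numeric_csv(path, c("x", "y"), optional = "weight")
  if ("weight" %in% names(out) && any(out$weight < 0, na.rm = TRUE)) {
    stop_validation(sprintf("%s: 'weight' must be nonnegative", path))
  }
  out
}

#' Read a clonogenic survival table
#'
#' @param path CSV file with columns `dose`, `sf` and optional `weight`.
#' @return A data frame with numeric columns.
#' @export
read_survival_table <- function(path) {
  read_numeric_csv(path, c("dose", "sf"), optional = "weight")
}

#' Read a one-column LET grid
#'
#' @param path CSV file with single column `let`.
#' @return Numeric vector of LET values, keV/um.
#' @export
read_let_grid <- function(path) {
  read_numeric_csv(path, "let")$let
}

#' Write a table to CSV at full numeric precision
#'
#' Numeric columns are formatted with 15 significant digits so a
#' write-then-read round trip preserves values to at least 12 significant
#' digits.
#'
#' @param x A data frame.
#' @param path Output CSV path (or `""` for standard output).
#' @return Invisibly, `x`.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- x
  for (col in names(fmt)) {
    if (is.numeric(fmt[[col]])) {
      fmt[[col]] <- formatC(fmt[[col]], digits = 15, format = "g")
    }
  }
  utils::write.csv(fmt, file = path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Bundled charge/turnover-LET calibration table
#'
#' The four (Z, LET_U) pairs available from pooled published survival
#' experiments that localise the turnover point well enough to calibrate
#' the Z-saturation relation: protons 30.5, helium 103.4, carbon 208 and
#' neon 233 keV/um.  These points are the default calibration data for
#' [fit_z_saturation()] and the source of the package's default
#' Z-saturation constants.
#'
#' @return A data frame with columns `z` (1, 2, 6, 10) and `let_u`
#'   (keV/um).
#' @export
#' @examples
#' z_letu_calibration()
z_letu_calibration <- function() {
  path <- system.file("extdata", "z_letu_calibration.csv", package = "rbelet",
                      mustWork = TRUE)
  out <- read_numeric_csv(path, c("z", "let_u"))
  out
}
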