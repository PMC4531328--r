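#' Fractionation schedule
#'
#' @param n Number of fractions, positive integer.
#' @param d Dose per fraction, Gy, > 0.
#' @param ab_ratio Alpha/beta ratio of the low-LET reference tissue, Gy, > 0.
#' @return A `schedule` object; `total_dose = n * d` is precomputed.
#' @export
#' @examples
#' s <- schedule(n = 30, d = 2, ab_ratio = 3)
#' bed_low(s)   # 100 Gy
schedule <- function(n, d, ab_ratio) {
  check_scalar(n, "n", positive = TRUE)
  if (n != round(n)) stop_validation("'n' must be a whole number of fractions")
  check_scalar(d, "d", positive = TRUE)
  check_scalar(ab_ratio, "ab_ratio", positive = TRUE)
  structure(list(n = as.integer(n), d = d, ab_ratio = ab_ratio,
                 total_dose = n * d),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d x %g Gy (total %g Gy), alpha/beta = %g Gy, BED = %g Gy\n",
              x$n, x$d, x$total_dose, x$ab_ratio, bed_low(x)))
  invisible(x)
}

#' Biologically effective dose of a low-LET schedule
#'
#' \eqn{BED = n\,d\,(1 + d/(\alpha/\beta))}, the standard
#' fractionation-corrected effect measure for the low-LET arm of an
#' iso-effect comparison.
#'
#' @param s A [schedule()].
#' @return BED in Gy.
#' @export
bed_low <- function(s) {
  stopifnot(inherits(s, "schedule"))
  s$n * s$d * (1 + s$d / s$ab_ratio)
}

#' High-LET dose per fraction matching a target BED
#'
#' Solves the high-LET BED equation
#' \deqn{m\,d_H\,[RBE_{max} + RBE_{min}^2\, d_H/(\alpha/\beta)_L] = BED}
#' for the dose per fraction \eqn{d_H} of an `m`-fraction high-LET schedule
#' iso-effective with a low-LET treatment of the given BED.  The unique
#' positive root of the quadratic
#' \eqn{(m\,RBE_{min}^2/(\alpha/\beta)_L)\,d_H^2 + m\,RBE_{max}\,d_H - BED = 0}
#' is returned; when \eqn{RBE_{min} = 0} the equation is linear.
#'
#' @param bed Target BED, Gy, > 0.
#' @param m Number of high-LET fractions, >= 1.
#' @param limits An `rbe_limits` object ([rbe_limits()] or
#'   [make_rbe_limits()]).
#' @param ab_ratio Low-LET alpha/beta ratio, Gy, > 0.
#' @return High-LET dose per fraction, Gy.
#' @export
solve_high_let_dose <- function(bed, m, limits, ab_ratio) {
  stopifnot(inherits(limits, "rbe_limits"))
  check_scalar(bed, "bed", positive = TRUE)
  check_scalar(m, "m", positive = TRUE)
  check_scalar(ab_ratio, "ab_ratio", positive = TRUE)
  if (limits$rbe_max <= 0 && limits$rbe_min <= 0) {
    stop_validation("rbe_max and rbe_min cannot both be zero: no dose attains the BED")
  }
  a <- m * limits$rbe_min^2 / ab_ratio
  b <- m * limits$rbe_max
  if (a == 0) return(bed / b)
  (-b + sqrt(b^2 + 4 * a * bed)) / (2 * a)
}

#' Iso-effective high-LET dose table across fraction numbers
#'
#' For each candidate number of high-LET fractions, solves the BED
#' iso-effect equation against a low-LET reference schedule and tabulates
#' the dose per fraction and total dose.  With `rbe_max > rbe_min` the
#' total high-LET dose rises with the number of fractions
#' (fractionation sparing).
#'
#' @param reference Low-LET reference [schedule()].
#' @param m_values Integer vector of high-LET fraction numbers, all >= 1.
#' @param limits An `rbe_limits` object for the high-LET beam quality.
#' @return A data frame with columns `m`, `d_h` (Gy per fraction) and
#'   `total_dose` (Gy); the reference BED is attached as attribute `"bed"`.
#' @export
#' @examples
#' ref <- schedule(30, 2, 3)
#' isoeffect_table(ref, m_values = c(5, 10, 20, 30),
#'                 limits = make_rbe_limits(rbe_max = 3, rbe_min = 1.2))
isoeffect_table <- function(reference, m_values, limits) {
  stopifnot(inherits(reference, "schedule"))
  check_numeric_vec(m_values, "m_values")
  if (any(m_values < 1) || any(m_values != round(m_values))) {
    stop_validation("'m_values' must be whole numbers >= 1")
  }
  bed <- bed_low(reference)
  d_h <- vapply(m_values, function(m) {
    solve_high_let_dose(bed, m, limits, reference$ab_ratio)
  }, numeric(1))
  out <- data.frame(m = as.integer(m_values), d_h = d_h,
                    total_dose = m_values * d_h)
  attr(out, "bed") <- bed
  out
}
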