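#' Linear-quadratic radiosensitivity pair
#'
#' @param alpha Linear coefficient, Gy^-1, >= 0.
#' @param beta Quadratic coefficient, Gy^-2, >= 0.
#' @return An `lq_params` object (list with `alpha`, `beta`).
#' @export
#' @examples
#' lq_params(0.16, 0.046)
lq_params <- function(alpha, beta) {
  check_scalar(alpha, "alpha", nonneg = TRUE)
  check_scalar(beta, "beta", nonneg = TRUE)
  structure(list(alpha = alpha, beta = beta), class = "lq_params")
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf("LQ parameters: alpha = %g Gy^-1, beta = %g Gy^-2 (alpha/beta = %g Gy)\n",
              x$alpha, x$beta, if (x$beta > 0) x$alpha / x$beta else Inf))
  invisible(x)
}

#' Dose producing a given LQ effect
#'
#' Solves \eqn{\alpha d + \beta d^2 = E} for the unique positive dose:
#' \eqn{d = (-\alpha + \sqrt{\alpha^2 + 4\beta E})/(2\beta)} for
#' \eqn{\beta > 0}, and \eqn{E/\alpha} for \eqn{\beta = 0}.  The negative
#' quadratic root is never physical for positive effect.
#'
#' @param effect LQ effect value(s) \eqn{E = -\ln SF}; must be > 0.
#' @param lq An [lq_params()] object with `alpha > 0` or `beta > 0`.
#' @return Dose(s) in Gy.
#' @export
solve_lq_dose <- function(effect, lq) {
  stopifnot(inherits(lq, "lq_params"))
  check_numeric_vec(effect, "effect")
  if (any(effect <= 0)) stop_validation("'effect' must be > 0")
  if (lq$alpha == 0 && lq$beta == 0) {
    stop_validation("alpha and beta cannot both be zero: no dose produces the effect")
  }
  if (lq$beta == 0) {
    effect / lq$alpha
  } else {
    (-lq$alpha + sqrt(lq$alpha^2 + 4 * lq$beta * effect)) / (2 * lq$beta)
  }
}

new_rbe_result <- function(d_h, d_l, effect, rbe = d_l / d_h, limit = FALSE) {
  structure(
    list(d_h = d_h, d_l = d_l, rbe = rbe,
         effect = effect, sf = exp(-effect), limit = limit),
    class = "rbe_result"
  )
}

#' @export
print.rbe_result <- function(x, ...) {
  if (x$limit) {
    cat(sprintf("RBE = %.4f (zero-dose analytic limit alpha_H/alpha_L)\n", x$rbe))
  } else {
    cat(sprintf("RBE = %.4f at high-LET dose %.4g Gy (iso-effective low-LET dose %.4g Gy)\n",
                x$rbe, x$d_h, x$d_l))
    cat(sprintf("  effect E = %.4g, surviving fraction = %.4g\n", x$effect, x$sf))
  }
  invisible(x)
}

#' RBE at a given high-LET dose
#'
#' Solves the LQ iso-effect equation
#' \eqn{\alpha_L d_L + \beta_L d_L^2 = \alpha_H d_H + \beta_H d_H^2}
#' for the low-LET dose producing the same effect as the high-LET dose
#' `d_h`, and returns the ratio \eqn{RBE = d_L/d_H}.
#'
#' @param d_h High-LET dose, Gy, > 0.
#' @param lq_low Low-LET control [lq_params()] (`alpha > 0`).
#' @param lq_high High-LET [lq_params()] at the LET of interest
#'   (\eqn{\alpha_H}, \eqn{\beta_H}).
#' @return An `rbe_result`: fields `d_h`, `d_l`, `rbe`, `effect`, `sf`,
#'   `limit` (FALSE here).
#' @export
#' @examples
#' low  <- lq_params(0.16, 0.046)
#' high <- lq_params(1.31, 0.15)
#' rbe_at_dose(0.5, low, high)
rbe_at_dose <- function(d_h, lq_low, lq_high) {
  stopifnot(inherits(lq_low, "lq_params"), inherits(lq_high, "lq_params"))
  check_scalar(d_h, "d_h", positive = TRUE)
  effect <- lq_high$alpha * d_h + lq_high$beta * d_h^2
  if (effect <= 0) {
    stop_validation("high-LET parameters produce zero effect at this dose")
  }
  d_l <- solve_lq_dose(effect, lq_low)
  new_rbe_result(d_h, d_l, effect)
}

#' RBE at a given surviving fraction
#'
#' Converts a survival level to the LQ effect \eqn{E = -\ln SF}, solves both
#' the high- and low-LET dose at that effect and returns their ratio.  At
#' `sf = 1` (zero dose) the iso-effect equation degenerates; the analytic
#' low-dose limit \eqn{RBE_{max} = \alpha_H/\alpha_L} is returned instead,
#' flagged by `limit = TRUE` in the result.
#'
#' @param sf Surviving fraction in (0, 1].
#' @inheritParams rbe_at_dose
#' @return An `rbe_result`.
#' @export
rbe_at_sf <- function(sf, lq_low, lq_high) {
  stopifnot(inherits(lq_low, "lq_params"), inherits(lq_high, "lq_params"))
  check_scalar(sf, "sf", positive = TRUE)
  if (sf > 1) stop_validation("'sf' must lie in (0, 1]")
  if (sf == 1) {
    if (lq_low$alpha <= 0) stop_validation("zero-dose RBE limit needs alpha_L > 0")
    return(new_rbe_result(0, 0, 0, rbe = lq_high$alpha / lq_low$alpha, limit = TRUE))
  }
  effect <- -log(sf)
  d_h <- solve_lq_dose(effect, lq_high)
  d_l <- solve_lq_dose(effect, lq_low)
  new_rbe_result(d_h, d_l, effect)
}

#' Dose-limit RBE values
#'
#' The RBE of an LQ iso-effect comparison is bracketed by two closed forms:
#' \eqn{RBE_{max} = \alpha_H/\alpha_L} as dose tends to zero and
#' \eqn{RBE_{min} = \sqrt{\beta_H/\beta_L}} as dose tends to infinity.
#' RBE_max is inversely related to the low-LET \eqn{\alpha/\beta} ratio,
#' RBE_min directly proportional to its square root.  No ordering between
#' the two is assumed; both are simply computed.
#'
#' @inheritParams rbe_at_dose
#' @return An `rbe_limits` object: fields `rbe_max`, `rbe_min`.
#' @export
rbe_limits <- function(lq_low, lq_high) {
  stopifnot(inherits(lq_low, "lq_params"), inherits(lq_high, "lq_params"))
  if (lq_low$alpha <= 0) stop_validation("'lq_low$alpha' must be > 0 for RBE_max")
  if (lq_low$beta <= 0) stop_validation("'lq_low$beta' must be > 0 for RBE_min")
  structure(
    list(rbe_max = lq_high$alpha / lq_low$alpha,
         rbe_min = sqrt(lq_high$beta / lq_low$beta)),
    class = "rbe_limits"
  )
}

#' @export
print.rbe_limits <- function(x, ...) {
  cat(sprintf("RBE limits: RBE_max = %.4f (dose -> 0), RBE_min = %.4f (dose -> Inf)\n",
              x$rbe_max, x$rbe_min))
  invisible(x)
}

#' Construct rbe_limits directly from the two limiting values
#'
#' Convenience constructor for fractionation calculations where the limits
#' are known rather than derived from LQ pairs.
#'
#' @param rbe_max Zero-dose RBE limit, > 0.
#' @param rbe_min Infinite-dose RBE limit, >= 0.
#' @return An `rbe_limits` object.
#' @export
make_rbe_limits <- function(rbe_max, rbe_min) {
  check_scalar(rbe_max, "rbe_max", positive = TRUE)
  check_scalar(rbe_min, "rbe_min", nonneg = TRUE)
  structure(list(rbe_max = rbe_max, rbe_min = rbe_min), class = "rbe_limits")
}

#' LET-RBE curve for one ion
#'
#' Runs the full model pipeline over an LET grid: turnover LET from the ion
#' charge (saturation relation), turnover radiosensitivities from the
#' low-LET control values (saturation relations), efficiency-scaled
#' \eqn{\alpha_H}, \eqn{\beta_H} per LET, and finally the RBE at the
#' requested dose or survival level.  Any of `let_u`, `alpha_u`, `beta_u`
#' may be pinned by the caller (as is done when matching a specific
#' experimental data set) to bypass the corresponding saturation relation.
#'
#' @param let Numeric vector of LET values, keV/um (all >= `let_c`).
#' @param lq_low Low-LET control [lq_params()].
#' @param z Ion charge number (>= 1); needed unless `let_u` is supplied.
#' @param dose High-LET dose per evaluation, Gy.  Exactly one of `dose`,
#'   `sf` must be given.
#' @param sf Surviving fraction at which to evaluate RBE.
#' @param let_u,alpha_u,beta_u Optional pinned turnover values overriding
#'   the saturation relations.
#' @param config A [model_config()] supplying the saturation constants and
#'   `let_c`/post-turnover defaults.
#' @return A data frame with columns `let`, `efficiency`, `alpha_h`,
#'   `beta_h`, `rbe`.  The `let_response` used is attached as attribute
#'   `"response"`.
#' @export
#' @examples
#' curve <- rbe_curve(let = c(10, 60, 120, 240), lq_low = lq_params(0.14, 0.05),
#'                    z = 6, dose = 1.5)
#' curve
rbe_curve <- function(let, lq_low, z = NULL, dose = NULL, sf = NULL,
                      let_u = NULL, alpha_u = NULL, beta_u = NULL,
                      config = model_config()) {
  stopifnot(inherits(lq_low, "lq_params"), inherits(config, "rbelet_config"))
  if (is.null(dose) == is.null(sf)) {
    stop_validation("exactly one of 'dose' or 'sf' must be supplied")
  }
  if (is.null(let_u)) {
    if (is.null(z)) stop_validation("supply either 'z' or a pinned 'let_u'")
    let_u <- let_u_from_z(z, z_params_from_config(config))
  }
  if (is.null(alpha_u)) {
    alpha_u <- alpha_u_from_alpha_l(lq_low$alpha, alpha_params_from_config(config))
  }
  if (is.null(beta_u)) {
    beta_u <- beta_u_from_beta_l(lq_low$beta, beta_params_from_config(config))
  }
  resp <- let_response(alpha_l = lq_low$alpha, beta_l = lq_low$beta,
                       alpha_u = alpha_u, beta_u = beta_u,
                       let_u = let_u, let_c = config$let_c, z = z)
  tab <- let_scaling_table(let, resp, config$post_turnover)
  tab$rbe <- vapply(seq_len(nrow(tab)), function(i) {
    lq_high <- lq_params(tab$alpha_h[i], tab$beta_h[i])
    if (is.null(sf)) {
      rbe_at_dose(dose, lq_low, lq_high)$rbe
    } else {
      rbe_at_sf(sf, lq_low, lq_high)$rbe
    }
  }, numeric(1))
  attr(tab, "response") <- resp
  tab
}
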