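#' Assembled LET response of a cell system to one ion
#'
#' Bundles everything needed to evaluate the radiosensitivities
#' \eqn{\alpha_H}, \eqn{\beta_H} at an arbitrary LET: the control (low-LET)
#' LQ parameters, the turnover-point LQ parameters, the turnover LET
#' \eqn{LET_U} and the control LET \eqn{LET_C}.
#'
#' @param alpha_l,beta_l Low-LET control LQ parameters (Gy^-1, Gy^-2);
#'   `alpha_l` must be positive (RBE_max divides by it), `beta_l` >= 0.
#' @param alpha_u,beta_u Turnover-point LQ parameters; must satisfy
#'   `alpha_u >= alpha_l` and `beta_u >= beta_l`.
#' @param let_u Turnover LET, keV/um.
#' @param let_c Control (reference) LET, keV/um; default 1.2, a megavoltage
#'   photon value.  Must satisfy `0 < let_c < let_u`.
#' @param z Optional ion charge number, carried for bookkeeping.
#' @return A `let_response` object.
#' @seealso [alpha_h()], [beta_h()], [let_efficiency()], [rbe_curve()]
#' @export
#' @examples
#' resp <- let_response(alpha_l = 0.3, beta_l = 0.046,
#'                      alpha_u = 1.3, beta_u = 0.15, let_u = 120)
#' alpha_h(60, resp)
let_response <- function(alpha_l, beta_l, alpha_u, beta_u, let_u,
                         let_c = 1.2, z = NULL) {
  check_scalar(alpha_l, "alpha_l", positive = TRUE)
  check_scalar(beta_l, "beta_l", nonneg = TRUE)
  check_scalar(alpha_u, "alpha_u", positive = TRUE)
  check_scalar(beta_u, "beta_u", nonneg = TRUE)
  check_scalar(let_u, "let_u", positive = TRUE)
  check_scalar(let_c, "let_c", positive = TRUE)
  if (let_c >= let_u) {
    stop_validation(sprintf(
      "'let_c' (%g) must lie below the turnover LET 'let_u' (%g)", let_c, let_u))
  }
  if (alpha_u < alpha_l) {
    stop_validation("'alpha_u' must be >= 'alpha_l': the turnover alpha is the maximum")
  }
  if (beta_u < beta_l) {
    stop_validation("'beta_u' must be >= 'beta_l': the turnover beta is the maximum")
  }
  if (!is.null(z)) check_scalar(z, "z", positive = TRUE)
  structure(
    list(z = z, let_u = let_u, let_c = let_c,
         lq_low = lq_params(alpha_l, beta_l),
         lq_turn = lq_params(alpha_u, beta_u)),
    class = "let_response"
  )
}

#' @export
print.let_response <- function(x, ...) {
  cat("LET response\n")
  if (!is.null(x$z)) cat(sprintf("  ion charge Z: %g\n", x$z))
  cat(sprintf("  LET_C = %g, LET_U = %g keV/um\n", x$let_c, x$let_u))
  cat(sprintf("  low-LET : alpha = %g Gy^-1, beta = %g Gy^-2\n",
              x$lq_low$alpha, x$lq_low$beta))
  cat(sprintf("  turnover: alpha = %g Gy^-1, beta = %g Gy^-2\n",
              x$lq_turn$alpha, x$lq_turn$beta))
  invisible(x)
}

#' Energy-transfer efficiency of cell kill at a given LET
#'
#' The core of the model: the fraction of its maximum effect that deposited
#' energy achieves at LET \eqn{LET_x}.  Efficiency rises linearly from 0 at
#' the control LET to 1 (100\%) at the turnover LET,
#' \deqn{(LET_x - LET_C)/(LET_U - LET_C),}
#' then, energy beyond the turnover point being wasted ("overkill"),
#' declines.  Two post-turnover forms are available:
#' * `"reciprocal"` (default): efficiency \eqn{= LET_U / LET_x}, the form
#'   both worked examples of the source model follow (e.g. LET 240 with
#'   turnover 120 is exactly 50\% efficient); decays asymptotically to 0.
#' * `"strict"`: \eqn{1 - (LET_x - LET_U)/LET_U}, the displayed biphasic
#'   formula, clamped at 0 (it would otherwise go negative beyond
#'   \eqn{2\,LET_U}).
#'
#' Both branches equal 1 exactly at `let_u`, so the curve is continuous.
#'
#' @param let_x LET value(s), keV/um; must be >= `resp$let_c` (the model is
#'   undefined below the control quality).
#' @param resp A [let_response()] object.
#' @param post_turnover `"reciprocal"` or `"strict"`.
#' @return Efficiency fraction(s) in (0, 1].
#' @export
let_efficiency <- function(let_x, resp, post_turnover = c("reciprocal", "strict")) {
  stopifnot(inherits(resp, "let_response"))
  post_turnover <- match.arg(post_turnover)
  check_numeric_vec(let_x, "let_x")
  if (any(let_x < resp$let_c)) {
    stop_validation(sprintf(
      "'let_x' must be >= the control LET let_c = %g keV/um", resp$let_c))
  }
  pre <- (let_x - resp$let_c) / (resp$let_u - resp$let_c)
  post <- if (post_turnover == "reciprocal") {
    resp$let_u / let_x
  } else {
    pmax(0, 1 - (let_x - resp$let_u) / resp$let_u)
  }
  ifelse(let_x <= resp$let_u, pre, post)
}

#' Alpha radiosensitivity at an arbitrary LET
#'
#' Scales alpha between its control and turnover values by the
#' energy-transfer efficiency:
#' \eqn{\alpha_H = \alpha_L + \mathrm{eff}(LET_x)\,(\alpha_U - \alpha_L)}.
#' Maximal (equal to \eqn{\alpha_U}) exactly at the turnover LET.
#'
#' @inheritParams let_efficiency
#' @return \eqn{\alpha_H} value(s), Gy^-1.
#' @export
alpha_h <- function(let_x, resp, post_turnover = c("reciprocal", "strict")) {
  eff <- let_efficiency(let_x, resp, post_turnover)
  resp$lq_low$alpha + eff * (resp$lq_turn$alpha - resp$lq_low$alpha)
}

#' Beta radiosensitivity at an arbitrary LET
#'
#' Identical proportionate scaling as [alpha_h()], with beta in place of
#' alpha and the SAME efficiency function and turnover LET -- the symmetry
#' that keeps the turnover position independent of dose.
#'
#' @inheritParams let_efficiency
#' @return \eqn{\beta_H} value(s), Gy^-2.
#' @export
beta_h <- function(let_x, resp, post_turnover = c("reciprocal", "strict")) {
  eff <- let_efficiency(let_x, resp, post_turnover)
  resp$lq_low$beta + eff * (resp$lq_turn$beta - resp$lq_low$beta)
}

#' Tabulate efficiency and scaled radiosensitivities over an LET grid
#'
#' @param let Numeric vector of LET values, keV/um.
#' @inheritParams let_efficiency
#' @return A data frame with columns `let`, `efficiency`, `alpha_h`,
#'   `beta_h`, one row per grid point.
#' @export
let_scaling_table <- function(let, resp, post_turnover = c("reciprocal", "strict")) {
  post_turnover <- match.arg(post_turnover)
  data.frame(
    let = let,
    efficiency = let_efficiency(let, resp, post_turnover),
    alpha_h = alpha_h(let, resp, post_turnover),
    beta_h = beta_h(let, resp, post_turnover)
  )
}
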