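#' Saturation parameters for the charge to turnover-LET relation
#'
#' The LET at which radiosensitivity (and hence RBE) peaks -- the turnover
#' point \eqn{LET_U} -- increases with the nuclear charge \eqn{Z} of the ion,
#' but with diminishing increments: a saturation effect.  The relation is the
#' solution of the rate equation \eqn{dLET_U/dZ = S - k\,LET_U}, anchored at
#' the proton value, giving
#' \deqn{LET_U(Z) = LET_U(1) + (S/k)\,(1 - e^{-k(Z-1)}).}
#'
#' @param S Initial slope of \eqn{LET_U} with Z (keV/um per unit charge); > 0.
#' @param k Rate constant of the saturation (per unit charge); > 0.
#' @param anchor_let \eqn{LET_U} at Z = 1, keV/um.  Default 30.5, the proton
#'   turnover LET used to anchor the relation.
#'
#' @return An object of class `z_saturation_params` with fields `S`, `k`,
#'   `anchor_let` and the derived `asymptote = anchor_let + S/k`.
#' @seealso [let_u_from_z()], [fit_z_saturation()]
#' @export
#' @examples
#' p <- z_saturation_params(S = 86.8, k = 0.423)
#' let_u_from_z(c(1, 2, 6, 10), p)
z_saturation_params <- function(S, k, anchor_let = 30.5) {
  check_scalar(S, "S", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(anchor_let, "anchor_let", positive = TRUE)
  structure(
    list(S = S, k = k, anchor_let = anchor_let, asymptote = anchor_let + S / k),
    class = "z_saturation_params"
  )
}

#' @export
print.z_saturation_params <- function(x, ...) {
  cat("Z -> LET_U saturation parameters\n")
  cat(sprintf("  anchor LET_U(Z=1): %.4g keV/um\n", x$anchor_let))
  cat(sprintf("  initial slope S:   %.6g keV/um per unit Z\n", x$S))
  cat(sprintf("  rate constant k:   %.6g per unit Z\n", x$k))
  cat(sprintf("  asymptote:         %.6g keV/um\n", x$asymptote))
  invisible(x)
}

#' Turnover LET for an ion of charge Z
#'
#' Evaluates the anchored saturation relation
#' \eqn{LET_U = LET_U(1) + (S/k)(1 - e^{-k(Z-1)})}.  Z is treated as a
#' continuous variable of at least 1; ion species correspond to integer
#' values (proton 1, helium 2, carbon 6, neon 10, argon 18).
#'
#' @param z Ion charge number(s), real, >= 1.
#' @param params A [z_saturation_params()] object.  `NULL` (default) uses the
#'   package calibration fitted to the bundled four-ion turnover table (see
#'   [z_letu_calibration()]).
#' @return Turnover LET values in keV/um, same length as `z`.  Strictly
#'   increasing and concave in `z`, bounded above by `anchor_let + S/k`.
#' @export
let_u_from_z <- function(z, params = NULL) {
  if (is.null(params)) params <- default_z_params()
  stopifnot(inherits(params, "z_saturation_params"))
  check_numeric_vec(z, "z")
  if (any(z < 1)) {
    stop_validation("'z' must be >= 1: the relation is anchored at the proton (Z = 1)")
  }
  params$anchor_let + (params$S / params$k) * (1 - exp(-params$k * (z - 1)))
}

#' Saturation parameters for alpha at the turnover point
#'
#' The maximum linear radiosensitivity \eqn{\alpha_U}, attained at the
#' turnover LET, saturates with the low-LET control value \eqn{\alpha_L}:
#' cells with small (radio-resistant) \eqn{\alpha_L} show the largest gain.
#' Two forms are supported:
#' * `"linear"` (default): a no-intercept proportionality
#'   \eqn{\alpha_U = c\,\alpha_L} with `c = 6.47`, the ion-beam regression
#'   coefficient valid for \eqn{\alpha_L < 0.35} Gy^-1.
#' * `"nonlinear"`: \eqn{\alpha_U = (A/j)(1 - e^{-j\alpha_L})}, the solution
#'   of \eqn{d\alpha_U/d\alpha_L = A - j\alpha_U}.  No ion-beam `A`, `j` are
#'   published, so this mode requires user-supplied values (or a fit via
#'   [fit_alpha_saturation()]).
#'
#' @param mode `"linear"` or `"nonlinear"`.
#' @param c Proportionality coefficient for linear mode; must exceed 1.
#' @param A Initial slope (dimensionless) for nonlinear mode; > 0.
#' @param j Rate constant (Gy) for nonlinear mode; > 0.
#' @return An `alpha_saturation_params` object.
#' @seealso [alpha_u_from_alpha_l()], [neutron_presets()]
#' @export
alpha_saturation_params <- function(mode = c("linear", "nonlinear"),
                                    c = 6.47, A = NULL, j = NULL) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    check_scalar(c, "c", positive = TRUE)
    if (c <= 1) stop_validation("'c' must be > 1: alpha_U below alpha_L is unphysical")
    out <- list(mode = mode, c = c, A = NULL, j = NULL, asymptote = Inf)
  } else {
    if (is.null(A) || is.null(j)) {
      stop_validation("nonlinear alpha mode requires both 'A' and 'j' (no published ion-beam defaults exist)")
    }
    check_scalar(A, "A", positive = TRUE)
    check_scalar(j, "j", positive = TRUE)
    out <- list(mode = mode, c = NULL, A = A, j = j, asymptote = A / j)
  }
  structure(out, class = "alpha_saturation_params")
}

#' Saturation parameters for beta at the turnover point
#'
#' The quadratic radiosensitivity \eqn{\beta} increases with LET far less
#' than \eqn{\alpha}.  Modes:
#' * `"nonlinear"` (default): \eqn{\beta_U = (R/u)(1 - e^{-u\beta_L})} with
#'   R = 2.5, u = 25, giving a modest increase with ceiling
#'   \eqn{R/u = 0.1} Gy^-2.
#' * `"linear"`: no-intercept proportionality \eqn{\beta_U = c\,\beta_L}.
#' * `"constant"`: \eqn{\beta_U = \beta_L}, for low-dose work where
#'   beta-related kill is negligible.
#'
#' @param mode One of `"nonlinear"`, `"linear"`, `"constant"`.
#' @param R Initial slope (dimensionless), nonlinear mode; > 0.
#' @param u Rate constant (Gy^2), nonlinear mode; > 0.
#' @param c Coefficient for linear mode; > 0.
#' @return A `beta_saturation_params` object.
#' @export
beta_saturation_params <- function(mode = c("nonlinear", "linear", "constant"),
                                   R = 2.5, u = 25, c = NULL) {
  mode <- match.arg(mode)
  out <- switch(mode,
    nonlinear = {
      check_scalar(R, "R", positive = TRUE)
      check_scalar(u, "u", positive = TRUE)
      list(mode = mode, R = R, u = u, c = NULL, asymptote = R / u)
    },
    linear = {
      if (is.null(c)) stop_validation("linear beta mode requires coefficient 'c'")
      check_scalar(c, "c", positive = TRUE)
      list(mode = mode, R = NULL, u = NULL, c = c, asymptote = Inf)
    },
    constant = list(mode = mode, R = NULL, u = NULL, c = 1, asymptote = Inf)
  )
  structure(out, class = "beta_saturation_params")
}

#' Turnover-point alpha from the low-LET control alpha
#'
#' @param alpha_l Low-LET alpha value(s), Gy^-1, >= 0.
#' @param params An [alpha_saturation_params()] object; default linear mode
#'   with c = 6.47.
#' @return \eqn{\alpha_U} values, Gy^-1.  The formula value is returned as
#'   is; callers wanting the physical ordering \eqn{\alpha_U > \alpha_L}
#'   must check it (see [let_response()]).
#' @export
alpha_u_from_alpha_l <- function(alpha_l, params = alpha_saturation_params()) {
  stopifnot(inherits(params, "alpha_saturation_params"))
  check_numeric_vec(alpha_l, "alpha_l", nonneg = TRUE)
  if (params$mode == "linear") {
    params$c * alpha_l
  } else {
    (params$A / params$j) * (1 - exp(-params$j * alpha_l))
  }
}

#' Turnover-point beta from the low-LET control beta
#'
#' @param beta_l Low-LET beta value(s), Gy^-2, >= 0.
#' @param params A [beta_saturation_params()] object; default nonlinear mode
#'   with R = 2.5, u = 25 (ceiling 0.1 Gy^-2).
#' @return \eqn{\beta_U} values, Gy^-2.
#' @export
beta_u_from_beta_l <- function(beta_l, params = beta_saturation_params()) {
  stopifnot(inherits(params, "beta_saturation_params"))
  check_numeric_vec(beta_l, "beta_l", nonneg = TRUE)
  switch(params$mode,
    nonlinear = (params$R / params$u) * (1 - exp(-params$u * beta_l)),
    linear = params$c * beta_l,
    constant = beta_l
  )
}

#' Fast-neutron radiosensitivity scaling presets
#'
#' Regression coefficients relating megavoltage X-ray radiosensitivities to
#' their 64 MV fast-neutron counterparts: linear no-intercept and nonlinear
#' saturation fits for both alpha and beta.  Shipped for reference and for
#' neutron-beam work only.
#'
#' @section Caveat: The turnover values \eqn{\alpha_U}, \eqn{\beta_U} of ion
#'   beams exceed the fast-neutron maxima, because the neutron LET spectrum
#'   need not sit at the ion turnover LET; these presets must NOT be used to
#'   derive ion-beam RBE.
#'
#' @return A named list of saturation parameter objects:
#'   `alpha_linear` (c = 2.72), `alpha_nonlinear` (A = 5.37, j = 3.68),
#'   `beta_linear` (c = 1.57), `beta_nonlinear` (R = 2.29, u = 23.57).
#'   The list carries attribute `ion_beam = FALSE`.
#' @export
neutron_presets <- function() {
  structure(
    list(
      alpha_linear = alpha_saturation_params("linear", c = 2.72),
      alpha_nonlinear = alpha_saturation_params("nonlinear", A = 5.37, j = 3.68),
      beta_linear = beta_saturation_params("linear", c = 1.57),
      beta_nonlinear = beta_saturation_params("nonlinear", R = 2.29, u = 23.57)
    ),
    ion_beam = FALSE
  )
}
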