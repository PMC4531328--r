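#' @name fitting
#' @title Deterministic least-squares calibration of the saturation relations
#' @description
#' All saturation fits share one numerical scheme.  The models are of the
#' form \eqn{y = y_0 + M\,(1 - e^{-r (x - x_0)})} with amplitude \eqn{M} and
#' rate \eqn{r}.  For fixed \eqn{r} the optimal amplitude is linear and has
#' the closed form \eqn{M(r) = \sum w\,\tilde y\,g / \sum w\,g^2} with
#' \eqn{g = 1 - e^{-r(x - x_0)}}, so the residual sum of squares is profiled
#' to a one-dimensional function of \eqn{r}.  That profile is scanned on a
#' log-spaced grid of rate constants (1e-3 to 100, wide enough to bracket
#' every rate the model works with, from Z-saturation ~0.4 to the beta rate
#' constants ~25) and polished with a golden-section/parabolic search
#' bracketed by the best grid neighbours.  The
#' scheme is deterministic, needs no starting guess from the user, and the
#' profiled optimum is the exact joint least-squares optimum.
NULL

fit_report <- function(estimate, residuals, weights, converged, n_iter) {
  structure(
    list(estimate = estimate,
         rss = sum(weights * residuals^2),
         residuals = residuals,
         converged = converged,
         n_iterations = n_iter),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Least-squares fit report\n")
  cat("  estimate:", paste(sprintf("%s = %.6g", names(x$estimate), x$estimate),
                           collapse = ", "), "\n")
  cat(sprintf("  RSS = %.6g over %d points; converged: %s (%d evaluations)\n",
              x$rss, length(x$residuals), x$converged, x$n_iterations))
  invisible(x)
}

# Profiled 1-D least squares for y = y0 + M (1 - exp(-r (x - x0))).
# Returns list(M, r, report).  Deterministic: log grid scan + optimize().
profile_exp_fit <- function(x, y, w, x0 = 0, y0 = 0,
                            rate_range = c(1e-3, 100), n_grid = 161L) {
  yy <- y - y0
  n_eval <- 0L
  amp_for <- function(r) {
    g <- 1 - exp(-r * (x - x0))
    s2 <- sum(w * g^2)
    if (s2 == 0) return(NA_real_)
    sum(w * yy * g) / s2
  }
  rss_for <- function(r) {
    n_eval <<- n_eval + 1L
    M <- amp_for(r)
    if (!is.finite(M)) return(Inf)
    g <- 1 - exp(-r * (x - x0))
    sum(w * (M * g - yy)^2)
  }
  grid <- exp(seq(log(rate_range[1]), log(rate_range[2]), length.out = n_grid))
  prof <- vapply(grid, rss_for, numeric(1))
  i <- which.min(prof)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(rss_for, lower = lo, upper = hi, tol = 1e-12)
  r <- opt$minimum
  M <- amp_for(r)
  g <- 1 - exp(-r * (x - x0))
  res <- yy - M * g
  at_edge <- (i == 1L && prof[1] < opt$objective) ||
    (i == n_grid && prof[n_grid] < opt$objective)
  if (at_edge) r <- grid[i]
  list(M = M, r = r,
       report = fit_report(c(amplitude = M, rate = r), res, w,
                           converged = !at_edge, n_iter = n_eval))
}

resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  check_numeric_vec(weights, "weights", nonneg = TRUE)
  if (length(weights) != n) stop_validation("'weights' must match the data length")
  weights
}

#' Fit the charge to turnover-LET saturation relation
#'
#' Calibrates \eqn{LET_U(Z) = LET_U(1) + (S/k)(1 - e^{-k(Z-1)})} to
#' observed (Z, LET_U) pairs by unweighted (or weighted) least squares.
#' By default the proton anchor is held FIXED at (1, 30.5) -- the relation
#' is constructed as normalised to the proton turnover LET -- and only the
#' amplitude \eqn{S/k} and rate \eqn{k} are free.  `fix_anchor = FALSE`
#' additionally frees the anchor, fitting it as a linear intercept.
#'
#' @param z Ion charge numbers, >= 1, at least two distinct non-anchor
#'   values.
#' @param let_u Observed turnover LETs, keV/um.
#' @param weights Optional nonnegative per-point weights.
#' @param anchor_let Proton turnover LET used as the fixed anchor, keV/um.
#' @param fix_anchor Keep the Z = 1 anchor fixed (default TRUE).
#' @return A list of class `saturation_fit`: `params`
#'   ([z_saturation_params()]) and `report` (a `fit_report`).
#' @export
#' @examples
#' cal <- z_letu_calibration()
#' fit <- fit_z_saturation(cal$z, cal$let_u)
#' predict(fit, c(6, 10, 18))
fit_z_saturation <- function(z, let_u, weights = NULL, anchor_let = 30.5,
                             fix_anchor = TRUE) {
  check_numeric_vec(z, "z")
  check_numeric_vec(let_u, "let_u")
  if (length(z) != length(let_u)) stop_validation("'z' and 'let_u' lengths differ")
  if (any(z < 1)) stop_validation("'z' must be >= 1")
  w <- resolve_weights(weights, length(z))
  free <- z > 1
  if (length(unique(z[free])) < 2L) {
    stop_validation("need at least two distinct non-anchor Z values to fit S/k and k")
  }
  if (fix_anchor) {
    fit <- profile_exp_fit(z, let_u, w, x0 = 1, y0 = anchor_let)
    params <- z_saturation_params(S = fit$M * fit$r, k = fit$r,
                                  anchor_let = anchor_let)
    report <- fit$report
  } else {
    # both intercept and amplitude are conditionally linear in the rate
    n_eval <- 0L
    coef_for <- function(r) {
      g <- 1 - exp(-r * (z - 1))
      X <- cbind(1, g)
      qr.coef(qr(sqrt(w) * X), sqrt(w) * let_u)
    }
    rss_for <- function(r) {
      n_eval <<- n_eval + 1L
      cf <- coef_for(r)
      g <- 1 - exp(-r * (z - 1))
      sum(w * (cf[1] + cf[2] * g - let_u)^2)
    }
    grid <- exp(seq(log(1e-3), log(100), length.out = 161))
    prof <- vapply(grid, rss_for, numeric(1))
    i <- which.min(prof)
    opt <- stats::optimize(rss_for,
                           lower = grid[max(1L, i - 1L)],
                           upper = grid[min(length(grid), i + 1L)],
                           tol = 1e-12)
    r <- opt$minimum
    cf <- coef_for(r)
    g <- 1 - exp(-r * (z - 1))
    res <- let_u - (cf[1] + cf[2] * g)
    params <- z_saturation_params(S = unname(cf[2]) * r, k = r, anchor_let = unname(cf[1]))
    report <- fit_report(c(anchor_let = unname(cf[1]), amplitude = unname(cf[2]),
                           rate = r),
                         res, w, converged = i > 1L && i < length(grid),
                         n_iter = n_eval)
  }
  structure(list(params = params, report = report, kind = "z_saturation"),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit (%s)\n", x$kind))
  print(x$params)
  print(x$report)
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, newdata, ...) {
  switch(object$kind,
    z_saturation = let_u_from_z(newdata, object$params),
    alpha_saturation = alpha_u_from_alpha_l(newdata, object$params),
    beta_saturation = beta_u_from_beta_l(newdata, object$params)
  )
}

# shared machinery for the alpha/beta radiosensitivity saturation fits
fit_radiosensitivity <- function(x, y, weights, mode, kind, make_linear,
                                 make_nonlinear) {
  check_numeric_vec(x, "x", nonneg = TRUE)
  check_numeric_vec(y, "y")
  if (length(x) != length(y)) stop_validation("predictor and response lengths differ")
  w <- resolve_weights(weights, length(x))
  if (mode == "linear") {
    sxx <- sum(w * x^2)
    if (sxx == 0) stop_validation("all predictors zero: no-intercept slope undefined")
    slope <- sum(w * x * y) / sxx
    res <- y - slope * x
    params <- make_linear(slope)
    report <- fit_report(c(slope = slope), res, w, converged = TRUE, n_iter = 1L)
  } else {
    if (length(unique(x)) < 2L) {
      stop_validation("nonlinear saturation fit needs at least two distinct predictor values")
    }
    fit <- profile_exp_fit(x, y, w)
    params <- make_nonlinear(fit$M, fit$r)
    report <- fit$report
  }
  structure(list(params = params, report = report, kind = kind),
            class = "saturation_fit")
}

#' Fit the alpha saturation relation
#'
#' Linear mode fits the no-intercept proportionality
#' \eqn{\alpha_U = c\,\alpha_L} (closed form \eqn{c = \sum xy/\sum x^2});
#' nonlinear mode fits \eqn{\alpha_U = (A/j)(1 - e^{-j\alpha_L})} over
#' (A, j) by the profiled scheme described in [fitting].
#'
#' @param alpha_l Low-LET alpha values, Gy^-1.
#' @param alpha_u Observed maximum (turnover-region) alpha values, Gy^-1.
#' @param mode `"linear"` or `"nonlinear"`.
#' @param weights Optional per-point weights.
#' @return A `saturation_fit` with [alpha_saturation_params()] `params`.
#' @export
fit_alpha_saturation <- function(alpha_l, alpha_u,
                                 mode = c("linear", "nonlinear"),
                                 weights = NULL) {
  mode <- match.arg(mode)
  fit_radiosensitivity(
    alpha_l, alpha_u, weights, mode, "alpha_saturation",
    make_linear = function(slope) alpha_saturation_params("linear", c = slope),
    make_nonlinear = function(M, r) {
      alpha_saturation_params("nonlinear", A = M * r, j = r)
    }
  )
}

#' Fit the beta saturation relation
#'
#' Same contracts as [fit_alpha_saturation()] with (R, u) in place of
#' (A, j).
#'
#' @param beta_l Low-LET beta values, Gy^-2.
#' @param beta_u Observed maximum beta values, Gy^-2.
#' @inheritParams fit_alpha_saturation
#' @return A `saturation_fit` with [beta_saturation_params()] `params`.
#' @export
fit_beta_saturation <- function(beta_l, beta_u,
                                mode = c("linear", "nonlinear"),
                                weights = NULL) {
  mode <- match.arg(mode)
  fit_radiosensitivity(
    beta_l, beta_u, weights, mode, "beta_saturation",
    make_linear = function(slope) beta_saturation_params("linear", c = slope),
    make_nonlinear = function(M, r) {
      beta_saturation_params("nonlinear", R = M * r, u = r)
    }
  )
}

#' Fit linear-quadratic parameters to clonogenic survival data
#'
#' Regresses \eqn{-\ln SF} on dose and dose squared without intercept --
#' the standard log-scale LQ fit -- with both coefficients constrained
#' nonnegative.  The unconstrained solution is the closed-form weighted
#' normal-equation solve; if it violates a bound, a bounded quasi-Newton
#' refinement (L-BFGS-B) from the clamped start is used, so boundary
#' solutions such as \eqn{\beta = 0} are returned exactly.
#'
#' @param dose Doses, Gy, > 0, at least three distinct values.
#' @param sf Surviving fractions in (0, 1].
#' @param weights Optional per-point weights (applied on the log scale).
#' @return A list of class `lq_fit`: `params` ([lq_params()]) and `report`.
#' @export
#' @examples
#' d <- 1:8
#' sf <- exp(-0.16 * d - 0.046 * d^2)
#' fit_lq_survival(d, sf)$params
fit_lq_survival <- function(dose, sf, weights = NULL) {
  check_numeric_vec(dose, "dose")
  check_numeric_vec(sf, "sf")
  if (length(dose) != length(sf)) stop_validation("'dose' and 'sf' lengths differ")
  if (any(dose <= 0)) stop_validation("'dose' must be > 0")
  if (any(sf <= 0 | sf > 1)) stop_validation("'sf' must lie in (0, 1]")
  if (length(unique(dose)) < 3L) {
    stop_validation("need at least three distinct doses to fit alpha and beta")
  }
  if (all(sf == 1)) stop_validation("all surviving fractions are 1: no effect to fit")
  w <- resolve_weights(weights, length(dose))
  y <- -log(sf)
  X <- cbind(d = dose, d2 = dose^2)
  cf <- qr.coef(qr(sqrt(w) * X), sqrt(w) * y)
  n_iter <- 1L
  converged <- TRUE
  if (any(cf < 0)) {
    rss_fun <- function(p) sum(w * (y - X %*% p)^2)
    grad_fun <- function(p) -2 * drop(crossprod(X, w * (y - X %*% p)))
    opt <- stats::optim(pmax(cf, 0), rss_fun, grad_fun, method = "L-BFGS-B",
                        lower = c(0, 0), control = list(factr = 1e3))
    cf <- opt$par
    n_iter <- n_iter + opt$counts[["function"]]
    converged <- opt$convergence == 0
    if (!converged) {
      stop_numerical("bounded LQ survival fit failed to converge")
    }
  }
  # snap coefficients sitting at (or rounding onto) the bound to exactly zero
  cf[abs(cf) < 1e-12] <- 0
  res <- y - drop(X %*% cf)
  structure(
    list(params = lq_params(cf[[1]], cf[[2]]),
         report = fit_report(c(alpha = cf[[1]], beta = cf[[2]]), res, w,
                             converged = converged, n_iter = n_iter)),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("LQ survival fit\n")
  print(x$params)
  print(x$report)
  invisible(x)
}
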