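# Model configuration: one validated bag of constants for the whole
# pipeline.  Defaults are the published model constants; the Z-saturation
# constants (S, k), which have no published values, default to the
# package's own deterministic calibration against the bundled four-ion
# turnover table.

.rbelet_env <- new.env(parent = emptyenv())

config_keys <- c("anchor_let", "S", "k", "alpha_mode", "alpha_c", "A", "j",
                 "beta_mode", "R", "u", "let_c", "post_turnover")

#' Model configuration
#'
#' Collects every tunable constant of the model.  All arguments default to
#' the standard values: proton anchor 30.5 keV/um, linear alpha scaling
#' with c = 6.47, nonlinear beta scaling with R = 2.5 and u = 25, control
#' LET 1.2 keV/um, reciprocal post-turnover decline.  `S` and `k` default
#' to `NULL`, meaning "use the calibration fitted to the bundled (Z, LET_U)
#' table" (see [z_letu_calibration()]).
#'
#' @param anchor_let Proton (Z = 1) turnover LET, keV/um.
#' @param S,k Z-saturation initial slope and rate constant; both or
#'   neither.
#' @param alpha_mode,alpha_c,A,j Alpha saturation mode and constants; see
#'   [alpha_saturation_params()].
#' @param beta_mode,R,u Beta saturation mode and constants; see
#'   [beta_saturation_params()].
#' @param let_c Control LET, keV/um.
#' @param post_turnover `"reciprocal"` or `"strict"`; see
#'   [let_efficiency()].
#' @return A validated `rbelet_config` object.
#' @seealso [load_config()]
#' @export
model_config <- function(anchor_let = 30.5, S = NULL, k = NULL,
                         alpha_mode = "linear", alpha_c = 6.47,
                         A = NULL, j = NULL,
                         beta_mode = "nonlinear", R = 2.5, u = 25,
                         let_c = 1.2,
                         post_turnover = "reciprocal") {
  cfg <- structure(
    list(anchor_let = anchor_let, S = S, k = k,
         alpha_mode = alpha_mode, alpha_c = alpha_c, A = A, j = j,
         beta_mode = beta_mode, R = R, u = u,
         let_c = let_c, post_turnover = post_turnover),
    class = "rbelet_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  chk(pos_scalar(cfg$anchor_let), "anchor_let")
  chk(is.null(cfg$S) || pos_scalar(cfg$S), "S")
  chk(is.null(cfg$k) || pos_scalar(cfg$k), "k")
  chk(is.null(cfg$S) == is.null(cfg$k), "S/k (supply both or neither)")
  chk(cfg$alpha_mode %in% c("linear", "nonlinear"), "alpha_mode")
  if (identical(cfg$alpha_mode, "linear")) {
    chk(pos_scalar(cfg$alpha_c) && cfg$alpha_c > 1, "alpha_c")
  } else {
    chk(pos_scalar(cfg$A), "A")
    chk(pos_scalar(cfg$j), "j")
  }
  chk(cfg$beta_mode %in% c("nonlinear", "linear", "constant"), "beta_mode")
  if (identical(cfg$beta_mode, "nonlinear")) {
    chk(pos_scalar(cfg$R), "R")
    chk(pos_scalar(cfg$u), "u")
  }
  chk(pos_scalar(cfg$let_c), "let_c")
  chk(cfg$post_turnover %in% c("reciprocal", "strict"), "post_turnover")
  if (length(bad)) {
    stop_validation(paste0("invalid configuration value(s) for: ",
                           paste(bad, collapse = ", ")))
  }
  cfg
}

#' @export
print.rbelet_config <- function(x, ...) {
  cat("rbelet model configuration\n")
  zsrc <- if (is.null(x$S)) "fitted to bundled calibration" else
    sprintf("S = %g, k = %g", x$S, x$k)
  cat(sprintf("  Z saturation: anchor %g keV/um; %s\n", x$anchor_let, zsrc))
  cat(sprintf("  alpha mode: %s", x$alpha_mode))
  if (x$alpha_mode == "linear") cat(sprintf(" (c = %g)\n", x$alpha_c))
  else cat(sprintf(" (A = %g, j = %g)\n", x$A, x$j))
  cat(sprintf("  beta mode: %s", x$beta_mode))
  if (x$beta_mode == "nonlinear") cat(sprintf(" (R = %g, u = %g)\n", x$R, x$u))
  else cat("\n")
  cat(sprintf("  control LET: %g keV/um; post-turnover: %s\n",
              x$let_c, x$post_turnover))
  invisible(x)
}

#' Load a model configuration from a YAML or JSON file
#'
#' Reads a flat key-value file, applies the standard defaults for absent
#' keys, rejects unknown keys, and validates every constraint of the
#' underlying parameter types.  An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML (or JSON; JSON is a YAML subset) file with
#'   any of the keys `anchor_let`, `S`, `k`, `alpha_mode`, `alpha_c`, `A`,
#'   `j`, `beta_mode`, `R`, `u`, `let_c`, `post_turnover`.
#' @return A validated `rbelet_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_validation("config file must contain a key: value mapping")
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop_validation(paste0("unknown configuration key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  do.call(model_config, raw)
}

# Default Z-saturation parameters: deterministic fit to the bundled
# calibration table, memoised per session.
default_z_params <- function() {
  if (is.null(.rbelet_env$z_params)) {
    cal <- z_letu_calibration()
    .rbelet_env$z_params <- fit_z_saturation(cal$z, cal$let_u)$params
  }
  .rbelet_env$z_params
}

z_params_from_config <- function(cfg) {
  if (is.null(cfg$S)) {
    p <- default_z_params()
    if (cfg$anchor_let != p$anchor_let) {
      p <- z_saturation_params(p$S, p$k, anchor_let = cfg$anchor_let)
    }
    p
  } else {
    z_saturation_params(cfg$S, cfg$k, anchor_let = cfg$anchor_let)
  }
}

alpha_params_from_config <- function(cfg) {
  if (cfg$alpha_mode == "linear") {
    alpha_saturation_params("linear", c = cfg$alpha_c)
  } else {
    alpha_saturation_params("nonlinear", A = cfg$A, j = cfg$j)
  }
}

beta_params_from_config <- function(cfg) {
  switch(cfg$beta_mode,
    nonlinear = beta_saturation_params("nonlinear", R = cfg$R, u = cfg$u),
    linear = beta_saturation_params("linear", c = cfg$R),
    constant = beta_saturation_params("constant")
  )
}
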