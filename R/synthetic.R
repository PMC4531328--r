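#' Generate synthetic clonogenic survival data
#'
#' Emulates a clonogenic assay at fixed radiation quality: the true
#' surviving fraction follows the LQ model
#' \eqn{SF = e^{-\alpha d - \beta d^2}} and each observed replicate is
#' perturbed by mean-preserving multiplicative lognormal noise with a given
#' coefficient of variation, the standard noise structure of colony-count
#' ratios.  With `noise_cv = 0` the exact LQ curve is returned.
#'
#' The lognormal sigma is \eqn{\sigma = \sqrt{\log(1 + cv^2)}} and the
#' noise factor \eqn{e^{\sigma Z - \sigma^2/2}}, so the expected observed
#' SF equals the true SF and its coefficient of variation equals
#' `noise_cv` exactly.
#'
#' @param lq True [lq_params()].
#' @param doses Dose levels, Gy, >= 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (nonnegative; e.g. 0.1 for 10%).
#' @param n_reps Replicates per dose level, >= 1.
#' @param seed Integer RNG seed; required whenever `noise_cv > 0` so runs
#'   are reproducible.
#' @return A data frame with columns `dose`, `sf`, `rep` and `sf_true`.
#' @export
#' @examples
#' generate_synthetic_survival(lq_params(0.16, 0.046), doses = c(1, 2, 4),
#'                             noise_cv = 0.1, n_reps = 2, seed = 7)
generate_synthetic_survival <- function(lq, doses, noise_cv = 0, n_reps = 1L,
                                        seed = NULL) {
  stopifnot(inherits(lq, "lq_params"))
  check_numeric_vec(doses, "doses", nonneg = TRUE)
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar(n_reps, "n_reps", positive = TRUE)
  if (noise_cv > 0 && is.null(seed)) {
    stop_validation("'seed' is required when 'noise_cv' > 0")
  }
  d <- rep(doses, each = n_reps)
  sf_true <- exp(-lq$alpha * d - lq$beta * d^2)
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    sigma <- sqrt(log1p(noise_cv^2))
    noise <- exp(stats::rnorm(length(d), mean = -sigma^2 / 2, sd = sigma))
  } else {
    noise <- 1
  }
  data.frame(dose = d,
             sf = pmin(1, sf_true * noise),
             rep = rep(seq_len(n_reps), times = length(doses)),
             sf_true = sf_true)
}
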