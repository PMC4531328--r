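# Independent numerical oracles used to cross-check the closed-form
# solvers.  Deliberately implemented by brute force, not by reusing the
# package's own algebra.

# Bisection root of alpha*d + beta*d^2 = effect on d in (0, upper].
bisect_lq_dose <- function(effect, alpha, beta, upper = 1e3, tol = 1e-12) {
  f <- function(d) alpha * d + beta * d^2 - effect
  lo <- 0
  hi <- upper
  stopifnot(f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Bisection solution of the high-LET BED equation
# m*d*(rbe_max + rbe_min^2 * d / ab) = bed.
bisect_high_let_dose <- function(bed, m, rbe_max, rbe_min, ab, tol = 1e-12) {
  f <- function(d) m * d * (rbe_max + rbe_min^2 * d / ab) - bed
  lo <- 0
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Fig-6-style nine-ion reference: charge numbers and turnover LETs
# (deuterons through argon, rounded above 100 keV/um).
nine_ion_z <- c(1, 2, 3, 5, 6, 7, 8, 10, 18)
nine_ion_let_u <- c(30.5, 103, 150, 200, 213, 221, 227, 232, 237)

random_lq_pair <- function() {
  low <- lq_params(stats::runif(1, 0.05, 0.5), stats::runif(1, 0.01, 0.08))
  high <- lq_params(low$alpha * stats::runif(1, 1, 10),
                    low$beta * stats::runif(1, 1, 4))
  list(low = low, high = high)
}
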