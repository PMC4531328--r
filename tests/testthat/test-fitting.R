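test_that("Z-saturation fit recovers noiseless parameters exactly", {
  truth <- z_saturation_params(S = 200 * 0.4, k = 0.4)  # S/k = 200
  z <- c(1, 2, 3, 4, 6, 8, 10)
  fit <- fit_z_saturation(z, let_u_from_z(z, truth))
  expect_equal(fit$params$k, 0.4, tolerance = 1e-6)
  expect_equal(fit$params$S / fit$params$k, 200, tolerance = 1e-6)
  expect_lt(fit$report$rss, 1e-12)
  expect_true(fit$report$converged)
  expect_error(fit_z_saturation(c(1, 2), c(30.5, 100)),
               class = "rbelet_validation_error")
})

test_that("calibration fit to the bundled turnover table matches the frozen oracle", {
  cal <- z_letu_calibration()
  expect_equal(cal$z, c(1, 2, 6, 10))
  expect_equal(cal$let_u, c(30.5, 103.4, 208, 233))
  fit <- fit_z_saturation(cal$z, cal$let_u)
  # frozen from an independent profiled least-squares oracle
  expect_equal(fit$params$k, 0.4230928, tolerance = 1e-5)
  expect_equal(fit$params$S / fit$params$k, 205.1677, tolerance = 1e-5)
  # anchored construction: the proton point is reproduced exactly
  expect_identical(predict(fit, 1), 30.5)
  # nearest-integer predictions at the heavier ions
  expect_equal(round(predict(fit, c(6, 10, 18))), c(211, 231, 236))
  # nine-ion reference turnover LETs recovered within 2% relative
  pred <- predict(fit, nine_ion_z)
  expect_lt(max(abs(pred - nine_ion_let_u) / nine_ion_let_u), 0.02)
})

test_that("fitted parameters are locally optimal on a surrounding grid", {
  cal <- z_letu_calibration()
  fit <- fit_z_saturation(cal$z, cal$let_u)
  M0 <- fit$params$S / fit$params$k
  k0 <- fit$params$k
  rss <- function(M, k) {
    sum((30.5 + M * (1 - exp(-k * (cal$z - 1))) - cal$let_u)^2)
  }
  grid <- expand.grid(M = M0 * seq(0.8, 1.2, length.out = 50),
                      k = k0 * seq(0.8, 1.2, length.out = 50))
  grid_rss <- mapply(rss, grid$M, grid$k)
  expect_lte(fit$report$rss, min(grid_rss) + 1e-9)
})

test_that("free-anchor Z fit recovers a shifted anchor", {
  truth <- z_saturation_params(S = 60, k = 0.3, anchor_let = 25)
  z <- c(1, 2, 3, 5, 8, 12)
  fit <- fit_z_saturation(z, let_u_from_z(z, truth), fix_anchor = FALSE)
  expect_equal(fit$params$anchor_let, 25, tolerance = 1e-5)
  expect_equal(fit$params$k, 0.3, tolerance = 1e-5)
})

test_that("alpha saturation fits: closed-form linear slope and exact nonlinear recovery", {
  x <- c(0.05, 0.1, 0.2, 0.3)
  fit <- fit_alpha_saturation(x, 6.47 * x, mode = "linear")
  expect_equal(fit$params$c, 6.47, tolerance = 1e-12)
  expect_lt(fit$report$rss, 1e-24)

  truth <- alpha_saturation_params("nonlinear", A = 5.37, j = 3.68)
  xs <- seq(0.02, 0.8, by = 0.06)
  fit <- fit_alpha_saturation(xs, alpha_u_from_alpha_l(xs, truth),
                              mode = "nonlinear")
  expect_equal(fit$params$A, 5.37, tolerance = 1e-6)
  expect_equal(fit$params$j, 3.68, tolerance = 1e-6)

  # noisy slope lands within three standard errors of the truth
  set.seed(101)
  xn <- runif(40, 0.02, 0.35)
  yn <- 6.47 * xn + rnorm(40, sd = 0.15)
  fit <- fit_alpha_saturation(xn, yn, mode = "linear")
  se <- sqrt(fit$report$rss / (length(xn) - 1) / sum(xn^2))
  expect_lt(abs(fit$params$c - 6.47), 3 * se)
})

test_that("beta saturation fits mirror the alpha contracts", {
  x <- c(0.01, 0.02, 0.04, 0.06)
  fit <- fit_beta_saturation(x, 1.57 * x, mode = "linear")
  expect_equal(fit$params$c, 1.57, tolerance = 1e-12)
  expect_lt(fit$report$rss, 1e-28)

  truth <- beta_saturation_params("nonlinear", R = 2.29, u = 23.57)
  xs <- seq(0.005, 0.12, by = 0.01)
  fit <- fit_beta_saturation(xs, beta_u_from_beta_l(xs, truth),
                             mode = "nonlinear")
  expect_equal(fit$params$R, 2.29, tolerance = 1e-6)
  expect_equal(fit$params$u, 23.57, tolerance = 1e-6)
})

test_that("LQ survival fit recovers parameters and respects the nonnegativity bound", {
  d <- 1:8
  sf <- exp(-0.16 * d - 0.046 * d^2)
  fit <- fit_lq_survival(d, sf)
  expect_equal(fit$params$alpha, 0.16, tolerance = 1e-8)
  expect_equal(fit$params$beta, 0.046, tolerance = 1e-8)

  # pure single-hit data: beta pinned at the boundary
  sf0 <- exp(-0.3 * d)
  fit0 <- fit_lq_survival(d, sf0)
  expect_equal(fit0$params$alpha, 0.3, tolerance = 1e-8)
  expect_identical(fit0$params$beta, 0)

  expect_error(fit_lq_survival(c(1, 2), c(0.9, 0.8)),
               class = "rbelet_validation_error")
  expect_error(fit_lq_survival(1:4, rep(1, 4)),
               class = "rbelet_validation_error")
})

test_that("LQ fit is nearly unbiased for alpha under replicated noisy assays", {
  truth <- lq_params(0.16, 0.046)
  alphas <- vapply(1:200, function(r) {
    tab <- generate_synthetic_survival(truth, doses = 1:8, noise_cv = 0.1,
                                       n_reps = 3, seed = 5000 + r)
    fit_lq_survival(tab$dose, tab$sf)$params$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - truth$alpha), 0.05 * truth$alpha)
})

test_that("estimates tighten as calibration data grow on a fixed seed ladder", {
  truth <- alpha_saturation_params("linear", c = 6.47)
  err <- vapply(c(10, 80, 640), function(n) {
    set.seed(77)
    x <- runif(n, 0.02, 0.35)
    y <- 6.47 * x + rnorm(n, sd = 0.2)
    abs(fit_alpha_saturation(x, y, mode = "linear")$params$c - 6.47)
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("synthetic survival generator is exact, seeded and calibrated", {
  truth <- lq_params(0.16, 0.046)
  clean <- generate_synthetic_survival(truth, doses = c(1, 2, 4, 8))
  expect_equal(clean$sf, exp(-0.16 * clean$dose - 0.046 * clean$dose^2))

  a <- generate_synthetic_survival(truth, 1:6, noise_cv = 0.1, n_reps = 4,
                                   seed = 99)
  b <- generate_synthetic_survival(truth, 1:6, noise_cv = 0.1, n_reps = 4,
                                   seed = 99)
  expect_identical(a, b)
  c2 <- generate_synthetic_survival(truth, 1:6, noise_cv = 0.1, n_reps = 4,
                                    seed = 100)
  expect_false(identical(a$sf, c2$sf))

  # empirical CV at each dose within 20% of the nominal 10%
  tab <- generate_synthetic_survival(truth, doses = c(4, 6, 8),
                                     noise_cv = 0.1, n_reps = 200, seed = 1234)
  cv <- vapply(split(tab$sf, tab$dose), function(s) sd(s) / mean(s), numeric(1))
  expect_true(all(abs(cv - 0.1) < 0.02))

  expect_error(generate_synthetic_survival(truth, 1:4, noise_cv = 0.1),
               class = "rbelet_validation_error")
})
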