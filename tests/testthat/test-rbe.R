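lq_low_bar <- lq_params(0.16, 0.046)   # Barendsen-style control values
lq_high_bar <- lq_params(1.31, 0.15)   # corresponding turnover values

test_that("solve_lq_dose returns the positive quadratic root", {
  expect_equal(solve_lq_dose(log(2), lq_high_bar), 0.50044325417, tolerance = 1e-9)
  expect_equal(solve_lq_dose(log(2), lq_low_bar), 2.51445530408, tolerance = 1e-9)
  expect_identical(solve_lq_dose(1, lq_params(0.5, 0)), 2)
  # back-substitution recovers the effect
  d <- solve_lq_dose(2.3, lq_high_bar)
  expect_equal(lq_high_bar$alpha * d + lq_high_bar$beta * d^2, 2.3,
               tolerance = 1e-10)
  expect_error(solve_lq_dose(-1, lq_low_bar), class = "rbelet_validation_error")
  expect_error(solve_lq_dose(1, lq_params(0, 0)), class = "rbelet_validation_error")
})

test_that("closed-form dose solver agrees with a bisection oracle on random draws", {
  set.seed(42)
  for (i in 1:1000) {
    alpha <- runif(1, 0.01, 2)
    beta <- runif(1, 0, 0.2)
    effect <- runif(1, 0.01, 5)
    if (alpha == 0 && beta == 0) next
    d <- solve_lq_dose(effect, lq_params(alpha, beta))
    expect_equal(d, bisect_lq_dose(effect, alpha, beta), tolerance = 1e-9)
  }
})

test_that("rbe_at_dose solves the iso-effect equation", {
  r <- rbe_at_dose(0.50044325417, lq_low_bar, lq_high_bar)
  expect_equal(r$rbe, 5.0244564, tolerance = 1e-6)
  expect_equal(r$sf, 0.5, tolerance = 1e-8)
  expect_equal(r$rbe, r$d_l / r$d_h, tolerance = 1e-12)
  # identical qualities give RBE 1 at every dose
  for (d in c(0.1, 1, 5, 20)) {
    expect_equal(rbe_at_dose(d, lq_low_bar, lq_low_bar)$rbe, 1, tolerance = 1e-12)
  }
})

test_that("RBE runs monotonically between its closed-form dose limits", {
  lim <- rbe_limits(lq_low_bar, lq_high_bar)
  expect_equal(lim$rbe_max, 1.31 / 0.16)
  expect_equal(lim$rbe_max, 8.1875)
  expect_equal(lim$rbe_min, sqrt(0.15 / 0.046))
  expect_equal(lim$rbe_min, 1.8057878, tolerance = 1e-7)
  expect_equal(rbe_limits(lq_low_bar, lq_params(1.31, 0.046))$rbe_min, 1)

  # numerical limits against the closed forms
  expect_equal(rbe_at_dose(1e-6, lq_low_bar, lq_high_bar)$rbe, lim$rbe_max,
               tolerance = 1e-4)
  expect_equal(rbe_at_dose(1e6, lq_low_bar, lq_high_bar)$rbe, lim$rbe_min,
               tolerance = 1e-4)

  set.seed(7)
  doses <- c(0.05, 0.2, 0.5, 1, 2, 5, 10, 30, 100)
  for (i in 1:40) {
    pair <- random_lq_pair()
    lim <- rbe_limits(pair$low, pair$high)
    rbe <- vapply(doses, function(d) rbe_at_dose(d, pair$low, pair$high)$rbe,
                  numeric(1))
    expect_true(all(rbe >= min(lim$rbe_max, lim$rbe_min) - 1e-9))
    expect_true(all(rbe <= max(lim$rbe_max, lim$rbe_min) + 1e-9))
    if (lim$rbe_max > lim$rbe_min + 1e-8) {
      expect_true(all(diff(rbe) < 0))
    } else if (lim$rbe_max < lim$rbe_min - 1e-8) {
      expect_true(all(diff(rbe) > 0))
    }
  }
  # equal limits: RBE constant in dose
  flat_low <- lq_params(0.2, 0.02)
  flat_high <- lq_params(0.4, 0.08)  # rbe_max = rbe_min = 2
  rbe <- vapply(doses, function(d) rbe_at_dose(d, flat_low, flat_high)$rbe,
                numeric(1))
  expect_equal(rbe, rep(2, length(doses)), tolerance = 1e-10)
})

test_that("rbe_at_sf matches rbe_at_dose at the same effect and handles sf = 1", {
  r_sf <- rbe_at_sf(0.5, lq_low_bar, lq_high_bar)
  r_d <- rbe_at_dose(r_sf$d_h, lq_low_bar, lq_high_bar)
  expect_equal(r_sf$rbe, r_d$rbe, tolerance = 1e-12)
  expect_equal(r_sf$effect, log(2))
  expect_equal(rbe_at_sf(0.37, lq_low_bar, lq_low_bar)$rbe, 1, tolerance = 1e-12)
  # zero-dose analytic limit, flagged
  r1 <- rbe_at_sf(1, lq_low_bar, lq_high_bar)
  expect_true(r1$limit)
  expect_equal(r1$rbe, 8.1875)
  # near sf = 1 the RBE approaches the limit from below the max
  expect_equal(rbe_at_sf(1 - 1e-8, lq_low_bar, lq_high_bar)$rbe, 8.1875,
               tolerance = 1e-4)
  expect_error(rbe_at_sf(0, lq_low_bar, lq_high_bar),
               class = "rbelet_validation_error")
  expect_error(rbe_at_sf(1.2, lq_low_bar, lq_high_bar),
               class = "rbelet_validation_error")
})

test_that("rbe_curve composes the full pipeline", {
  lq_low <- lq_params(0.14, 0.05)
  # at the control LET the curve degenerates to RBE 1
  tab <- rbe_curve(1.2, lq_low, let_u = 120, alpha_u = 0.9, beta_u = 0.08,
                   dose = 2)
  expect_equal(tab$rbe, 1, tolerance = 1e-12)
  # single grid point at the turnover equals a direct turnover evaluation
  tab <- rbe_curve(120, lq_low, let_u = 120, alpha_u = 0.9, beta_u = 0.08,
                   dose = 2)
  direct <- rbe_at_dose(2, lq_low, lq_params(0.9, 0.08))
  expect_equal(tab$rbe, direct$rbe, tolerance = 1e-12)
  expect_error(rbe_curve(60, lq_low, let_u = 120, dose = 2, sf = 0.5),
               class = "rbelet_validation_error")
  expect_error(rbe_curve(60, lq_low, dose = 2),
               class = "rbelet_validation_error")
})

test_that("nine-ion curve family reproduces the per-ion turnover LETs", {
  lq_low <- lq_params(0.14, 0.05)
  for (i in seq_along(nine_ion_z)) {
    tab <- rbe_curve(seq(2, 500, by = 2), lq_low, z = nine_ion_z[i], dose = 1.5)
    resp <- attr(tab, "response")
    expect_equal(resp$let_u, nine_ion_let_u[i], tolerance = 0.02)
    # the RBE peak sits at the grid point nearest the turnover LET
    grid <- tab$let
    expect_equal(grid[which.max(tab$rbe)],
                 grid[which.min(abs(grid - resp$let_u))])
  }
})

test_that("the LET of peak RBE is invariant across dose and survival levels", {
  lq_low <- lq_params(0.14, 0.05)
  grid <- seq(2, 500, by = 1)
  peaks <- c(
    vapply(c(0.5, 1.5, 4, 10), function(d) {
      tab <- rbe_curve(grid, lq_low, z = 6, dose = d)
      tab$let[which.max(tab$rbe)]
    }, numeric(1)),
    vapply(c(0.5, 0.1, 0.05), function(s) {
      tab <- rbe_curve(grid, lq_low, z = 6, sf = s)
      tab$let[which.max(tab$rbe)]
    }, numeric(1))
  )
  expect_length(unique(peaks), 1L)
})
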