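test_that("T1/Tc inversion is the exact inverse of the twitch Emax model", {
  pt <- pd_tab$t1tc
  expect_equal(invert_t1tc(0.5, pt), pt$ec50)
  expect_equal(invert_t1tc(1, pt), 0)
  t_grid <- seq(0.1, 0.9, by = 0.1)
  round_trip <- emax_response(invert_t1tc(t_grid, pt), pt)
  expect_lt(max(abs(round_trip - t_grid)), 1e-10)
  expect_error(invert_t1tc(0, pt), "0, 1")
  expect_error(invert_t1tc(1.01, pt), "0, 1")
})

test_that("closed-form amplitude-T1/Tc curve equals the emax-o-invert composition", {
  t_grid <- seq(0.001, 0.999, length.out = 501)
  for (m in c("Del", "APB", "TA", "AH")) {
    closed <- mu_of_t1tc(t_grid, pd_tab[[m]], pd_tab$t1tc)
    composed <- emax_response(invert_t1tc(t_grid, pd_tab$t1tc), pd_tab[[m]])
    expect_lt(max(abs(closed - composed) / composed), 1e-10)
    expect_true(all(diff(closed) > 0))         # strictly increasing
  }
  expect_equal(mu_of_t1tc(1, pd_tab$Del, pd_tab$t1tc), 366)
  # shared EC50 and Hill collapse the curve to proportionality
  pm <- pd_params("m", 500, 2.69, 2.23)
  expect_equal(mu_of_t1tc(t_grid, pm, pd_tab$t1tc), 500 * t_grid,
               tolerance = 1e-10)
})

test_that("shape classifier reproduces the qualitative parameter rules", {
  pt <- pd_params("t1tc", 1, 2, 2)
  expect_identical(classify_shape(pd_params("m", 100, 1, 2), pt), "convex_up")
  expect_identical(classify_shape(pd_params("m", 100, 4, 2), pt), "concave_up")
  expect_identical(classify_shape(pd_params("m", 100, 2, 4), pt),
                   "sigmoid_max_slope_mid")
  expect_identical(classify_shape(pd_params("m", 100, 2, 1), pt),
                   "sigmoid_min_slope_mid")
  expect_identical(classify_shape(pd_params("m", 100, 2, 2), pt), "linear")
  # invariant to rescaling the muscle baseline
  expect_identical(classify_shape(pd_params("m", 1e6, 1, 2), pt), "convex_up")
  # every label is reachable over the EC50-ratio x Hill-ratio sweep
  labels <- character(0)
  for (er in c(0.5, 1, 2)) {
    for (hr in c(0.5, 1, 2)) {
      labels <- c(labels, classify_shape(pd_params("m", 100, 2 * er, 2 * hr), pt))
    }
  }
  expect_setequal(unique(labels),
                  c("linear", "convex_up", "concave_up",
                    "sigmoid_max_slope_mid", "sigmoid_min_slope_mid"))
})

test_that("critical T1/Tc solves mu(t) = mu* and flags unattainable targets", {
  # identical dose-response (scaled): half the baseline maps to t = 0.5
  pm <- pd_params("m", 500, 2.69, 2.23)
  half <- critical_t1tc_for_amplitude(250, pm, pd_tab$t1tc)
  expect_equal(half$t1tc, 0.5, tolerance = 1e-12)

  # mutual inverse with mu_of_t1tc across muscles and targets
  for (m in c("Del", "APB", "TA", "AH")) {
    for (frac in c(0.15, 0.4, 0.75)) {
      mu_star <- frac * pd_tab[[m]]$baseline
      sol <- critical_t1tc_for_amplitude(mu_star, pd_tab[[m]], pd_tab$t1tc)
      expect_true(sol$attainable)
      expect_rel(mu_of_t1tc(sol$t1tc, pd_tab[[m]], pd_tab$t1tc), mu_star, 1e-8)
      # bisection fallback agrees with the closed form
      bis <- critical_t1tc_for_amplitude(mu_star, pd_tab[[m]], pd_tab$t1tc,
                                         method = "bisection")
      expect_rel(bis$t1tc, sol$t1tc, 1e-8)
    }
  }

  # a target above the typical baseline cannot be reached at any T1/Tc
  ta <- critical_t1tc_for_amplitude(757, pd_tab$TA, pd_tab$t1tc)
  expect_false(ta$attainable)
  expect_true(is.na(ta$t1tc))
  expect_error(critical_t1tc_for_amplitude(-5, pd_tab$TA, pd_tab$t1tc),
               "positive")
})
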