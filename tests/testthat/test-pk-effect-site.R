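tg <- seq(0, 3600, by = 5)

test_that("plasma kinetics are linear: zero dose, dose-proportionality, superposition", {
  z <- simulate_plasma(dose_event(0, 0, 64), pk_def, tg)
  expect_true(all(z$cp_mg_per_l == 0))

  s1 <- simulate_plasma(dose_event(0, 0.3, 64), pk_def, tg)
  s2 <- simulate_plasma(dose_event(0, 0.6, 64), pk_def, tg)
  expect_rel(s2$cp_mg_per_l[-1], 2 * s1$cp_mg_per_l[-1], 1e-8)

  both <- simulate_plasma(dose_event(c(0, 600), 0.3, 64), pk_def, tg)
  late <- simulate_plasma(dose_event(600, 0.3, 64), pk_def, tg)
  expect_lt(max(abs(both$cp_mg_per_l - (s1$cp_mg_per_l + late$cp_mg_per_l))) /
              max(both$cp_mg_per_l), 1e-8)
})

test_that("matrix-exponential and adaptive ODE routes agree to 1e-8", {
  a <- simulate_plasma(dose_event(0, 0.6, 64), pk_def, tg)
  b <- simulate_plasma(dose_event(0, 0.6, 64), pk_def, tg, method = "ode")
  expect_lt(max(abs(a$cp_mg_per_l - b$cp_mg_per_l)) / max(a$cp_mg_per_l), 1e-8)

  a2 <- simulate_plasma(dose_event(c(0, 600), 0.3, 64), pk_def, tg)
  b2 <- simulate_plasma(dose_event(c(0, 600), 0.3, 64), pk_def, tg,
                        method = "ode")
  expect_lt(max(abs(a2$cp_mg_per_l - b2$cp_mg_per_l)) / max(a2$cp_mg_per_l),
            1e-8)
})

test_that("drug amount is conserved when elimination is switched off", {
  pk0 <- pk_params(volumes = pk_def$volumes,
                   clearances = c(cl = 0, q2 = 0.012, q3 = 0.003), ke0 = 0.2)
  m <- rocumep:::pk_matrix(pk0, 64)
  st <- rocumep:::propagate_matexp(m$A, c(38.4, 0, 0), seq(0, 7200, 10),
                                   integer(0), numeric(0))
  expect_rel(rowSums(st), 38.4, 1e-8)
})

test_that("terminal log-slope equals the slowest eigenvalue of the system", {
  m <- rocumep:::pk_matrix(pk_def, 64)
  lam <- max(eigen(m$A, only.values = TRUE)$values)  # least negative
  tl <- seq(0, 360000, by = 600)
  cp <- simulate_plasma(dose_event(0, 0.6, 64), pk_def, tl)$cp_mg_per_l
  tail_i <- (length(tl) - 50):length(tl)
  slope <- stats::coef(stats::lm(log(cp[tail_i]) ~ tl[tail_i]))[[2]]
  expect_rel(slope, lam, 0.01)
})

test_that("effect site equilibrates to plasma and lags behind it", {
  # constant plasma level: Ce converges to Cp in uM (ke0 0.2/min: the
  # 3 h horizon is ~36 equilibration time constants)
  cp <- rep(2, 2161)
  ce <- effect_site(cp, seq(0, 10800, by = 5), ke0 = 0.2,
                    molar_mass = 609.68)
  expect_rel(ce[length(ce)], 2 * 1000 / 609.68, 1e-4)
  expect_equal(ce[1], 0)

  # near-instantaneous equilibration tracks Cp within 0.1% after one step
  prof <- simulate_pkpd_profile(tmax_s = 1800, dt_s = 1)
  ce_fast <- effect_site(prof$cp_mg_per_l, prof$time_s, ke0 = 6e4)
  expect_rel(ce_fast[-1], prof$cp_mg_per_l[-1] * 1000 / 609.68, 1e-3)

  # after a bolus the Ce peak comes strictly later than the Cp peak
  expect_gt(prof$time_s[which.max(prof$ce_um)],
            prof$time_s[which.max(prof$cp_mg_per_l)])
  # piecewise-exact integrator agrees with the joint matexp solution
  ce2 <- effect_site(prof$cp_mg_per_l, prof$time_s, pk_def$ke0,
                     pk_def$molar_mass)
  expect_rel(ce2[-1], prof$ce_um[-1], 1e-4)
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(pk_params(volumes = c(v1 = -1, v2 = 1, v3 = 1),
                         clearances = c(cl = 1, q2 = 1, q3 = 1), ke0 = 0.2),
               "positive")
  expect_error(pk_params(volumes = c(v1 = 1, v2 = 1), clearances = c(cl = 1, q2 = 1),
                         ke0 = 0), "ke0")
  expect_error(simulate_plasma(dose_event(-30, 0.6, 64), pk_def, tg),
               "before the first grid point")
  expect_error(simulate_plasma(dose_event(7, 0.6, 64), pk_def, tg),
               "on the time grid")
  expect_error(simulate_plasma(dose_event(0, 0.6, 64), pk_def, c(0, 10, 5)),
               "increasing")
  expect_error(effect_site(c(1, -1), 0:1, 0.2), "non-negative")
  expect_error(effect_site(c(1, 1), 0:1, -0.1), "ke0")
})
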