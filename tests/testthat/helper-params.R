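# shared fixtures: packaged parameter sets and variability-free variants
pd_tab <- load_pd_params()
cv_tab <- load_cv_params()
pk_def <- load_pk_params()
crit_amp <- attr(cv_tab, "critical_amplitude_uv")

zero_var_pd <- lapply(pd_tab, function(p) {
  p$bsv_sd[] <- 0
  p$wsv_sd <- 0
  p
})

quiet_config <- function(...) {
  cohort_config(pd = zero_var_pd, t1tc_noise_sd = 0, amplitude_noise = FALSE,
                occasion_wsv = FALSE, ...)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
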