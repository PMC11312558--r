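test_that("a noise-free subject lies exactly on the deterministic model curves", {
  co <- generate_cohort(1, quiet_config(), seed = 2)
  rec <- co$records
  t1 <- dplyr::filter(rec, .data$endpoint == "t1tc")
  expect_equal(t1$value, emax_response(t1$ce_um, zero_var_pd$t1tc),
               tolerance = 1e-12)
  for (m in c("Del", "APB", "TA", "AH")) {
    mus <- dplyr::filter(rec, .data$endpoint == m, !.data$below_floor)
    expect_equal(mus$value, emax_response(mus$ce_um, zero_var_pd[[m]]),
                 tolerance = 1e-12)
  }
})

test_that("cohort generation is deterministic: same seed, same bytes", {
  a <- generate_cohort(5, seed = 31)
  b <- generate_cohort(5, seed = 31)
  expect_identical(a$records, b$records)
  expect_identical(a$subjects, b$subjects)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort_csv(a, d1); write_cohort_csv(b, d2)
  expect_identical(readLines(file.path(d1, "records.csv")),
                   readLines(file.path(d2, "records.csv")))
  c_other <- generate_cohort(5, seed = 32)
  expect_false(identical(a$records$value, c_other$records$value))
})

test_that("missingness flags follow the requested MCAR rate", {
  co <- generate_cohort(10, seed = 6)
  none <- impose_missingness(co, 0, seed = 1)
  expect_equal(sum(none$records$missing), 0L)
  some <- impose_missingness(co, 0.2, seed = 1)
  n_mep <- sum(co$records$endpoint != "t1tc")
  x <- sum(some$records$missing)
  half_width <- stats::qnorm(0.995) * sqrt(n_mep * 0.2 * 0.8)
  expect_lt(abs(x - 0.2 * n_mep), half_width)
  # only MEP rows are flagged, flags reproduce under the seed
  expect_true(all(some$records$endpoint[some$records$missing] != "t1tc"))
  again <- impose_missingness(co, 0.2, seed = 1)
  expect_identical(some$records$missing, again$records$missing)
  expect_error(impose_missingness(co, 1), "\\[0, 1\\)")
})

test_that("regression imputation is exact for log-linear data and bounded in noise", {
  # subject whose amplitudes follow log(value + 1) = a + b * t1tc exactly
  t1tc <- rep(seq(0.1, 0.9, by = 0.1), each = 2)
  val <- exp(1.5 + 3.2 * t1tc) - 1
  rec <- tibble::tibble(subject_id = 1, time_s = seq_along(val) * 60,
                        endpoint = "Del", value = val, t1tc_obs = t1tc,
                        ce_um = 1, below_floor = FALSE, missing = FALSE,
                        imputed = FALSE)
  co <- structure(list(records = rec), class = "mep_cohort")
  cm <- impose_missingness(co, 0.3, seed = 2)
  ci <- regression_impute(cm)
  idx <- which(ci$records$imputed)
  expect_gt(length(idx), 0)
  expect_equal(ci$records$value[idx], ci$records$value_true[idx],
               tolerance = 1e-8)
  expect_true(all(ci$records$value[idx] >= 0))

  # on a realistic cohort at 10% MCAR the median relative error stays within
  # twice the simulated residual CV (<= ~0.4 at the amplitudes involved)
  co2 <- impose_missingness(generate_cohort(20, seed = 42), 0.1, seed = 3)
  ci2 <- suppressWarnings(regression_impute(co2))
  j <- which(ci2$records$imputed)
  rel_err <- abs(ci2$records$value[j] - ci2$records$value_true[j]) /
    pmax(ci2$records$value_true[j], 1)
  expect_lt(stats::median(rel_err), 2 * 0.4)
})

test_that("simulated population reproduces the baseline amplitude ordering", {
  co <- generate_cohort(100, seed = 17)
  med <- vapply(c("Del", "APB", "TA", "AH"), function(m) {
    stats::median(co$individual_pd[[m]]$baseline_i)
  }, numeric(1))
  # APB highest, deltoid lowest; TA and AH statistically indistinguishable
  expect_gt(med[["APB"]], med[["TA"]])
  expect_gt(med[["APB"]], med[["AH"]])
  expect_gt(med[["TA"]], med[["Del"]])
  expect_gt(med[["AH"]], med[["Del"]])
  expect_lt(abs(log(med[["TA"]] / med[["AH"]])), 0.5)
})

test_that("twitch and amplitudes recover within two hours for nearly all subjects", {
  co <- generate_cohort(100, seed = 21)
  ce_2h <- co$profile$ce_um[co$profile$time_s == 7200]
  t1 <- co$individual_pd$t1tc
  rec_t1 <- vapply(seq_len(100), function(i) {
    emax_response(ce_2h, rocumep:::as_pd_realization(t1[i, ]))
  }, numeric(1))
  expect_gte(mean(rec_t1 >= 0.95), 0.9)
  for (m in c("Del", "APB", "TA", "AH")) {
    ind <- co$individual_pd[[m]]
    frac <- vapply(seq_len(100), function(i) {
      p <- rocumep:::as_pd_realization(ind[i, ])
      emax_response(ce_2h, p) / p$baseline
    }, numeric(1))
    expect_gte(stats::median(frac), 0.9)
  }
})

test_that("cohort summaries round-trip through the variance-function fit", {
  co <- generate_cohort(100, seed = 21)
  s <- suppressWarnings(summarize_amplitudes(co, bias_correct = TRUE))
  # empirical CVs decrease with amplitude across pooled quartiles
  pooled <- dplyr::filter(s, !is.na(.data$cv))
  qs <- stats::quantile(pooled$mu, c(0, 0.25, 0.5, 0.75, 1))
  med_cv <- tapply(pooled$cv, cut(pooled$mu, qs, include.lowest = TRUE),
                   stats::median)
  expect_true(all(diff(med_cv) < 0))
  # the fitted deltoid maximum CV lands near the simulated alpha1 + alpha2
  fb <- suppressWarnings(fit_sigma_mu(dplyr::filter(s, .data$muscle == "Del"),
                                      "bi"))
  expect_true(fb$converged)
  a_sum <- sum(fb$estimates$value[fb$estimates$parameter %in%
                                    c("alpha1", "alpha2")])
  expect_rel(a_sum, cv_tab$Del$alpha1 + cv_tab$Del$alpha2, 0.2)
})
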