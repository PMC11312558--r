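test_that("fixed-effects fit recovers generating values from deterministic data", {
  co <- generate_cohort(12, quiet_config(), seed = 3)
  fit <- fit_population(co, endpoints = c("t1tc", "Del"),
                        random_effects = FALSE)
  expect_true(fit$converged)
  del <- stats::setNames(fit$endpoints$Del$fixed_effects$value,
                         fit$endpoints$Del$fixed_effects$parameter)
  expect_rel(del[["baseline"]], 366, 0.01)
  expect_rel(del[["ec50"]], 3.05, 0.01)
  expect_rel(del[["hill"]], 2.67, 0.01)
  t1 <- stats::setNames(fit$endpoints$t1tc$fixed_effects$value,
                        fit$endpoints$t1tc$fixed_effects$parameter)
  expect_rel(t1[["ec50"]], 2.69, 0.01)
  expect_rel(t1[["hill"]], 2.23, 0.01)
})

test_that("estimates are invariant to the ordering of input records", {
  co <- generate_cohort(12, seed = 8)
  rec <- co$records
  fit1 <- suppressWarnings(fit_population(rec, endpoints = "Del"))
  set.seed(99)
  shuffled <- rec[sample.int(nrow(rec)), ]
  fit2 <- suppressWarnings(fit_population(shuffled, endpoints = "Del"))
  expect_true(fit1$converged && fit2$converged)
  expect_rel(fit2$endpoints$Del$fixed_effects$value,
             fit1$endpoints$Del$fixed_effects$value, 1e-6)
})

test_that("population fits refuse degenerate cohorts", {
  co <- generate_cohort(4, seed = 1)
  expect_error(fit_population(co), "10 subjects")
})

test_that("empirical Bayes estimates vanish for subjects at the population values", {
  co <- generate_cohort(12, quiet_config(), seed = 5)
  ebe <- individual_ebe(co$records, "Del", pd_tab$Del, resid_sd = 0.3)
  expect_lt(max(abs(c(ebe$eta_baseline, ebe$eta_ec50, ebe$eta_hill))), 1e-3)
})

test_that("EBE shrinkage: sparse subjects shrink further towards the population", {
  co <- generate_cohort(50, seed = 9)
  rec <- dplyr::filter(co$records, .data$endpoint == "Del", !.data$below_floor)
  pick <- function(n) {
    dplyr::ungroup(dplyr::slice_sample(dplyr::group_by(rec, .data$subject_id),
                                       n = n))
  }
  set.seed(4)
  e_sparse <- individual_ebe(pick(2), "Del", pd_tab$Del, resid_sd = 0.4)
  e_rich <- individual_ebe(pick(50), "Del", pd_tab$Del, resid_sd = 0.4)
  expect_lt(mean(abs(e_sparse$eta_baseline)), mean(abs(e_rich$eta_baseline)))
})

test_that("individual predictions from EBEs track noise-free observations", {
  cfg <- cohort_config(t1tc_noise_sd = 0, amplitude_noise = FALSE,
                       occasion_wsv = FALSE)
  co <- generate_cohort(30, cfg, seed = 3)
  rec <- dplyr::filter(co$records, .data$endpoint == "Del",
                       !.data$below_floor)
  ebe <- individual_ebe(rec, "Del", pd_tab$Del, resid_sd = 0.1)
  joined <- dplyr::left_join(rec, ebe, by = "subject_id")
  pred <- joined$baseline_i * joined$ec50_i^joined$hill_i /
    (joined$ec50_i^joined$hill_i + joined$ce_um^joined$hill_i)
  expect_gt(stats::cor(log(joined$value), log(pred)), 0.95)
})

test_that("package EBEs agree with the mixed-model posterior modes", {
  co <- generate_cohort(30, seed = 14)
  fit <- suppressWarnings(fit_population(co, endpoints = "APB"))
  expect_true(fit$converged)
  f <- fit$endpoints$APB
  pop <- pd_params("APB",
                   baseline = f$fixed_effects$value[1],
                   ec50 = f$fixed_effects$value[2],
                   hill = f$fixed_effects$value[3],
                   bsv_sd = stats::setNames(f$random_effect_sds$sd,
                                            f$random_effect_sds$parameter))
  mine <- individual_ebe(co$records, "APB", pop, resid_sd = f$resid_sd)
  nlme_re <- nlme::ranef(f$fit)
  ord <- match(rownames(nlme_re), as.character(mine$subject_id))
  expect_gt(stats::cor(mine$eta_baseline[ord], nlme_re$lB), 0.95)
  expect_gt(stats::cor(mine$eta_ec50[ord], nlme_re$lE), 0.95)
})
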