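#' Configuration of the virtual monitoring cohort
#'
#' Bundles every knob of the virtual-trial generator. The defaults emulate
#' the monitored study design: a 0.6 mg/kg rocuronium bolus at induction,
#' T1/Tc sampled every 30 s, MEPs elicited periodically (every 2 min) plus
#' at the first crossing of each 10% T1/Tc increment during recovery, four
#' muscles, demographics drawn from the reported cohort moments
#' (weight 64 +/- 12 kg, height 163 +/- 8 cm, 59% female, truncated at
#' +/- 3 SD), and a 1 uV recording floor.
#'
#' @param pd Named list of [pd_params] (must contain `t1tc` plus the
#'   muscles); default the packaged population estimates.
#' @param cv Named list of [cv_params] per muscle; default packaged.
#' @param pk [pk_params]; default packaged.
#' @param muscles Muscles to simulate.
#' @param dose_mg_per_kg Bolus dose, mg/kg.
#' @param tmax_s Monitoring horizon, s.
#' @param dt_s PK grid step, s.
#' @param t1tc_interval_s Twitch sampling interval, s.
#' @param t1tc_noise_sd Additive observation noise SD on the logit of T1/Tc
#'   (not part of the published model; simulation plumbing).
#' @param mep_increments T1/Tc recovery thresholds triggering an MEP trial.
#' @param mep_interval_s Periodic MEP interval, s.
#' @param amplitude_noise Logical; apply proportional log-normal MEP noise
#'   whose CV equals the subject's bi-exponential CV at the predicted mean.
#' @param occasion_wsv Logical; apply the per-measurement log-normal
#'   baseline multiplier with the endpoint's WSV SD.
#' @param floor_uv Recording floor, uV; simulated amplitudes below it are
#'   recorded at the floor and flagged `below_floor`.
#' @param cv_form Decay kernel of the CV model, see [cv_of_mu()].
#' @param weight_mean,weight_sd,height_mean,height_sd,female_prop,trunc_sd
#'   Demographic sampling moments.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(pd = load_pd_params(), cv = load_cv_params(),
                          pk = load_pk_params(),
                          muscles = c("Del", "APB", "TA", "AH"),
                          dose_mg_per_kg = 0.6, tmax_s = 9000, dt_s = 1,
                          t1tc_interval_s = 30, t1tc_noise_sd = 0.05,
                          mep_increments = seq(0.1, 0.9, by = 0.1),
                          mep_interval_s = 120, amplitude_noise = TRUE,
                          occasion_wsv = TRUE, floor_uv = 1,
                          cv_form = "efold",
                          weight_mean = 64, weight_sd = 12,
                          height_mean = 163, height_sd = 8,
                          female_prop = 0.59, trunc_sd = 3) {
  if (!all(c("t1tc", muscles) %in% names(pd))) {
    stop("`pd` must contain 't1tc' and every requested muscle", call. = FALSE)
  }
  if (!all(muscles %in% names(cv))) {
    stop("`cv` must contain every requested muscle", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, k) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- abs(x - mean) > k * sd)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Sample individual CV-model parameters
#'
#' Log-normal between-subject draws from a population [cv_params] set,
#' mirroring [sample_individual()] for the variance-function model.
#'
#' @param pop Population [cv_params].
#' @param n Number of subjects.
#' @param seed Optional seed.
#' @return A tibble with `subject_id` and realised `alpha1`, `alpha2`,
#'   `mu50_1`, `mu50_2`.
#' @export
sample_cv_individual <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "cv_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  re <- pop$random_effect_sd
  eta <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  tibble::tibble(
    subject_id = seq_len(n),
    alpha1 = pop$alpha1 * exp(eta(re[["alpha1"]])),
    alpha2 = pop$alpha2 * exp(eta(re[["alpha2"]])),
    mu50_1 = pop$mu50_1 * exp(eta(re[["mu50_1"]])),
    mu50_2 = pop$mu50_2 * exp(eta(re[["mu50_2"]]))
  )
}

first_crossings <- function(time_s, t1tc_obs, thresholds) {
  i0 <- which.min(t1tc_obs)  # deepest observed block
  if (i0 >= length(t1tc_obs)) return(numeric(0))
  seg_t <- time_s[i0:length(time_s)]
  seg_v <- t1tc_obs[i0:length(t1tc_obs)]
  out <- vapply(thresholds, function(th) {
    j <- which(seg_v >= th)[1]
    if (is.na(j)) NA_real_ else seg_t[j]
  }, numeric(1))
  out[!is.na(out)]
}

#' Generate a virtual monitoring cohort
#'
#' Simulates the full per-subject data stream of the monitoring design:
#' demographics, bolus dosing, the shared rocuronium exposure profile
#' (weight-proportional dosing with per-kg parameters makes concentrations
#' weight-invariant), individual Emax parameters for T1/Tc and each muscle,
#' noisy T1/Tc observations every 30 s, and MEP amplitudes at each 10%
#' T1/Tc recovery increment plus a periodic schedule, with
#' amplitude-dependent proportional noise and a recording floor.
#'
#' @param n Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical seed and config reproduce the cohort
#'   exactly.
#' @return An object of class `mep_cohort`: a list with `subjects`,
#'   `records` (long format: `subject_id`, `time_s`, `endpoint`, `value`,
#'   `t1tc_obs`, `ce_um`, `below_floor`, `missing`, `imputed`),
#'   `individual_pd` (realised Emax parameters), `individual_cv`, `profile`
#'   (the exposure profile), `config` and `seed`.
#' @export
generate_cohort <- function(n = 100, config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  subjects <- tibble::tibble(
    subject_id = seq_len(n),
    sex = ifelse(stats::runif(n) < cfg$female_prop, "F", "M"),
    weight_kg = rnorm_trunc(n, cfg$weight_mean, cfg$weight_sd, cfg$trunc_sd),
    height_cm = rnorm_trunc(n, cfg$height_mean, cfg$height_sd, cfg$trunc_sd),
    dose_mg_per_kg = cfg$dose_mg_per_kg, dose_time_s = 0
  )
  profile <- simulate_pkpd_profile(cfg$dose_mg_per_kg, weight = 70,
                                   params = cfg$pk, tmax_s = cfg$tmax_s,
                                   dt_s = cfg$dt_s)
  ce_at <- function(times) {
    stats::approx(profile$time_s, profile$ce_um, xout = times, rule = 2)$y
  }
  endpoints <- c("t1tc", cfg$muscles)
  ind_pd <- lapply(endpoints, function(ep) sample_individual(cfg$pd[[ep]], n))
  names(ind_pd) <- endpoints
  ind_cv <- lapply(cfg$muscles, function(m) sample_cv_individual(cfg$cv[[m]], n))
  names(ind_cv) <- cfg$muscles

  t_t1 <- seq(0, cfg$tmax_s, by = cfg$t1tc_interval_s)
  ce_t1 <- ce_at(t_t1)
  periodic <- seq(0, cfg$tmax_s, by = cfg$mep_interval_s)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    p_t <- as_pd_realization(ind_pd$t1tc[i, ])
    m_t1 <- emax_response(ce_t1, p_t)
    if (cfg$t1tc_noise_sd > 0) {
      lg <- stats::qlogis(pmin(pmax(m_t1, 1e-9), 1 - 1e-9))
      obs_t1 <- stats::plogis(lg + stats::rnorm(length(lg), 0, cfg$t1tc_noise_sd))
    } else {
      obs_t1 <- m_t1
    }
    t1_rec <- tibble::tibble(subject_id = i, time_s = t_t1, endpoint = "t1tc",
                             value = obs_t1, t1tc_obs = obs_t1, ce_um = ce_t1,
                             below_floor = FALSE)
    t_mep <- sort(unique(c(periodic,
                           first_crossings(t_t1, obs_t1, cfg$mep_increments))))
    ce_mep <- ce_at(t_mep)
    t1_at_mep <- stats::approx(t_t1, obs_t1, xout = t_mep, rule = 2)$y
    mus <- lapply(cfg$muscles, function(m) {
      p_m <- as_pd_realization(ind_pd[[m]][i, ])
      pred <- emax_response(ce_mep, p_m)
      wsv <- cfg$pd[[m]]$wsv_sd
      if (cfg$occasion_wsv && wsv > 0) {
        pred <- pred * exp(stats::rnorm(length(pred), 0, wsv))
      }
      if (cfg$amplitude_noise) {
        cvp_i <- as.list(ind_cv[[m]][i, ])
        cv <- cv_of_mu(pred, cvp_i, form = cfg$cv_form)
        sdlog <- sqrt(log1p(cv^2))  # lognormal with SD/mean exactly cv
        obs <- pred * exp(stats::rnorm(length(pred), 0, sdlog))
      } else {
        obs <- pred
      }
      below <- obs < cfg$floor_uv
      tibble::tibble(subject_id = i, time_s = t_mep, endpoint = m,
                     value = ifelse(below, cfg$floor_uv, obs),
                     t1tc_obs = t1_at_mep, ce_um = ce_mep, below_floor = below)
    })
    recs[[i]] <- dplyr::bind_rows(c(list(t1_rec), mus))
  }
  records <- dplyr::bind_rows(recs)
  records$missing <- FALSE
  records$imputed <- FALSE
  structure(list(subjects = subjects, records = records,
                 individual_pd = ind_pd, individual_cv = ind_cv,
                 profile = profile, config = cfg, seed = seed),
            class = "mep_cohort")
}

#' @export
print.mep_cohort <- function(x, ...) {
  cat(sprintf("<mep_cohort> %d subjects, %d records (%d MEP, %d T1/Tc)\n",
              nrow(x$subjects), nrow(x$records),
              sum(x$records$endpoint != "t1tc"),
              sum(x$records$endpoint == "t1tc")))
  invisible(x)
}

#' Flag MEP records as missing
#'
#' Marks MEP amplitude records missing completely at random at the given
#' rate. The generating value is retained in `value_true` so that
#' imputation accuracy can be scored.
#'
#' @param cohort An `mep_cohort`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param mechanism Only `"mcar"` is implemented (the study protocol does
#'   not state a mechanism).
#' @param seed Optional seed.
#' @return The cohort with `missing` flags set and `value` blanked to NA on
#'   flagged rows.
#' @export
impose_missingness <- function(cohort, rate, mechanism = "mcar", seed = NULL) {
  stopifnot(inherits(cohort, "mep_cohort"))
  mechanism <- match.arg(mechanism, "mcar")
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("`rate` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- cohort$records
  r$value_true <- r$value
  is_mep <- r$endpoint != "t1tc"
  hit <- is_mep & stats::runif(nrow(r)) < rate
  r$missing <- hit
  r$value[hit] <- NA_real_
  cohort$records <- r
  cohort
}

#' Regression imputation of missing MEP amplitudes
#'
#' Replaces each missing amplitude by the prediction of a per-subject,
#' per-muscle linear regression of `log(amplitude + 1)` on the concurrent
#' T1/Tc, fitted to that subject's non-missing records. Groups with fewer
#' than 3 non-missing records, or without meaningful T1/Tc spread, are left
#' missing with a warning. Imputed values are non-negative by construction.
#'
#' @param cohort An `mep_cohort` with `missing` flags (see
#'   [impose_missingness()] or real data flags).
#' @param min_obs Minimum non-missing records per group (default 3).
#' @param min_span Minimum T1/Tc spread in the group (default 0.1).
#' @return The cohort with imputations filled in and `imputed` flags set.
#' @export
regression_impute <- function(cohort, min_obs = 3L, min_span = 0.1) {
  stopifnot(inherits(cohort, "mep_cohort"))
  r <- cohort$records
  idx_missing <- which(r$missing & r$endpoint != "t1tc")
  if (length(idx_missing) == 0L) return(cohort)
  skipped <- 0L
  for (grp in split(idx_missing,
                    paste(r$subject_id[idx_missing], r$endpoint[idx_missing]))) {
    sid <- r$subject_id[grp[1]]
    ep <- r$endpoint[grp[1]]
    obs <- r$subject_id == sid & r$endpoint == ep & !r$missing & !is.na(r$value)
    if (sum(obs) < min_obs ||
        diff(range(r$t1tc_obs[obs])) < min_span) {
      skipped <- skipped + length(grp)
      next
    }
    fit <- stats::lm(log(value + 1) ~ t1tc_obs, data = r[obs, ])
    pred <- stats::predict(fit, newdata = r[grp, ])
    r$value[grp] <- pmax(exp(pred) - 1, 0)
    r$imputed[grp] <- TRUE
    r$missing[grp] <- FALSE
  }
  if (skipped > 0L) {
    warning(skipped, " missing record(s) left unimputed (insufficient data)",
            call. = FALSE)
  }
  cohort$records <- r
  cohort
}

#' Simulate per-subject sigma--mu summaries from a CV model
#'
#' Direct generator for variance-function experiments (model selection and
#' parameter recovery): each subject receives log-normal realisations of the
#' CV parameters, a set of mean amplitudes log-uniform over `mu_range`, and
#' observed SDs `sigma = mu * CV_i(mu) * exp(eps)` with log-normal residual
#' `eps ~ N(0, resid_sd^2)`.
#'
#' @param n_subjects Number of subjects.
#' @param cv_pop Population [cv_params] (set its `random_effect_sd` to zero
#'   for a fixed-effects-only truth).
#' @param m_per_subject Amplitude levels per subject (default 8).
#' @param mu_range Amplitude range, uV (default 30 to 6000).
#' @param resid_sd Residual SD on log sigma (default 0.2).
#' @param form Decay kernel.
#' @param model `"bi"` or `"mono"` (mono uses only the first exponential).
#' @param seed Optional seed.
#' @return A tibble compatible with [fit_sigma_mu()] (`subject_id`, `mu`,
#'   `sigma`, `cv`, `n_obs`).
#' @export
simulate_sigma_summaries <- function(n_subjects, cv_pop, m_per_subject = 8,
                                     mu_range = c(30, 6000), resid_sd = 0.2,
                                     form = c("efold", "half"),
                                     model = c("bi", "mono"), seed = NULL) {
  form <- match.arg(form)
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  ind <- sample_cv_individual(cv_pop, n_subjects)
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    mu <- exp(stats::runif(m_per_subject, log(mu_range[1]), log(mu_range[2])))
    p_i <- as.list(ind[i, ])
    cv_true <- if (model == "bi") {
      cv_of_mu(mu, p_i, form)
    } else {
      p_i$alpha1 * cv_kernel(mu / p_i$mu50_1, form)
    }
    sigma <- mu * cv_true * exp(stats::rnorm(m_per_subject, 0, resid_sd))
    tibble::tibble(subject_id = i, mu = mu, sigma = sigma,
                   cv = sigma / mu, n_obs = 10L)
  })
}
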