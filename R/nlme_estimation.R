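#' Fit population Emax models to longitudinal cohort data
#'
#' Estimates, per endpoint, the fixed effects (baseline, EC50, Hill; the
#' T1/Tc endpoint has its baseline fixed at 1) and the log-normal
#' between-subject variability SDs by approximate marginal maximum
#' likelihood. Pharmacokinetics are taken as known: every record must carry
#' its effect-site concentration (`ce_um`), as produced by
#' [generate_cohort()] or [attach_ce()]. Endpoints are fitted independently
#' and sequentially (T1/Tc first), matching the per-endpoint structure of
#' the published estimates. Muscle amplitudes are modelled on the log scale
#' (proportional residual); T1/Tc on the logit scale (additive residual).
#' Records flagged missing or below the recording floor are excluded
#' (truncation; see the methods vignette for the rationale and its limits).
#'
#' Estimation uses [nlme::nlme()] (Lindstrom-Bates) on the log-parameter
#' scale, with data-driven starts: the baseline from per-subject maxima, the
#' EC50 from the concentration at which each subject crosses half its
#' recovery range, and a Hill start of 2. Rows are canonicalised by subject
#' and time so estimates do not depend on input ordering.
#'
#' @param cohort An `mep_cohort` or a records tibble with `subject_id`,
#'   `endpoint`, `time_s`, `value`, `ce_um` (plus optional `missing`,
#'   `below_floor` flags).
#' @param endpoints Endpoints to fit; default all present.
#' @param random_effects Logical; `FALSE` drops the random effects and fits
#'   fixed effects only by [stats::nls()] (useful on deterministic data).
#' @param seed Integer recorded in the result (estimation itself is
#'   deterministic).
#' @return An object of class `pd_fit`: per-endpoint elements each holding
#'   `fixed_effects` (natural scale with approximate %RSE from the
#'   observed information), `random_effect_sds` (log-scale SDs, %RSE from
#'   the approximate variance of the variance parameters where available),
#'   `resid_sd`, `loglik`, `aic`, `k` and `converged`; plus `seed` and an
#'   overall `converged` flag. Non-convergence is flagged, never silent.
#' @export
fit_population <- function(cohort, endpoints = NULL, random_effects = TRUE,
                           seed = NULL) {
  records <- if (inherits(cohort, "mep_cohort")) cohort$records else cohort
  stopifnot(all(c("subject_id", "endpoint", "value", "ce_um") %in%
                  names(records)))
  if (length(unique(records$subject_id)) < 10L) {
    stop("refusing to fit a population model on fewer than 10 subjects",
         call. = FALSE)
  }
  if (is.null(endpoints)) endpoints <- unique(records$endpoint)
  fits <- lapply(endpoints, function(ep) {
    fit_one_endpoint(records, ep, random_effects)
  })
  names(fits) <- endpoints
  structure(list(endpoints = fits, seed = seed,
                 converged = all(vapply(fits, `[[`, TRUE, "converged"))),
            class = "pd_fit")
}

endpoint_data <- function(records, ep) {
  d <- dplyr::filter(records, .data$endpoint == ep, !is.na(.data$value))
  if ("missing" %in% names(d)) d <- dplyr::filter(d, !.data$missing)
  if ("imputed" %in% names(d)) d <- dplyr::filter(d, !.data$imputed)
  if ("below_floor" %in% names(d)) d <- dplyr::filter(d, !.data$below_floor)
  d <- dplyr::arrange(d, .data$subject_id, .data$time_s)
  if (ep == "t1tc") {
    d <- dplyr::filter(d, .data$value > 0.005, .data$value < 0.995,
                       .data$ce_um > 1e-6)
    d$y <- stats::qlogis(d$value)
  } else {
    d <- dplyr::filter(d, .data$value > 0)
    d$y <- log(d$value)
  }
  d$lce <- log(pmax(d$ce_um, 1e-12))
  as.data.frame(d)
}

# Data-driven starting values. T1/Tc: the logit is linear in log(ce)
# (slope -Hill, intercept Hill*log(EC50)), so a pooled regression yields
# both starts. Muscles: a robust per-subject baseline proxy (90th value
# percentile, insensitive to log-normal noise maxima), the EC50 from the
# median concentration among mid-range responses, Hill start 2.
endpoint_starts <- function(d, ep) {
  if (ep == "t1tc") {
    cf <- stats::coef(stats::lm(y ~ lce, data = d))
    h <- max(-cf[[2]], 0.3)
    return(c(lE = cf[[1]] / h, lH = log(h)))
  }
  b_s <- tapply(d$value, d$subject_id, stats::quantile, probs = 0.9)
  prox <- b_s[as.character(d$subject_id)]
  mid <- d$value > 0.3 * prox & d$value < 0.7 * prox & d$ce_um > 0.05
  ce_mid <- if (any(mid)) stats::median(d$ce_um[mid]) else
    stats::median(d$ce_um[d$ce_um > 0.05])
  c(lB = log(stats::median(b_s)), lE = log(max(ce_mid, 1e-3)),
    lH = log(2))
}

fit_one_endpoint <- function(records, ep, random_effects = TRUE) {
  d <- endpoint_data(records, ep)
  start <- endpoint_starts(d, ep)
  if (ep == "t1tc") {
    rhs <- y ~ exp(lH) * (lE - lce)
    nat_names <- c("ec50", "hill")
  } else {
    rhs <- y ~ lB - log1p(exp(exp(lH) * (lce - lE)))
    nat_names <- c("baseline", "ec50", "hill")
  }
  pnames <- names(start)
  msg <- NA_character_
  if (random_effects) {
    fx <- stats::as.formula(paste(paste(pnames, collapse = " + "), "~ 1"))
    # PNLS step halving is sensitive to its tolerance on steep Emax data;
    # retry with progressively relaxed pnlsTol before declaring failure
    fit <- NULL
    for (ptol in c(1e-3, 1e-2, 1e-1)) {
      fit <- tryCatch(
        nlme::nlme(rhs, data = d, fixed = fx, random = nlme::pdDiag(fx),
                   groups = ~subject_id, start = start, method = "ML",
                   control = nlme::nlmeControl(maxIter = 400,
                                               pnlsMaxIter = 25,
                                               msMaxIter = 300,
                                               pnlsTol = ptol)),
        error = function(e) {msg <<- conditionMessage(e); NULL})
      if (!is.null(fit)) {
        msg <- NA_character_
        break
      }
    }
  } else {
    fit <- tryCatch(
      # scaleOffset keeps the convergence test meaningful on (near-)
      # noise-free data, where the residual sum of squares tends to zero
      stats::nls(rhs, data = d, start = start,
                 control = stats::nls.control(maxiter = 200,
                                              scaleOffset = 1)),
      error = function(e) {msg <<- conditionMessage(e); NULL})
  }
  if (is.null(fit)) {
    return(list(endpoint = ep, converged = FALSE, message = msg,
                fixed_effects = NULL, random_effect_sds = NULL,
                resid_sd = NA_real_, loglik = NA_real_, aic = NA_real_,
                k = NA_integer_, n_obs = nrow(d)))
  }
  cf <- if (random_effects) nlme::fixef(fit) else stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  fixed <- tibble::tibble(parameter = nat_names,
                          value = exp(unname(cf[pnames])),
                          rse_pct = 100 * unname(se[seq_along(pnames)]))
  re <- NULL
  if (random_effects) {
    vc <- nlme::VarCorr(fit)
    re_rse <- rep(NA_real_, length(pnames))
    av <- fit$apVar
    if (is.matrix(av)) {
      # apVar rows are on the log-SD scale; SE(log sd) * 100 ~ %RSE of the SD
      se_log <- sqrt(diag(av))
      re_rse <- 100 * se_log[seq_along(pnames)]
    }
    re <- tibble::tibble(parameter = nat_names,
                         sd = as.numeric(vc[pnames, "StdDev"]),
                         rse_pct = re_rse)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  list(endpoint = ep, converged = TRUE, message = msg, fixed_effects = fixed,
       random_effect_sds = re, resid_sd = stats::sigma(fit), loglik = ll,
       aic = 2 * k - 2 * ll, k = k, n_obs = nrow(d), fit = fit)
}

#' @export
print.pd_fit <- function(x, ...) {
  cat("<pd_fit> population Emax estimates\n")
  for (ep in names(x$endpoints)) {
    f <- x$endpoints[[ep]]
    if (!f$converged) {
      cat(sprintf("  %s: DID NOT CONVERGE (%s)\n", ep, f$message))
      next
    }
    est <- paste(sprintf("%s %.4g", f$fixed_effects$parameter,
                         f$fixed_effects$value), collapse = ", ")
    cat(sprintf("  %s (n=%d): %s; AIC %.1f\n", ep, f$n_obs, est, f$aic))
  }
  invisible(x)
}

#' Attach effect-site concentrations to a records table
#'
#' For externally supplied long-format data, computes the rocuronium
#' effect-site concentration at every record time from the subject's dosing
#' (one weight-based bolus per subject) and a PK parameter set.
#'
#' @param records Tibble with `subject_id`, `time_s`.
#' @param subjects Tibble with `subject_id`, `weight_kg`, `dose_mg_per_kg`,
#'   `dose_time_s`.
#' @param pk [pk_params].
#' @param dt_s Internal simulation step, s.
#' @return `records` with a `ce_um` column.
#' @export
attach_ce <- function(records, subjects, pk = load_pk_params(), dt_s = 1) {
  tmax <- max(records$time_s)
  prof <- simulate_pkpd_profile(dose_mg_per_kg = subjects$dose_mg_per_kg[1],
                                weight = subjects$weight_kg[1], params = pk,
                                tmax_s = tmax + dt_s, dt_s = dt_s,
                                dose_times_s = subjects$dose_time_s[1])
  # per-kg parameters + per-kg dosing: the concentration profile is
  # weight-invariant, so one profile serves all subjects
  records$ce_um <- stats::approx(prof$time_s, prof$ce_um,
                                 xout = records$time_s, rule = 2)$y
  records
}

#' Empirical Bayes estimates of individual random effects
#'
#' Posterior-mode (MAP) estimation of each subject's log-scale random
#' effects given known population parameters: minimises the penalised
#' residual sum of squares
#' `sum((y_ij - f(ce_ij, theta exp(eta)))^2) / (2 sigma^2) +
#'  sum(eta_k^2) / (2 omega_k^2)` per subject, on the same observation
#' scales as [fit_population()] (logit for T1/Tc, log for amplitudes).
#' Parameters with zero BSV SD have their random effect pinned at zero.
#'
#' @param records Records tibble or `mep_cohort` (one endpoint is
#'   extracted).
#' @param endpoint Endpoint to evaluate.
#' @param pop Population [pd_params] (typical values).
#' @param re_sd Named BSV SDs (`baseline`, `ec50`, `hill`); defaults to
#'   `pop$bsv_sd`.
#' @param resid_sd Residual SD on the observation scale.
#' @return A tibble with `subject_id`, `eta_baseline`, `eta_ec50`,
#'   `eta_hill`, the realised individual parameters, and `n_obs`.
#' @export
individual_ebe <- function(records, endpoint, pop, re_sd = NULL,
                           resid_sd = 0.3) {
  if (inherits(records, "mep_cohort")) records <- records$records
  if (is.null(re_sd)) re_sd <- pop$bsv_sd
  d <- endpoint_data(records, endpoint)
  if (nrow(d) == 0L) stop("no usable observations for endpoint ", endpoint,
                          call. = FALSE)
  est <- if (endpoint == "t1tc") c("ec50", "hill") else
    c("baseline", "ec50", "hill")
  free <- est[re_sd[est] > 0]
  purrr::map_dfr(split(d, d$subject_id), function(s) {
    obj <- function(eta_free) {
      eta <- stats::setNames(numeric(3), c("baseline", "ec50", "hill"))
      eta[free] <- eta_free
      p <- list(baseline = pop$baseline * exp(eta[["baseline"]]),
                ec50 = pop$ec50 * exp(eta[["ec50"]]),
                hill = pop$hill * exp(eta[["hill"]]))
      pred <- if (endpoint == "t1tc") {
        m <- emax_response(s$ce_um, p)
        stats::qlogis(pmin(pmax(m, 1e-9), 1 - 1e-9))
      } else {
        log(emax_response(s$ce_um, p))
      }
      sum((s$y - pred)^2) / (2 * resid_sd^2) +
        sum((eta_free / re_sd[free])^2) / 2
    }
    eta_hat <- stats::setNames(numeric(3), c("baseline", "ec50", "hill"))
    if (length(free) > 0) {
      opt <- stats::optim(stats::setNames(numeric(length(free)), free), obj,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      eta_hat[free] <- opt$par
    }
    tibble::tibble(subject_id = s$subject_id[1],
                   eta_baseline = eta_hat[["baseline"]],
                   eta_ec50 = eta_hat[["ec50"]],
                   eta_hill = eta_hat[["hill"]],
                   baseline_i = pop$baseline * exp(eta_hat[["baseline"]]),
                   ec50_i = pop$ec50 * exp(eta_hat[["ec50"]]),
                   hill_i = pop$hill * exp(eta_hat[["hill"]]),
                   n_obs = nrow(s))
  })
}
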