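#' Per-subject amplitude summaries by blockade stratum
#'
#' Computes the mean, standard deviation (n-1 denominator) and coefficient
#' of variation of repeated MEP amplitude measurements within
#' subject x muscle x T1/Tc-stratum groups. These summaries are the raw
#' material of the variance-function regression ([fit_sigma_mu()]).
#'
#' @param records A [generate_cohort()] object or a tibble of amplitude
#'   records with columns `subject_id`, `endpoint`, `value`, `t1tc_obs`
#'   (the concurrent T1/Tc) and optionally `missing`.
#' @param breaks T1/Tc stratum boundaries (default deciles `seq(0, 1, 0.1)`).
#' @param bias_correct Divide each group SD by the Gaussian small-sample
#'   factor c4(n) (E\[s\] = c4 sigma; c4(2) = 0.80, c4(5) = 0.94), removing
#'   the downward bias of SDs from very small groups. Off by default (the
#'   plain sigma/mu definition); recommended when many groups have fewer
#'   than ~5 observations, as in variance-function fitting.
#' @return A tibble with `subject_id`, `muscle`, `stratum`, `mu`, `sigma`,
#'   `cv` (NA with `zero_mean = TRUE` for all-zero groups) and `n_obs`.
#'   Single-observation groups are dropped with one summarising warning.
#' @export
summarize_amplitudes <- function(records, breaks = seq(0, 1, by = 0.1),
                                 bias_correct = FALSE) {
  if (inherits(records, "mep_cohort")) records <- records$records
  rec <- dplyr::filter(records, .data$endpoint != "t1tc", !is.na(.data$value))
  if ("missing" %in% names(rec)) rec <- dplyr::filter(rec, !.data$missing)
  if (any(rec$value < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  rec$stratum <- cut(pmin(rec$t1tc_obs, max(breaks)), breaks,
                     include.lowest = TRUE)
  out <- rec |>
    dplyr::group_by(subject_id = .data$subject_id, muscle = .data$endpoint,
                    stratum = .data$stratum) |>
    dplyr::summarise(mu = mean(.data$value), sigma = stats::sd(.data$value),
                     n_obs = dplyr::n(), .groups = "drop")
  n_single <- sum(out$n_obs < 2L)
  if (n_single > 0) {
    warning(n_single, " single-observation group(s) excluded", call. = FALSE)
    out <- dplyr::filter(out, .data$n_obs >= 2L)
  }
  if (bias_correct) {
    c4 <- sqrt(2 / (out$n_obs - 1)) *
      exp(lgamma(out$n_obs / 2) - lgamma((out$n_obs - 1) / 2))
    out$sigma <- out$sigma / c4
  }
  out$zero_mean <- out$mu == 0
  out$cv <- ifelse(out$zero_mean, NA_real_, out$sigma / out$mu)
  dplyr::select(out, "subject_id", "muscle", "stratum", "mu", "sigma",
                "cv", "n_obs", "zero_mean")
}

cv_kernel <- function(x, form) {
  switch(form, efold = exp(-x), half = 2^(-x),
         stop("unknown form: ", form, call. = FALSE))
}

#' Coefficient of variation as a function of mean amplitude
#'
#' Evaluates the bi-exponential variance-function model
#' `CV(mu) = alpha1 * g(mu/mu50_1) + alpha2 * g(mu/mu50_2)`, strictly
#' decreasing from `CV(0) = alpha1 + alpha2` towards zero. The default decay
#' kernel is `g(x) = exp(-x)` (`form = "efold"`, under which each `mu50` is
#' an e-folding amplitude); `form = "half"` uses `g(x) = 2^(-x)` so each
#' term halves at its `mu50`. See the methods vignette for why e-fold is
#' the default.
#'
#' @param mu Mean amplitude(s), uV, non-negative.
#' @param p A [cv_params] object (or a subject-level realisation with the
#'   same fields).
#' @param form `"efold"` (default) or `"half"`.
#' @return CV value(s), dimensionless.
#' @export
cv_of_mu <- function(mu, p, form = c("efold", "half")) {
  form <- match.arg(form)
  if (any(mu < 0)) stop("`mu` must be non-negative", call. = FALSE)
  p$alpha1 * cv_kernel(mu / p$mu50_1, form) +
    p$alpha2 * cv_kernel(mu / p$mu50_2, form)
}

#' Amplitude attaining a target coefficient of variation
#'
#' Inverts [cv_of_mu()]: finds the unique `mu` with `CV(mu) = cv_target`
#' by bisection on the strictly decreasing CV function (converged to 1e-10
#' relative within 200 iterations). A target at or above the maximum
#' `alpha1 + alpha2` is reached only at zero amplitude, returned as
#' `mu = 0` with `boundary = TRUE`.
#'
#' @param cv_target Target CV, > 0 (dimensionless, e.g. 0.25 for 25%).
#' @param p A [cv_params] object.
#' @param form Decay kernel, see [cv_of_mu()].
#' @return A list with `mu` (uV) and `boundary`.
#' @export
solve_mu_for_cv <- function(cv_target, p, form = c("efold", "half")) {
  form <- match.arg(form)
  if (!is.numeric(cv_target) || length(cv_target) != 1L || cv_target <= 0) {
    stop("`cv_target` must be a single positive value", call. = FALSE)
  }
  cv0 <- p$alpha1 + p$alpha2
  if (cv_target >= cv0) return(list(mu = 0, boundary = TRUE))
  lo <- 0
  hi <- p$mu50_2
  while (cv_of_mu(hi, p, form) > cv_target) hi <- hi * 2
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (cv_of_mu(mid, p, form) > cv_target) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-10 * max(hi, 1)) break
  }
  list(mu = (lo + hi) / 2, boundary = FALSE)
}

sigma_mu_rhs <- function(model, form) {
  # log sigma = log mu + log CV(mu); kernel absorbed via scale constant
  cns <- if (form == "half") log(2) else 1
  if (model == "mono") {
    stats::as.formula(sprintf(
      "lsig ~ lmu + la1 - %.17g * mu * exp(-lm1)", cns))
  } else {
    stats::as.formula(sprintf(
      "lsig ~ lmu + log(exp(la1 - %.17g * mu * exp(-lm1)) + exp(la2 - %.17g * mu * exp(-lm2)))",
      cns, cns))
  }
}

sigma_mu_starts <- function(d, model, form) {
  cns <- if (form == "half") log(2) else 1
  mu_max <- max(d$mu)
  mu_min <- max(min(d$mu), 1)
  clamp_m <- function(m, lo, hi) min(max(m, lo), hi)
  lcv <- log(pmax(d$cv, 1e-6))
  hi <- d$mu > stats::median(d$mu)
  f2 <- stats::lm(lcv[hi] ~ d$mu[hi])
  a2 <- exp(min(max(stats::coef(f2)[1], -4), 0))
  m2 <- clamp_m(cns / max(-stats::coef(f2)[2], 1e-7),
                stats::median(d$mu), 5 * mu_max)
  if (model == "mono") {
    return(c(la1 = log(a2), lm1 = log(m2)))
  }
  res <- pmax(d$cv - a2 * cv_kernel(d$mu / m2, form), 1e-4)
  lo <- !hi
  f1 <- stats::lm(log(res[lo]) ~ d$mu[lo])
  a1 <- exp(min(max(stats::coef(f1)[1], -4), 0))
  m1 <- clamp_m(cns / max(-stats::coef(f1)[2], 1e-6), mu_min / 2, m2 / 5)
  c(la1 = log(a1), la2 = log(a2), lm1 = log(m1), lm2 = log(m2))
}

# refine heuristic starts by a fixed-effects nls pass, clamping runaway
# scale parameters (mu50_2 is often at its identifiability boundary)
sigma_mu_refine <- function(d, start, rhs) {
  f <- tryCatch(
    suppressWarnings(stats::nls(rhs, data = d, start = start,
                                control = stats::nls.control(
                                  maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(f)) return(start)
  cf <- stats::coef(f)
  if (any(!is.finite(cf))) return(start)
  lim <- log(10 * max(d$mu))
  cf["lm2"] <- min(cf[["lm2"]], lim)
  cf["lm1"] <- min(cf[["lm1"]], cf[["lm2"]] - log(5))
  cf["la1"] <- min(max(cf[["la1"]], -5), 1)
  cf["la2"] <- min(max(cf[["la2"]], -5), 1)
  cf[names(start)]
}

#' Fit the variance-function model to amplitude summaries
#'
#' Nonlinear regression of `log(sigma)` on `mu` under the mono- or
#' bi-exponential CV model, on the natural-log parameter scale. With
#' `random_effects = TRUE` (the default) log-normal between-subject random
#' effects with a diagonal covariance are placed on every parameter and the
#' model is fitted by [nlme::nlme()] (Lindstrom-Bates approximate marginal
#' likelihood); otherwise a fixed-effects-only [stats::nls()] fit is used.
#' The bi-exponential model nests the mono-exponential one (`alpha2 -> 0`),
#' so AIC comparison between the two is meaningful; `k` counts all estimated
#' fixed effects, random-effect SDs and the residual SD.
#'
#' @param summaries Output of [summarize_amplitudes()] (one muscle at a
#'   time), or any tibble with `subject_id`, `mu`, `sigma` (`cv` optional).
#' @param model `"bi"` (default) or `"mono"`.
#' @param random_effects Logical; fit subject-level random effects.
#' @param form Decay kernel, see [cv_of_mu()].
#' @param control Passed to [nlme::nlmeControl()].
#' @return An object of class `sigma_mu_fit`: estimates on the natural scale
#'   with approximate %RSE, random-effect SDs, `loglik`, `aic`, `k` and a
#'   `converged` flag (failures are flagged, never silently dropped).
#' @export
fit_sigma_mu <- function(summaries, model = c("bi", "mono"),
                         random_effects = TRUE, form = c("efold", "half"),
                         control = NULL) {
  model <- match.arg(model)
  form <- match.arg(form)
  d <- dplyr::filter(summaries, .data$mu > 0, .data$sigma > 0)
  if (nrow(d) < 20L) stop("need at least 20 usable summaries", call. = FALSE)
  if (is.null(d$cv)) d$cv <- d$sigma / d$mu
  d <- dplyr::arrange(d, .data$subject_id, .data$mu)
  d$lsig <- log(d$sigma)
  d$lmu <- log(d$mu)
  rhs <- sigma_mu_rhs(model, form)
  start <- sigma_mu_starts(d, model, form)
  pnames <- names(start)
  fit <- NULL
  msg <- NA_character_
  re_used <- pnames
  if (random_effects) {
    # convergence ladder: relax the PNLS tolerance, refine the starts by a
    # fixed-effects nls pass, and as a last resort drop random effects on
    # the weakly informed scale parameters (mu50_2 foremost; its random
    # effect is near the identifiability boundary on realistic data). The
    # attempt used is recorded in `message`.
    refined <- if (model == "bi") sigma_mu_refine(d, start, rhs) else start
    attempts <- list(
      list(st = start, re = pnames, ptol = 1e-3, pmax = 10),
      list(st = start, re = pnames, ptol = 1e-2, pmax = 10),
      list(st = refined, re = pnames, ptol = 1e-2, pmax = 10),
      list(st = refined, re = setdiff(pnames, "lm2"), ptol = 1e-2,
           pmax = 10),
      list(st = refined, re = intersect(pnames, c("la1", "la2", "lm1")),
           ptol = 1e-1, pmax = 25),
      list(st = refined, re = intersect(pnames, c("la1", "lm1")),
           ptol = 1e-1, pmax = 25)
    )
    fit <- NULL
    tried <- character(0)
    for (at in attempts) {
      if (length(at$re) == 0L) next
      key <- paste(paste(at$re, collapse = ","), at$ptol,
                   paste(round(at$st, 6), collapse = ","))
      if (key %in% tried) next
      tried <- c(tried, key)
      ctrl <- do.call(nlme::nlmeControl,
                      c(list(maxIter = 100, pnlsMaxIter = at$pmax,
                             msMaxIter = 200, pnlsTol = at$ptol), control))
      fit <- tryCatch(
        nlme::nlme(rhs, data = as.data.frame(d),
                   fixed = stats::as.formula(
                     paste(paste(pnames, collapse = " + "), "~ 1")),
                   random = nlme::pdDiag(stats::as.formula(
                     paste(paste(at$re, collapse = " + "), "~ 1"))),
                   groups = ~subject_id,
                   start = at$st, control = ctrl, method = "ML"),
        error = function(e) {msg <<- conditionMessage(e); NULL})
      if (!is.null(fit)) {
        re_used <- at$re
        msg <- if (length(at$re) < length(pnames)) {
          paste("random effects reduced to", paste(at$re, collapse = ", "))
        } else NA_character_
        break
      }
    }
  } else {
    fit <- tryCatch(
      stats::nls(rhs, data = d, start = start,
                 control = stats::nls.control(maxiter = 200,
                                              scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) {msg <<- conditionMessage(e); NULL})
  }
  if (is.null(fit)) {
    return(structure(list(model = model, form = form,
                          random_effects = random_effects, converged = FALSE,
                          message = msg, estimates = NULL, re_sd = NULL,
                          loglik = NA_real_, aic = NA_real_, k = NA_integer_),
                     class = "sigma_mu_fit"))
  }
  cf <- if (random_effects) nlme::fixef(fit) else stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  nat <- sub("^l", "", pnames)
  nat <- sub("^m", "mu50_", nat)
  nat <- sub("^a", "alpha", nat)
  est <- tibble::tibble(parameter = nat, value = exp(unname(cf[pnames])),
                        rse_pct = 100 * unname(se[seq_along(pnames)]))
  re_sd <- NULL
  if (random_effects) {
    vc <- nlme::VarCorr(fit)
    sds <- stats::setNames(rep(0, length(pnames)), pnames)
    sds[re_used] <- as.numeric(vc[re_used, "StdDev"])
    re_sd <- tibble::tibble(parameter = nat, sd = unname(sds))
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(model = model, form = form, random_effects = random_effects,
                 converged = TRUE, message = msg, estimates = est,
                 re_sd = re_sd, resid_sd = stats::sigma(fit), loglik = ll,
                 aic = 2 * k - 2 * ll, k = k, fit = fit),
            class = "sigma_mu_fit")
}

#' @export
print.sigma_mu_fit <- function(x, ...) {
  cat(sprintf("<sigma_mu_fit> %s-exponential (%s kernel), %s\n", x$model,
              x$form,
              if (x$random_effects) "mixed effects" else "fixed effects only"))
  if (!x$converged) {
    cat("  DID NOT CONVERGE:", x$message, "\n")
    return(invisible(x))
  }
  e <- x$estimates
  if (!is.null(x$re_sd)) e <- dplyr::left_join(e, x$re_sd, by = "parameter")
  print(as.data.frame(e), digits = 4)
  cat(sprintf("  logLik %.2f, AIC %.2f (k = %d)\n", x$loglik, x$aic, x$k))
  invisible(x)
}

#' T1/Tc threshold for a target coefficient of variation
#'
#' Composes the two inversions of the analysis: the amplitude at which the
#' CV model reaches `cv_target` ([solve_mu_for_cv()]), then the T1/Tc at
#' which the typical muscle amplitude reaches that value
#' ([critical_t1tc_for_amplitude()]). When the required amplitude exceeds
#' the muscle's typical baseline the target is unattainable at any blockade
#' depth and the flag is propagated.
#'
#' @param p_cv [cv_params] of the muscle.
#' @param pd_mu,pd_t Muscle and T1/Tc [pd_params].
#' @param cv_target Target CV (e.g. 0.25).
#' @param form Decay kernel, see [cv_of_mu()].
#' @return A list: `cv_target`, `mu_star`, `boundary` (target above the
#'   maximum CV, threshold pinned at complete block), `t1tc`, `attainable`.
#' @export
threshold_pipeline <- function(p_cv, pd_mu, pd_t, cv_target,
                               form = c("efold", "half")) {
  form <- match.arg(form)
  sol <- solve_mu_for_cv(cv_target, p_cv, form)
  if (sol$boundary) {
    return(list(cv_target = cv_target, mu_star = 0, boundary = TRUE,
                t1tc = 0, attainable = TRUE))
  }
  crit <- critical_t1tc_for_amplitude(sol$mu, pd_mu, pd_t)
  list(cv_target = cv_target, mu_star = sol$mu, boundary = FALSE,
       t1tc = crit$t1tc, attainable = crit$attainable)
}
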