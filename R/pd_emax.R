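#' Inhibitory sigmoid Emax response
#'
#' Evaluates `baseline * ec50^hill / (ec50^hill + ce^hill)`: the drug-free
#' response at `ce = 0`, half the baseline at `ce = ec50`, and full
#' suppression in the limit of infinite concentration (Imax = 1).
#'
#' @param ce Effect-site concentration(s), uM, non-negative.
#' @param p A [pd_params] object (or any list with `baseline`, `ec50`,
#'   `hill`), typically a population set or one subject's realisation.
#' @return Response in the unit of `baseline`, same length as `ce`.
#' @export
emax_response <- function(ce, p) {
  if (any(ce < 0)) stop("`ce` must be non-negative", call. = FALSE)
  # log1p formulation is stable for extreme hill or ce >> ec50
  out <- numeric(length(ce))
  pos <- ce > 0
  out[!pos] <- p$baseline
  if (any(pos)) {
    out[pos] <- p$baseline *
      exp(-log1p(exp(p$hill * (log(ce[pos]) - log(p$ec50)))))
  }
  out
}

#' Sample individual pharmacodynamic parameters
#'
#' Draws `n` subjects' realised parameters from the log-normal
#' between-subject distribution of a population [pd_params] set:
#' `theta_i = theta_pop * exp(eta)`, `eta ~ N(0, bsv_sd^2)` independently
#' per parameter. The population value is the median of each marginal, so
#' with all SDs zero every subject equals the population set. Per-occasion
#' baseline multipliers `exp(kappa)`, `kappa ~ N(0, wsv_sd^2)` are drawn at
#' observation time by the cohort generator (see [generate_cohort()]),
#' because the number of occasions is a property of the sampling schedule.
#'
#' @param pop Population [pd_params].
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `subject_id`, `endpoint`, `baseline_i`,
#'   `ec50_i`, `hill_i`.
#' @export
sample_individual <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pd_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  tibble::tibble(
    subject_id = seq_len(n),
    endpoint = pop$endpoint,
    baseline_i = pop$baseline * exp(eta(pop$bsv_sd[["baseline"]])),
    ec50_i = pop$ec50 * exp(eta(pop$bsv_sd[["ec50"]])),
    hill_i = pop$hill * exp(eta(pop$bsv_sd[["hill"]]))
  )
}

as_pd_realization <- function(row) {
  list(endpoint = row$endpoint[1], baseline = row$baseline_i[1],
       ec50 = row$ec50_i[1], hill = row$hill_i[1])
}

#' Predict endpoint trajectories from an effect-site profile
#'
#' Applies [emax_response()] for each endpoint parameter set along an
#' effect-site concentration series, yielding the noise-free model
#' trajectories (T1/Tc and/or mean MEP amplitude over time).
#'
#' @param profile A tibble with `time_s` and `ce_um` (e.g. from
#'   [simulate_pkpd_profile()]).
#' @param params A single [pd_params]/realisation or a (named) list of them.
#' @return A long tibble with `time_s`, `endpoint`, `value`.
#' @export
predict_endpoints <- function(profile, params) {
  stopifnot(all(c("time_s", "ce_um") %in% names(profile)))
  if (inherits(params, "pd_params") || !is.null(params$baseline)) {
    params <- list(params)
  }
  purrr::map_dfr(params, function(p) {
    tibble::tibble(time_s = profile$time_s,
                   endpoint = if (!is.null(p$endpoint)) p$endpoint else "endpoint",
                   value = emax_response(profile$ce_um, p))
  })
}
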