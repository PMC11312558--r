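#' Effect-site concentration implied by an observed T1/Tc
#'
#' Inverts the T1/Tc Emax model (baseline 1):
#' `ce = ec50 * ((1 - t) / t)^(1/hill)`. Exact inverse of
#' [emax_response()] for the twitch endpoint.
#'
#' @param t T1/Tc value(s) in (0, 1].
#' @param pd_t [pd_params] of the T1/Tc endpoint.
#' @return Effect-site concentration(s), uM.
#' @export
invert_t1tc <- function(t, pd_t) {
  if (any(t <= 0 | t > 1)) stop("`t` must lie in (0, 1]", call. = FALSE)
  pd_t$ec50 * ((1 - t) / t)^(1 / pd_t$hill)
}

#' Mean MEP amplitude as a function of T1/Tc
#'
#' Eliminates the effect-site concentration between the muscle and T1/Tc
#' Emax models, giving the closed form
#' \deqn{\mu(t) = \frac{B_\mu}{1 + (EC_{50,t}/EC_{50,\mu})^{\gamma_\mu}
#'   \left(\frac{1-t}{t}\right)^{\gamma_\mu/\gamma_t}}}{
#'   mu(t) = B / (1 + (ec50_t/ec50_mu)^hill_mu * ((1-t)/t)^(hill_mu/hill_t))}
#' which is strictly increasing in `t` and equals the muscle baseline at
#' `t = 1`. Identical EC50 and Hill in the two models give the identity
#' shape `mu(t) = B * t`.
#'
#' @param t T1/Tc value(s) in (0, 1].
#' @param pd_mu Muscle [pd_params] (or realisation).
#' @param pd_t T1/Tc [pd_params] (or realisation).
#' @return Mean amplitude(s), uV.
#' @export
mu_of_t1tc <- function(t, pd_mu, pd_t) {
  if (any(t <= 0 | t > 1)) stop("`t` must lie in (0, 1]", call. = FALSE)
  k <- pd_mu$hill * (log(pd_t$ec50) - log(pd_mu$ec50))
  m <- pd_mu$hill / pd_t$hill
  out <- numeric(length(t))
  at1 <- t == 1
  out[at1] <- pd_mu$baseline
  if (any(!at1)) {
    lodds <- log(1 - t[!at1]) - log(t[!at1])
    out[!at1] <- pd_mu$baseline * exp(-log1p(exp(k + m * lodds)))
  }
  out
}

#' Tabulate a mu--T1/Tc link curve
#'
#' @param pd_mu,pd_t Muscle and T1/Tc parameter sets.
#' @param t1tc_grid Grid in (0, 1]; default 999 points on (0.001, 0.999)
#'   plus the endpoint 1.
#' @param ... Passed to [classify_shape()].
#' @return A tibble `t1tc`, `mu_uv` with attribute `"shape"` holding the
#'   [classify_shape()] label.
#' @export
link_curve <- function(pd_mu, pd_t,
                       t1tc_grid = c(seq(0.001, 0.999, length.out = 999), 1),
                       ...) {
  out <- tibble::tibble(t1tc = t1tc_grid,
                        mu_uv = mu_of_t1tc(t1tc_grid, pd_mu, pd_t))
  attr(out, "shape") <- classify_shape(pd_mu, pd_t, ...)
  out
}

#' Classify the qualitative shape of a mu--T1/Tc curve
#'
#' Works on the baseline-normalised curve `g(t) = mu(t)/B` over a dense grid
#' spanning the observable blockade window (default T1/Tc 0.1 to 0.9, the
#' resolution at which amplitudes are recorded during recovery; behaviour
#' outside that window is invisible to the monitoring design). If `g`
#' deviates from the identity by less than `linear_tol` in sup-norm the
#' curve is `"linear"` (exactly equal EC50 and Hill give the identity, hence
#' `"linear"` at any tolerance; the default band 0.05 is the typical
#' standard error of a stratum mean amplitude relative to baseline, i.e. the
#' smallest deviation from proportionality the data could resolve).
#' Otherwise the label follows the sign pattern of the second derivative:
#' positive throughout is `"convex_up"` (muscle more resistant than the
#' twitch, EC50 ratio < 1 at equal Hill), negative throughout is
#' `"concave_up"`, a single + to - change is `"sigmoid_max_slope_mid"`
#' (interior slope maximum, at T1/Tc 0.5 when the EC50s are equal and the
#' muscle Hill is the larger), and - to + is `"sigmoid_min_slope_mid"` (the
#' mirror case). The label is invariant to rescaling the muscle baseline.
#'
#' @param pd_mu,pd_t Muscle and T1/Tc parameter sets (realisations allowed).
#' @param grid_n Number of grid points (default 999).
#' @param t_range Classification window on the T1/Tc axis.
#' @param linear_tol Sup-norm band around the identity counted as linear.
#' @return One of `"linear"`, `"convex_up"`, `"concave_up"`,
#'   `"sigmoid_max_slope_mid"`, `"sigmoid_min_slope_mid"`.
#' @export
classify_shape <- function(pd_mu, pd_t, grid_n = 999,
                           t_range = c(0.1, 0.9), linear_tol = 0.05) {
  t <- seq(t_range[1], t_range[2], length.out = grid_n)
  g <- mu_of_t1tc(t, pd_mu, pd_t) / pd_mu$baseline
  if (max(abs(g - t)) < linear_tol) return("linear")
  h <- t[2] - t[1]
  d2 <- diff(g, differences = 2) / h^2
  # ignore numerically flat stretches when reading the sign pattern
  sgn <- sign(d2) * (abs(d2) > 1e-9)
  sgn <- sgn[sgn != 0]
  if (length(sgn) == 0L) return("linear")
  flips <- which(diff(sgn) != 0)
  if (length(flips) == 0L) {
    return(if (sgn[1] > 0) "convex_up" else "concave_up")
  }
  # monotone-in-odds composition admits at most one genuine inflection;
  # classify by the dominant first-to-last transition
  if (sgn[1] > 0 && sgn[length(sgn)] < 0) return("sigmoid_max_slope_mid")
  if (sgn[1] < 0 && sgn[length(sgn)] > 0) return("sigmoid_min_slope_mid")
  if (sgn[1] > 0) "convex_up" else "concave_up"
}

#' Critical T1/Tc at which the mean amplitude reaches a target
#'
#' Solves `mu(t) = mu_star` for `t` by inverting the closed form of
#' [mu_of_t1tc()] (the curve is strictly increasing, so the solution is
#' unique): the muscle model is inverted at `mu_star` to the implied
#' effect-site concentration, which is then mapped through the T1/Tc model.
#' This is the typical-value computation (population means in, one threshold
#' out). Targets at or above the muscle baseline are unattainable at any
#' blockade depth and are flagged rather than raised.
#'
#' @param mu_star Target mean amplitude, uV (> 0).
#' @param pd_mu,pd_t Muscle and T1/Tc parameter sets.
#' @param method `"closed_form"` (default) or `"bisection"` (generic
#'   monotone fallback, used as a cross-check).
#' @return A list with `t1tc` (NA when unattainable), `attainable`,
#'   `ce_um` (concentration at the threshold, NA when unattainable) and
#'   `mu_star`.
#' @export
critical_t1tc_for_amplitude <- function(mu_star, pd_mu, pd_t,
                                        method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  if (!is.numeric(mu_star) || length(mu_star) != 1L || mu_star <= 0) {
    stop("`mu_star` must be a single positive amplitude", call. = FALSE)
  }
  if (mu_star >= pd_mu$baseline) {
    return(list(t1tc = NA_real_, attainable = FALSE, ce_um = NA_real_,
                mu_star = mu_star))
  }
  if (method == "closed_form") {
    ce <- pd_mu$ec50 * (pd_mu$baseline / mu_star - 1)^(1 / pd_mu$hill)
    t <- 1 / (1 + (ce / pd_t$ec50)^pd_t$hill)
  } else {
    f <- function(t) mu_of_t1tc(t, pd_mu, pd_t) - mu_star
    t <- stats::uniroot(f, lower = 1e-12, upper = 1 - 1e-12,
                        tol = 1e-12, maxiter = 200)$root
    ce <- invert_t1tc(t, pd_t)
  }
  list(t1tc = t, attainable = TRUE, ce_um = ce, mu_star = mu_star)
}

#' Census of individual mu--T1/Tc curve shapes in a cohort
#'
#' Classifies every simulated individual's muscle curve (using the
#' individual's realised Emax parameters for both the muscle and the T1/Tc
#' endpoint) and tabulates the labels. Replicates the Monte-Carlo
#' observation that all five qualitative shapes arise from between-subject
#' variability in the EC50 and Hill parameters alone.
#'
#' @param cohort An `mep_cohort` from [generate_cohort()].
#' @param linear_tol Passed to [classify_shape()].
#' @return A tibble with `muscle`, `shape`, `n`.
#' @export
shape_census <- function(cohort, linear_tol = 0.05) {
  stopifnot(inherits(cohort, "mep_cohort"))
  muscles <- setdiff(names(cohort$individual_pd), "t1tc")
  t1 <- cohort$individual_pd$t1tc
  purrr::map_dfr(muscles, function(m) {
    ind <- cohort$individual_pd[[m]]
    lab <- vapply(seq_len(nrow(ind)), function(i) {
      classify_shape(as_pd_realization(ind[i, ]),
                     as_pd_realization(t1[i, ]), linear_tol = linear_tol)
    }, character(1))
    dplyr::count(tibble::tibble(muscle = m, shape = lab), .data$muscle,
                 .data$shape, name = "n")
  })
}
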