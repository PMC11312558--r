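#' Pharmacokinetic parameter set for a mammillary compartment model
#'
#' Constructs and validates the parameter object used by [simulate_plasma()]
#' and [simulate_pkpd_profile()]. The model is a two- or three-compartment
#' linear mammillary system with bolus input into the central compartment and
#' a first-order effect-site compartment. Volumes and clearances are given
#' per kilogram of body weight and scale linearly with weight (no allometry).
#'
#' @param volumes Named numeric, `v1`, `v2` (and `v3` for three
#'   compartments), in L/kg.
#' @param clearances Named numeric, `cl` (elimination), `q2` (and `q3`), in
#'   L/kg/min.
#' @param ke0 Effect-site equilibration rate constant, 1/min.
#' @param molar_mass Molar mass in g/mol used to convert plasma mg/L to
#'   effect-site uM.
#' @param n_compartments 2 or 3.
#' @return An object of class `pk_params`.
#' @seealso [load_pk_params()] for the packaged rocuronium set.
#' @export
pk_params <- function(volumes, clearances, ke0, molar_mass = 609.68,
                      n_compartments = length(volumes)) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(2L, 3L)) {
    stop("`n_compartments` must be 2 or 3", call. = FALSE)
  }
  need_v <- paste0("v", seq_len(n_compartments))
  need_q <- c("cl", paste0("q", seq_len(n_compartments)[-1]))
  volumes <- unlist(volumes)[need_v]
  clearances <- unlist(clearances)[need_q]
  if (anyNA(volumes) || anyNA(clearances)) {
    stop("volumes must name ", paste(need_v, collapse = ", "),
         " and clearances ", paste(need_q, collapse = ", "), call. = FALSE)
  }
  if (any(volumes <= 0)) stop("all volumes must be strictly positive", call. = FALSE)
  if (any(clearances < 0)) stop("clearances must be non-negative", call. = FALSE)
  if (!is.numeric(ke0) || length(ke0) != 1L || ke0 <= 0) {
    stop("`ke0` must be a single positive number (1/min)", call. = FALSE)
  }
  if (!is.numeric(molar_mass) || molar_mass <= 0) {
    stop("`molar_mass` must be positive", call. = FALSE)
  }
  structure(
    list(n_compartments = n_compartments, volumes = volumes,
         clearances = clearances, ke0 = ke0, molar_mass = molar_mass),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> %d-compartment mammillary model\n", x$n_compartments))
  cat("  volumes (L/kg):    ", paste(sprintf("%s=%.4g", names(x$volumes), x$volumes),
                                     collapse = "  "), "\n")
  cat("  clearances (L/kg/min):", paste(sprintf("%s=%.4g", names(x$clearances),
                                                x$clearances), collapse = "  "), "\n")
  cat(sprintf("  ke0 = %.4g /min, molar mass = %.2f g/mol\n", x$ke0, x$molar_mass))
  invisible(x)
}

#' Pharmacodynamic parameter set for an inhibitory sigmoid Emax endpoint
#'
#' One endpoint is either the T1/Tc twitch ratio (dimensionless baseline 1)
#' or the mean MEP amplitude of a muscle (baseline in uV). The response to an
#' effect-site concentration `ce` is
#' `baseline * ec50^hill / (ec50^hill + ce^hill)` (full inhibition).
#' Between-subject variability is log-normal on each parameter;
#' within-subject (occasion) variability is log-normal on the baseline only.
#'
#' @param endpoint Endpoint code, e.g. `"t1tc"`, `"Del"`, `"APB"`, `"TA"`,
#'   `"AH"`.
#' @param baseline Drug-free response (1 for T1/Tc, uV for muscles).
#' @param ec50 Effect-site concentration of half-maximal suppression, uM.
#' @param hill Hill coefficient (steepness), dimensionless.
#' @param bsv_sd Named log-scale SDs of between-subject variability for
#'   `baseline`, `ec50`, `hill` (missing names default to 0).
#' @param wsv_sd Log-scale SD of the per-occasion baseline multiplier.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(endpoint, baseline, ec50, hill,
                      bsv_sd = c(baseline = 0, ec50 = 0, hill = 0),
                      wsv_sd = 0) {
  stopifnot(is.character(endpoint), length(endpoint) == 1L)
  if (!is.numeric(baseline) || baseline <= 0) stop("`baseline` must be > 0", call. = FALSE)
  if (!is.numeric(ec50) || ec50 <= 0) stop("`ec50` must be > 0", call. = FALSE)
  if (!is.numeric(hill) || hill <= 0) stop("`hill` must be > 0", call. = FALSE)
  full <- c(baseline = 0, ec50 = 0, hill = 0)
  bsv_sd <- unlist(bsv_sd)
  full[names(bsv_sd)] <- bsv_sd
  if (any(full < 0) || wsv_sd < 0) stop("variability SDs must be >= 0", call. = FALSE)
  if (identical(endpoint, "t1tc") && (baseline != 1 || wsv_sd != 0)) {
    stop("the T1/Tc endpoint has baseline 1 and no occasion variability", call. = FALSE)
  }
  structure(
    list(endpoint = endpoint, baseline = baseline, ec50 = ec50, hill = hill,
         bsv_sd = full, wsv_sd = wsv_sd),
    class = "pd_params"
  )
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("<pd_params> %s: baseline %.4g, EC50 %.4g uM, Hill %.4g\n",
              x$endpoint, x$baseline, x$ec50, x$hill))
  cat("  BSV log-SD:", paste(sprintf("%s=%.3g", names(x$bsv_sd), x$bsv_sd),
                             collapse = "  "),
      sprintf(" WSV log-SD: %.3g\n", x$wsv_sd))
  invisible(x)
}

#' Bi-exponential coefficient-of-variation parameter set for one muscle
#'
#' Parameters of the variance-function model
#' `CV(mu) = alpha1 * g(mu/mu50_1) + alpha2 * g(mu/mu50_2)` relating the
#' within-subject coefficient of variation of repeated MEP amplitude
#' measurements to the mean amplitude `mu`. See [cv_of_mu()] for the decay
#' kernel `g`. `mu50_1 <= mu50_2` is enforced by reordering (identifiability
#' convention: the first exponential is the fast, low-amplitude one).
#'
#' @param muscle Muscle code.
#' @param alpha1,alpha2 Dimensionless CV contributions of the two
#'   exponentials; `CV(0) = alpha1 + alpha2`.
#' @param mu50_1,mu50_2 Amplitude scales (uV) of the two exponentials.
#' @param random_effect_sd Named log-scale SDs of between-subject random
#'   effects on the four parameters (missing names default to 0).
#' @return An object of class `cv_params`.
#' @export
cv_params <- function(muscle, alpha1, alpha2, mu50_1, mu50_2,
                      random_effect_sd = c(alpha1 = 0, alpha2 = 0,
                                           mu50_1 = 0, mu50_2 = 0)) {
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, mu50_1 = mu50_1, mu50_2 = mu50_2)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all four fixed effects must be positive and finite", call. = FALSE)
  }
  full <- c(alpha1 = 0, alpha2 = 0, mu50_1 = 0, mu50_2 = 0)
  random_effect_sd <- unlist(random_effect_sd)
  full[names(random_effect_sd)] <- random_effect_sd
  if (any(full < 0)) stop("random-effect SDs must be >= 0", call. = FALSE)
  if (mu50_1 > mu50_2) {  # reorder terms so the fast scale comes first
    tmp <- c(alpha1, mu50_1); alpha1 <- alpha2; mu50_1 <- mu50_2
    alpha2 <- tmp[1]; mu50_2 <- tmp[2]
    full <- full[c("alpha2", "alpha1", "mu50_2", "mu50_1")]
    names(full) <- c("alpha1", "alpha2", "mu50_1", "mu50_2")
  }
  structure(
    list(muscle = muscle, alpha1 = alpha1, alpha2 = alpha2,
         mu50_1 = mu50_1, mu50_2 = mu50_2, random_effect_sd = full),
    class = "cv_params"
  )
}

#' @export
print.cv_params <- function(x, ...) {
  cat(sprintf("<cv_params> %s: alpha1 %.3g, alpha2 %.3g, mu50_1 %.4g uV, mu50_2 %.4g uV\n",
              x$muscle, x$alpha1, x$alpha2, x$mu50_1, x$mu50_2))
  cat(sprintf("  CV(0) = %.1f%%\n", 100 * (x$alpha1 + x$alpha2)))
  invisible(x)
}

rocumep_file <- function(name) {
  path <- system.file("extdata", name, package = "rocumep")
  if (!nzchar(path)) stop("packaged file not found: ", name, call. = FALSE)
  path
}

#' Load the packaged rocuronium pharmacokinetic parameter set
#'
#' Reads a YAML pharmacokinetic configuration (by default the packaged
#' synthetic rocuronium set, see
#' `inst/extdata/pk_rocuronium_synthetic.yaml`) into a [pk_params] object.
#' Individual fields, most usefully `ke0`, can be overridden.
#'
#' @param path YAML file path; `NULL` for the packaged default.
#' @param ... Named overrides passed to [pk_params()] (e.g. `ke0 = 0.3`).
#' @return A [pk_params] object.
#' @export
load_pk_params <- function(path = NULL, ...) {
  if (is.null(path)) path <- rocumep_file("pk_rocuronium_synthetic.yaml")
  y <- yaml::read_yaml(path)
  args <- list(volumes = unlist(y$volumes), clearances = unlist(y$clearances),
               ke0 = y$ke0, molar_mass = y$molar_mass,
               n_compartments = y$n_compartments)
  over <- list(...)
  args[names(over)] <- over
  do.call(pk_params, args)
}

#' Load the packaged population pharmacodynamic estimates
#'
#' Reads the packaged transcription of the published population Emax
#' estimates (T1/Tc plus four muscles) into a named list of [pd_params]
#' objects. Reported relative standard errors are attached as the
#' `"rse_pct"` attribute of each element.
#'
#' @param path YAML file path; `NULL` for the packaged default.
#' @return Named list of [pd_params] with elements `t1tc`, `Del`, `APB`,
#'   `TA`, `AH`.
#' @export
load_pd_params <- function(path = NULL) {
  if (is.null(path)) path <- rocumep_file("pd_population.yaml")
  y <- yaml::read_yaml(path)$endpoints
  out <- lapply(names(y), function(nm) {
    e <- y[[nm]]
    p <- pd_params(nm, e$baseline, e$ec50, e$hill,
                   bsv_sd = unlist(e$bsv_sd), wsv_sd = e$wsv_sd)
    attr(p, "rse_pct") <- unlist(e$rse_pct)
    attr(p, "label") <- e$label
    p
  })
  names(out) <- names(y)
  out
}

#' Load the packaged bi-exponential CV estimates
#'
#' Reads the packaged transcription of the published bi-exponential
#' variance-function estimates into a named list of [cv_params] objects.
#' The published per-muscle critical amplitudes (uV) are attached as the
#' `"critical_amplitude_uv"` attribute of the list.
#'
#' @param path YAML file path; `NULL` for the packaged default.
#' @return Named list of [cv_params] with elements `Del`, `APB`, `TA`, `AH`.
#' @export
load_cv_params <- function(path = NULL) {
  if (is.null(path)) path <- rocumep_file("cv_biexponential.yaml")
  y <- yaml::read_yaml(path)
  out <- lapply(names(y$muscles), function(nm) {
    m <- y$muscles[[nm]]
    p <- cv_params(nm, m$alpha1, m$alpha2, m$mu50_1, m$mu50_2,
                   random_effect_sd = unlist(m$random_effect_sd))
    attr(p, "rse_pct") <- unlist(m$rse_pct)
    p
  })
  names(out) <- names(y$muscles)
  attr(out, "critical_amplitude_uv") <- unlist(y$critical_amplitude_uv)
  out
}
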