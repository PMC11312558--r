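---
title: "Modelling MEP amplitude and its reliability under partial neuromuscular blockade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MEP amplitude and its reliability under partial neuromuscular blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocumep)
```

## The problem

Intraoperative motor-evoked potentials (MEPs) are the standard guard
against motor-pathway injury during brain and spine surgery: transcranial
electrical stimulation elicits a compound muscle response whose
peak-to-peak amplitude is tracked against a baseline, with a drop of more
than ~50% treated as a warning. Neuromuscular blockade (NMB) — here
rocuronium, given as a 0.6 mg/kg intubating bolus — attenuates these
amplitudes and inflates their trial-to-trial variability, so
anesthesiologists who maintain partial blockade need to know *how deep* a
block still permits reliable MEP interpretation. Blockade depth is
monitored as T1/Tc: the first twitch of a train-of-four stimulation
relative to the pre-drug control twitch (1 = no block, 0 = complete
block).

`rocumep` implements the full quantitative chain linking the three layers:

1. **Exposure**: rocuronium plasma and effect-site concentration after
   weight-based bolus dosing (linear mammillary PK plus a first-order
   effect compartment);
2. **Response**: inhibitory sigmoid Emax models mapping the effect-site
   concentration Ce to T1/Tc and to the mean MEP amplitude $\mu$ of four
   muscles (deltoid, abductor pollicis brevis, tibialis anterior, abductor
   hallucis);
3. **Reliability**: a bi-exponential model of the coefficient of variation
   (CV) of repeated amplitudes as a function of $\mu$, inverted to find the
   T1/Tc above which monitoring remains trustworthy.

## Models

### Effect-site kinetics

Plasma kinetics are a two- or three-compartment linear mammillary system
with bolus input to the central compartment; the effect site follows
$\mathrm{d}C_e/\mathrm{d}t = k_{e0}(C_p - C_e)$. Because the system is
linear, `simulate_plasma()` propagates the exact matrix-exponential
transition over each grid step (default 1 s); an independent adaptive ODE
route (`method = "ode"`) exists purely as a numerical cross-check and the
two agree to better than $10^{-8}$ relative. Plasma is carried in mg/L and
the effect site is reported in µM (EC50s are in µM); the conversion uses
the molar mass of rocuronium bromide (609.68 g/mol), a config value.

The packaged PK parameter set
(`inst/extdata/pk_rocuronium_synthetic.yaml`) is **synthetic**: a
literature-informed three-compartment adult rocuronium parameterisation
(clearance ≈ 0.36 L/min per 70 kg, V1 ≈ 45 mL/kg, $k_{e0}$ = 0.2/min),
fixed once so that a 0.6 mg/kg bolus reproduces the clinical time course —
50% twitch recovery near 25 min, ~95% near 60–70 min, complete recovery
within two hours. No headline threshold depends on the PK values: they
enter only the virtual-cohort simulation, where the identical anchors were
required. Dosing is weight-proportional with per-kg parameters and no
allometry, so all virtual subjects share one concentration profile; this
mirrors the finding that no covariates explained the response variability.

### Exposure–response

Each endpoint follows a full-inhibition sigmoid Emax model
$$E(C_e) = \mathrm{baseline}\cdot
  \frac{EC_{50}^{\gamma}}{EC_{50}^{\gamma} + C_e^{\gamma}},$$
with baseline ≡ 1 for T1/Tc. Imax is fixed at 1: deep block abolishes both
the twitch and the MEP. Between-subject variability (BSV) is log-normal on
baseline, $EC_{50}$ and $\gamma$; within-subject variability (WSV) is a
log-normal per-measurement baseline multiplier for the muscles. The
packaged population values (`load_pd_params()`) are the published
estimates from a prospective cohort of 100 adults monitored through
recovery from a single intubating bolus.

### The µ–T1/Tc link curve

Eliminating $C_e$ between two Emax models gives the closed form
$$\mu(t) = \frac{B_\mu}{1 + \left(\frac{EC_{50,t}}{EC_{50,\mu}}\right)^{\gamma_\mu}
  \left(\frac{1-t}{t}\right)^{\gamma_\mu/\gamma_t}},$$
strictly increasing on $(0, 1]$ with $\mu(1) = B_\mu$
(`mu_of_t1tc()`; verified against the explicit composition
`emax_response(invert_t1tc(t))` to $10^{-10}$). Its qualitative shape is
governed by the two parameter ratios: at equal Hill coefficients, a lower
(higher) muscle $EC_{50}$ gives a convex (concave) curve; at equal
$EC_{50}$s, a higher (lower) muscle Hill gives a sigmoid with its maximum
(minimum) slope at T1/Tc = 0.5.

`classify_shape()` labels a curve by the sign pattern of the second
derivative of the baseline-normalised curve on a 999-point grid over
T1/Tc ∈ [0.1, 0.9]. Two design choices matter here and were genuinely
open:

* **Window.** Amplitudes are recorded at each 10% T1/Tc increment, so
  curvature confined to T1/Tc < 0.1 or > 0.9 is invisible to the design;
  classifying on the full open interval would label nearly every
  BSV realisation "sigmoid" because of inflections adjacent to the
  endpoints that no observer could see.
* **Linear band.** A curve is called linear when it deviates from the
  identity by less than 5% of baseline in sup-norm. The 5% figure is the
  resolvability limit of the data: with a within-subject CV of ≥ ~20% and
  typically 10–20 repeats per stratum, the standard error of a stratum
  mean is ~5% of baseline, so smaller deviations from proportionality
  cannot be distinguished from it. Exact parameter equality yields the
  identity and is labelled linear at any tolerance.

With these choices a 100-subject Monte Carlo at the published parameters
produces all five shape labels, as the clinical data did.

### Within-subject variability

For repeated amplitudes at comparable blockade depth, the CV declines
bi-exponentially with the mean:
$$CV(\mu) = \alpha_1 e^{-\mu/\mu_{50,1}} + \alpha_2 e^{-\mu/\mu_{50,2}},
  \qquad CV(0) = \alpha_1 + \alpha_2 .$$
Two decay conventions are implemented (`cv_of_mu(form=)`): the e-fold
kernel above (default) and a half-decay kernel $2^{-\mu/\mu_{50}}$. The
e-fold form is the default because, with the packaged fixed effects, it
reproduces the published table of amplitudes attaining 25/30/35% target
CVs to four significant figures for three of the four muscles (the
deltoid row of that source table is internally inconsistent under *any*
exponential convention and is reproduced by neither; the package computes
honestly from the printed fixed effects rather than back-fitting the
printed amplitudes). This convention check is asserted in the test suite.

`fit_sigma_mu()` estimates the model by nonlinear mixed-effects
regression of $\log\sigma$ on $\mu$ (log-normal random effects on all
four parameters, diagonal covariance), exactly nesting the
mono-exponential alternative ($\alpha_2 \to 0$) so the AIC comparison
between the two is meaningful; $k$ counts fixed effects, random-effect
SDs and the residual SD. $\mu_{50,2}$ sits near its identifiability
boundary on realistic data (its reported relative standard error is
>100%), so the fitter uses a convergence ladder — progressively relaxed
PNLS tolerances, an nls-refined start with clamped scales, then dropping
the $\mu_{50,2}$ (and if needed further) random effects — and records
which rung succeeded; failures are flagged, never silent. Because many
subject × stratum groups contain only 2–4 repeats, `summarize_amplitudes()`
offers a `bias_correct` switch dividing each SD by the Gaussian
small-sample factor $c_4(n)$ ($E[s] = c_4\sigma$, $c_4(2)=0.80$); the
plain $\sigma/\mu$ definition remains the default.

### Thresholds

Two inversions close the analysis:

* `critical_t1tc_for_amplitude()` solves $\mu(t) = \mu^*$ in closed form
  (with a bisection fallback for arbitrary monotone models). This is the
  **typical-value** computation: population means in, one threshold out.
  Targets at or above the typical baseline are returned with an
  `attainable = FALSE` flag, not an error.
* `solve_mu_for_cv()` inverts the strictly decreasing CV model by
  bisection ($10^{-10}$ relative in ≤ 200 iterations); targets at or
  above $\alpha_1+\alpha_2$ pin $\mu = 0$ with a boundary flag.

`threshold_pipeline()` composes them: target CV → required amplitude →
T1/Tc threshold. At a 25% target (chosen so ±2 SD stays inside the usual
50% warning criterion) the upper-limb muscles yield thresholds near
0.6–0.8 while tibialis anterior and abductor hallucis are flagged
unattainable — their required amplitudes exceed their typical baselines —
supporting the overall recommendation to keep T1/Tc above ~0.6 under
partial blockade.

### Population estimation

`fit_population()` re-estimates baseline, $EC_{50}$, $\gamma$ and their
BSV SDs per endpoint from longitudinal data with the PK fixed, using
`nlme::nlme` (Lindstrom–Bates approximate marginal ML) on the
log-parameter scale: amplitudes on the log scale (proportional residual),
T1/Tc on the logit scale (additive residual), endpoints fitted
sequentially (T1/Tc first), rows canonicalised by subject and time so
estimates are invariant to input ordering. Starting values are
data-driven: for T1/Tc, a pooled regression of the logit on
$\log C_e$ (whose slope and intercept are −Hill and Hill·log EC50); for
muscles, a robust per-subject baseline proxy (90th percentile) and the
median concentration among mid-range responses. Observations below the
1 µV recording floor are flagged and excluded — a truncation, not the
censored-likelihood treatment one would use in a tool with a richer
likelihood; with this design most observations sit well above the floor
and parameter recovery stays within the tolerances demonstrated in the
test suite. `individual_ebe()` computes per-subject posterior-mode random
effects by penalised least squares given any population fit; it is
written in-package and cross-checked against the mixed-model posterior
modes in the tests.

## The virtual cohort

`generate_cohort()` emulates the monitoring design: demographics from the
reported cohort moments (weight 64 ± 12 kg, height 163 ± 8 cm, 59%
female, truncated at ±3 SD), one 0.6 mg/kg bolus at time zero, T1/Tc
observed every 30 s with additive logit-scale noise (SD 0.05 — not part
of the published model, pure simulation plumbing), and MEPs at the first
crossing of each 10% T1/Tc recovery increment plus a periodic schedule.
The periodic cadence is 2 min by default: the protocol only states that
MEPs were evoked "periodically", and a few minutes between trains is
routine practice; the cadence is configurable. Amplitude noise is
proportional log-normal with SD chosen so the observation CV equals the
subject's bi-exponential CV at the predicted mean — coupling the
simulation noise to the variability model so that summaries of simulated
data reproduce the CV–µ structure by construction. Amplitudes below 1 µV
are recorded at the floor and flagged. `impose_missingness()` (MCAR; the
protocol states no mechanism) and `regression_impute()` (per-subject,
per-muscle regression of log(amplitude+1) on T1/Tc) complete the
missing-data path.

What the generator does **not** emulate: anesthetic covariate effects
(propofol/remifentanil depth, temperature, hemodynamics), stimulation
artefacts, electrode drift, within-train facilitation, or any
non-log-normal tail behaviour. Passing tests on simulated cohorts
therefore demonstrate internal consistency of the pipeline — the
estimators recover the parameters that generated the data under the
study's sampling design — not external validity on real recordings.

## Problem sizes and numerical choices

The simulation experiments in the tests use 100 virtual subjects (the
cohort size of the study design) and three fixed seeds for each
stochastic claim; the PK grid is 1 s over 150 min. With baseline BSV SDs
near 1.0, the realised median of a 100-subject cohort itself has a ~10%
standard error, so parameter-recovery experiments at this size are
dominated by cohort sampling noise rather than estimator error — the
estimates track the realised cohort medians to within a few percent, with
a ~5% upward Hill bias typical of linearised marginal likelihood at large
random-effect variances. Degenerate inputs are handled explicitly: zero
dose gives zero concentration; zero variability collapses individuals to
the population values; solver boundary cases (targets at the CV maximum,
amplitudes above baseline) return flags rather than errors; ties in the
classifier default to the conservative non-linear labels only outside the
resolvability band.

## Known limitations

* The PK set is a synthetic stand-in, not a transcription of the original
  model's appendix table; absolute concentrations (and anything read off
  them) carry that caveat.
* Estimation is Lindstrom–Bates, not SAEM as in the original analysis;
  agreement is demonstrated by parameter recovery, not by replicating the
  original estimation path.
* The deltoid variance-function row of the source estimates is internally
  inconsistent (see above); deltoid CV-target thresholds computed from
  the printed fixed effects differ accordingly from the printed ones.
* Below-floor amplitudes are truncated rather than treated by a censored
  likelihood; at deeper sustained blocks than this design produces, that
  shortcut would bias $EC_{50}$ and Hill.
* Endpoints are fitted independently; correlations between muscles within
  a subject are not modelled (matching the per-endpoint structure of the
  published estimates).
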