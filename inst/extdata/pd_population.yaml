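# Population pharmacodynamic estimates for the inhibitory sigmoid Emax models
# linking rocuronium effect-site concentration (Ce, uM) to the T1/Tc twitch
# ratio and to the mean MEP amplitude (mu, uV) of four muscles, as estimated
# by nonlinear mixed-effects modelling in a prospective cohort of 100 adults
# undergoing brain tumour removal surgery.
#
# Units: baseline is dimensionless (=1) for T1/Tc and uV for muscles;
# ec50 is uM; hill is dimensionless. Between-subject variability (bsv_sd)
# and within-subject baseline variability (wsv_sd) are log-scale standard
# deviations of log-normal random effects. rse_pct entries are the reported
# relative standard errors (%) of the point estimates, kept as metadata.
endpoints:
  t1tc:
    label: "T1/Tc twitch ratio"
    baseline: 1.0
    ec50: 2.69
    hill: 2.23
    bsv_sd: {baseline: 0.0, ec50: 0.153, hill: 0.39}
    wsv_sd: 0.0
    rse_pct: {ec50: 2.62, hill: 4.98, bsv_ec50: 17.7, bsv_hill: 12.2}
  Del:
    label: "deltoid"
    baseline: 366
    ec50: 3.05
    hill: 2.67
    bsv_sd: {baseline: 0.976, ec50: 0.59, hill: 0.485}
    wsv_sd: 0.0436
    rse_pct: {baseline: 10.5, ec50: 7.06, hill: 6.31,
              bsv_baseline: 7.77, bsv_ec50: 9.36, bsv_hill: 10.5, wsv: 57.0}
  APB:
    label: "abductor pollicis brevis"
    baseline: 1520
    ec50: 2.64
    hill: 2.03
    bsv_sd: {baseline: 0.883, ec50: 0.647, hill: 0.678}
    wsv_sd: 0.0549
    rse_pct: {baseline: 9.62, ec50: 7.92, hill: 8.03,
              bsv_baseline: 7.8, bsv_ec50: 9.86, bsv_hill: 8.95, wsv: 17.1}
  TA:
    label: "tibialis anterior"
    baseline: 738
    ec50: 2.46
    hill: 2.43
    bsv_sd: {baseline: 1.07, ec50: 0.648, hill: 0.808}
    wsv_sd: 0.0915
    rse_pct: {baseline: 11.2, ec50: 7.62, hill: 9.22,
              bsv_baseline: 8.37, bsv_ec50: 9.62, bsv_hill: 8.47, wsv: 13.8}
  AH:
    label: "abductor hallucis"
    baseline: 737
    ec50: 1.83
    hill: 1.59
    bsv_sd: {baseline: 1.09, ec50: 1.03, hill: 0.596}
    wsv_sd: 0.124
    rse_pct: {baseline: 11.7, ec50: 12.6, hill: 7.56,
              bsv_baseline: 8.79, bsv_ec50: 11.7, bsv_hill: 11.2, wsv: 12.4}
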