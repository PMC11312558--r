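# SYNTHETIC rocuronium pharmacokinetic parameter set (three-compartment
# mammillary model with an effect-site compartment).
#
# These values are NOT a transcription of any single published fit: they are
# a literature-informed stand-in assembled from typical adult rocuronium
# pharmacokinetics (clearance ~0.25-0.35 L/min per 70 kg, central volume
# ~40-45 mL/kg, Vss ~0.15-0.2 L/kg, effect-site equilibration ke0
# ~0.15-0.4 /min) and calibrated once against the clinical time course of a
# 0.6 mg/kg intubating bolus: ~50% T1 recovery near 25 min, ~95% recovery
# near 60-70 min, complete twitch recovery within two hours.
#
# Volumes are L/kg, clearances L/kg/min, ke0 1/min (converted to 1/s
# internally; simulation time is in seconds). Weight scaling is linear
# (per-kg); allometric exponents are intentionally absent (off by default).
n_compartments: 3
volumes: {v1: 0.045, v2: 0.040, v3: 0.070}      # L/kg
clearances: {cl: 0.0052, q2: 0.0120, q3: 0.0030} # L/kg/min
ke0: 0.20                                        # 1/min
# Molar mass used to convert plasma mg/L to effect-site uM. Doses are
# labelled as rocuronium bromide, molar mass 609.68 g/mol.
molar_mass: 609.68
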