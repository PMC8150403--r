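# Case-study configuration: guided iCBT programme for major depressive
# disorder vs usual care. All monetary values in EUR.
model:
  start_age: 46
  horizon_age: 100
  female_fraction: 0.681
  discount_cost: 0.03
  discount_effect: 0.03
  wtp: 30000
  rr_mortality:
    remission: 1.0
    depression: 1.68

arms:
  control:
    p_recover: 0.29
    p_relapse: 0.14
    u_remission: 0.62
    u_depression: 0.532
    cost_oneoff: 0.0
    cost_recurring: 0.0
  intervention:
    p_recover: 0.4853
    p_relapse: 0.0
    u_remission: 0.665
    u_depression: 0.529
    cost_oneoff: 395.26
    cost_recurring: 2439.0

# Annual per-state costs shared by both arms: healthcare resource use, and
# productivity losses (the societal add-on).
state_costs:
  healthcare:
    remission: 451.0
    depression: 826.0
  societal:
    remission: 991.0
    depression: 1842.0

# Synthetic Gompertz-Makeham life table: remaining life expectancy at 46 of
# 37 y (women) and 33 y (men).
life_table:
  synthetic:
    max_age: 110
    female: {a: 9.5544850781e-06, b: 0.105, c: 2.0e-4}
    male: {a: 2.1008698807e-05, b: 0.100, c: 5.0e-4}

sweeps:
  session_cost:
    max_reduction: 0.25
    steps: 26
  effect_discount:
    max_rate: 0.05
    steps: 51

generator:
  n: 229
  female_fraction: 0.681
  severity_dist: {mild: 0.50, moderate: 0.35, severe: 0.15}
  theta: 0.4853
  p_missing_post: 0.00437
  p_completer: 0.642
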