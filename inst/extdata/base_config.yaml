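# Base-case run configuration: published cohort summary statistics,
# 52-week treatment-effect profiles, complication cost/utility tables,
# thresholds, and the synthetic stand-in risk equations.

seed: 1.0
cohort:
  n_patients: 1000.0
  age:
  - 56.0
  - 10.3
  duration:
  - 7.0
  - 5.9
  hba1c:
  - 8.2
  - 1.0
  bmi:
  - 32.8
  - 6.7
  sbp:
  - 131.41
  - 14.6
  dbp:
  - 80.01
  - 9.5
  tc:
  - 4.75
  - 1.09
  hdl:
  - 1.2
  - 0.3
  ldl:
  - 2.64
  - 0.88
  tg:
  - 2.12
  - 1.55
  egfr:
  - 97.35
  - 15.34
  female: 0.48
  race:
    white: 0.77
    black: 0.0684
    asian: 0.14
    amerindian: 0.0025
    other: 0.0191
  smoking_current: 0.1422
  history:
    mi: 0.04
    angina: 0.02
    pvd: 0.01
    renal: 0.005
    microalbuminuria: 0.005
    retinopathy: 0.08
profiles:
  intervention:
    label: semaglutide
    annual_drug_cost: 558.2
    treatment_time: 5.0
    post_treatment_annual_cost: 558.2
    lipid_delta_unit: percent
    post_treatment_effect: hold
    deltas:
      hba1c:
      - -1.44
      - 0.03
      sbp:
      - -4.11
      - 0.36
      dbp:
      - -1.27
      - 0.23
      tc:
      - -6.15
      - 0.9
      hdl:
      - 1.53
      - 0.22
      ldl:
      - -2.48
      - 0.77
      tg:
      - -31.16
      - 3.36
      bmi:
      - -1.92
      - 0.06
      egfr:
      - 0.15
      - 0.23
  comparator:
    label: empagliflozin
    annual_drug_cost: 558.2
    treatment_time: 5.0
    post_treatment_annual_cost: 558.2
    lipid_delta_unit: percent
    post_treatment_effect: hold
    deltas:
      hba1c:
      - -0.83
      - 0.05
      sbp:
      - -4.48
      - 0.56
      dbp:
      - -2.39
      - 0.37
      tc:
      - 4.14
      - 1.39
      hdl:
      - 2.63
      - 0.34
      ldl:
      - 4.18
      - 1.19
      tg:
      - -15.13
      - 5.17
      bmi:
      - -1.32
      - 0.09
      egfr:
      - -0.06
      - 0.37
equations:
  file: risk_equations_synthetic.txt
costs:
  management: 1427.1
  events:
    ihd:
      fatal: 0.0
      nonfatal: 6293.3
      subsequent: 1123.51
    mi:
      fatal: 7855.14
      nonfatal: 7855.14
      subsequent: 484.52
    chf:
      fatal: 3033.73
      nonfatal: 3033.73
      subsequent: 1604.12
    stroke:
      fatal: 2266.31
      nonfatal: 3059.07
      subsequent: 539.32
    amputation:
      fatal: 4434.6
      nonfatal: 4434.6
      subsequent: 4316.66
    blindness:
      fatal: .na
      nonfatal: 2361.49
      subsequent: 1747.01
    renal:
      fatal: 0.0
      nonfatal: 14685.91
      subsequent: 14685.91
    ulcer:
      fatal: .na
      nonfatal: 2310.0
      subsequent: 813.01
utilities:
  initial: 0.876
  events:
    ihd:
      event: 0.09
      subsequent: 0.09
    mi:
      event: 0.055
      subsequent: 0.236
    chf:
      event: 0.236
      subsequent: 0.236
    stroke:
      event: 0.164
      subsequent: 0.326
    amputation:
      event: 0.38
      subsequent: 0.38
    blindness:
      event: 0.157
      subsequent: 0.157
    renal:
      event: 0.4
      subsequent: 0.4
    ulcer:
      event: 0.059
      subsequent: 0.059
econ:
  discount_rate: 0.05
  wtp: 10425.29
  wtp_3x: 31275.88
  currency: USD
  cny_per_usd: 6.8
sim:
  horizon: 40.0
  event_order:
  - ihd
  - mi
  - chf
  - stroke
  - amputation
  - blindness
  - renal
  - ulcer
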