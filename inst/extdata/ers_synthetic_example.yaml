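score_name: synthetic_true_effects
variables:
- name: age
  type: continuous
  beta: 0.01
- name: age_at_menarche
  type: continuous
  beta: -0.05
- name: parity
  type: categorical
  breaks:
  - -0.5
  - 0.5
  - 1.5
  - 2.5
  - 3.5
  - .inf
  betas:
  - 0.0
  - -0.1
  - -0.2
  - -0.3
  - -0.4
- name: bmi
  type: continuous
  beta: 0.02
- name: height_m
  type: continuous
  beta: 0.0
- name: alcohol_g_day
  type: continuous
  beta: 0.005
- name: menopausal_status
  type: continuous
  beta: 0.1
- name: age_at_menopause
  type: continuous
  beta: 0.02
- name: mht_current
  type: continuous
  beta: 0.25
- name: oc_ever
  type: continuous
  beta: 0.0
- name: smoking_status
  type: categorical
  levels:
    never: 0.0
    former: 0.05
    current: 0.1
- name: fdr_bc
  type: continuous
  beta: 0.35
unavailable: []
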