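# Template for a Dierssen-Sotos-style environmental risk score.
#
# This file encodes the VARIABLE STRUCTURE of that published score (the
# risk-factor set and its categorization) but deliberately ships all betas
# as 0.0: the published coefficients live in the original publication's
# supplementary material and must be filled in by the user before the score
# is meaningful. A worked example with non-zero coefficients is
# ers_synthetic_example.yaml.
score_name: dierssen_sotos_template
variables:
- name: age
  type: continuous
  beta: 0.0
  center: 60
- name: age_at_menarche
  type: categorical
  breaks: [0.0, 12.0, 15.0, .inf]   # <=12 / 12-14 / >=15
  betas: [0.0, 0.0, 0.0]
- name: age_at_first_birth
  type: categorical
  breaks: [0.0, 21.0, 30.0, .inf]
  betas: [0.0, 0.0, 0.0]
- name: parity
  type: categorical
  breaks: [-0.5, 0.5, 2.5, .inf]    # nulliparous / 1-2 / >=3
  betas: [0.0, 0.0, 0.0]
- name: menopausal_status
  type: categorical
  levels:
    premenopausal: 0.0
    postmenopausal: 0.0
- name: age_at_menopause
  type: categorical
  breaks: [0.0, 50.0, .inf]         # <50 / >=50
  betas: [0.0, 0.0]
- name: mht_current
  type: continuous
  beta: 0.0
- name: bmi
  type: categorical
  breaks: [0.0, 25.0, 30.0, .inf]
  betas: [0.0, 0.0, 0.0]
- name: height_m
  type: categorical
  breaks: [0.0, 1.60, 1.65, 1.70, .inf]
  betas: [0.0, 0.0, 0.0, 0.0]
- name: alcohol_g_day
  type: categorical
  breaks: [0.0, 5.0, 30.0, .inf]
  betas: [0.0, 0.0, 0.0]
- name: smoking_status
  type: categorical
  levels:
    never: 0.0
    former: 0.0
    current: 0.0
- name: fdr_bc
  type: continuous
  beta: 0.0
unavailable: []
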