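states:
- on_ATD_initial
- remission
- long_term_remission
- relapse_on_long_term_ATD
- hypothyroid
- dead
complication_types:
- TAO
- atrial_fibrillation
- heart_failure
- osteoporosis
- fracture
- thyroid_cancer
parameters:
- name: prevalence_hyperthyroidism
  role: transition_probability
  base: 0.072
  low: 0.0576
  high: 0.0864
  distribution: beta
- name: p_atd_failure
  role: transition_probability
  base: 0.05
  low: 0.04
  high: 0.06
  horizon_years: 1.5
  distribution: beta
- name: p_hypothyroidism
  role: transition_probability
  base: 0.029
  low: 0.0232
  high: 0.0348
  horizon_years: 10.199999999999999
  distribution: beta
- name: p_relapse
  role: transition_probability
  base: 0.528
  low: 0.4224
  high: 0.6336
  horizon_years: 3.73
  distribution: beta
- name: p_tao
  role: transition_probability
  base: 0.25
  low: 0.2
  high: 0.3
  distribution: beta
- name: p_atrial_fibrillation
  role: transition_probability
  base: 0.043
  low: 0.03
  high: 0.05
  distribution: beta
- name: p_heart_failure
  role: transition_probability
  base: 0.016
  low: 0.011
  high: 0.021
  distribution: beta
- name: p_osteoporosis
  role: transition_probability
  base: 0.0159
  low: 0.0109
  high: 0.0209
  distribution: beta
- name: p_fracture
  role: transition_probability
  base: 0.033
  low: 0.028
  high: 0.038
  distribution: beta
- name: p_thyroid_cancer
  role: transition_probability
  base: 0.0123
  low: 0.009
  high: 0.02
  distribution: beta
- name: sens_digital
  role: test_characteristic
  base: 0.8713
  low: 0.784
  high: 0.958
  distribution: beta
- name: spec_digital
  role: test_characteristic
  base: 0.8378
  low: 0.754
  high: 0.9215
  distribution: beta
- name: sens_tft
  role: test_characteristic
  base: 1.0
  low: 1.0
  high: 1.0
  distribution: fixed
- name: spec_tft
  role: test_characteristic
  base: 1.0
  low: 1.0
  high: 1.0
  distribution: fixed
- name: u_thyroid_cancer
  role: utility
  base: 0.897
  low: 0.852
  high: 0.941
  distribution: beta
- name: u_hypothyroid
  role: utility
  base: 0.9479
  low: 0.902
  high: 0.997
  distribution: beta
- name: u_tao
  role: utility
  base: 0.84
  low: 0.798
  high: 0.882
  distribution: beta
- name: u_atd
  role: utility
  base: 0.86
  low: 0.817
  high: 0.903
  distribution: beta
- name: u_osteoporosis
  role: utility
  base: 0.91
  low: 0.8645
  high: 0.9555
  distribution: beta
- name: u_fracture
  role: utility
  base: 0.83
  low: 0.7885
  high: 0.8715
  distribution: beta
- name: u_atrial_fibrillation
  role: utility
  base: 0.81
  low: 0.729
  high: 0.891
  distribution: beta
- name: u_heart_failure
  role: utility
  base: 0.78
  low: 0.702
  high: 0.858
  distribution: beta
- name: u_remission
  role: utility
  base: 1.0
  low: 1.0
  high: 1.0
  distribution: fixed
- name: c_acute_care
  role: one_time_cost
  base: 1125.150000000000091
  low: 1012.639999999999986
  high: 1237.670000000000073
  distribution: gamma
- name: c_tao
  role: annual_cost
  base: 386.769999999999982
  low: 367.439999999999998
  high: 406.110000000000014
  distribution: gamma
- name: c_atrial_fibrillation
  role: annual_cost
  base: 150.539999999999992
  low: 143.02000000000001
  high: 158.069999999999993
  distribution: gamma
- name: c_heart_failure
  role: annual_cost
  base: 439.629999999999995
  low: 417.649999999999977
  high: 461.610000000000014
  distribution: gamma
- name: c_osteoporosis
  role: annual_cost
  base: 208.490000000000009
  low: 198.069999999999993
  high: 218.909999999999997
  distribution: gamma
- name: c_fracture
  role: annual_cost
  base: 347.410000000000025
  low: 330.04000000000002
  high: 364.779999999999973
  distribution: gamma
- name: c_thyroid_cancer
  role: annual_cost
  base: 149.22999999999999
  low: 141.77000000000001
  high: 156.689999999999998
  distribution: gamma
- name: c_hypothyroid
  role: annual_cost
  base: 250.370000000000005
  low: 225.340000000000003
  high: 275.410000000000025
  distribution: gamma
- name: c_long_term_atd
  role: annual_cost
  base: 48.869999999999997
  low: 43.979999999999997
  high: 53.759999999999998
  distribution: gamma
- name: monthly_fee
  role: annual_cost
  base: 30.0
  low: 10.0
  high: 50.0
  distribution: gamma
- name: c_tft_visit
  role: annual_cost
  base: 92.439999999999998
  low: 64.709999999999994
  high: 120.170000000000002
  distribution: gamma
- name: discount_rate
  role: rate
  base: 0.045
  low: 0.03
  high: 0.05
  distribution: fixed
economics:
  discount_rate: 0.045
  wtp: 32255.0
  currency_label: USD 2022
structure:
  atd_course_years: 2
  remission_window_years: 5
  tao_window_years: 2
  subsequent_remission_prob: 0.05
  classification_priority:
  - complication
  - hypothyroid
  - long_term_remission
  - relapse_on_long_term_ATD
  excess_mortality:
    on_ATD_initial: 1.0
    remission: 1.0
    long_term_remission: 1.0
    relapse_on_long_term_ATD: 1.0
    hypothyroid: 1.0
  extra_annual_cost:
    control: 0.0
    digital: 0.0
intervention:
  sensitivity: 0.8713
  specificity: 0.8378
  monthly_fee: 30.0
  visit_cost_reduction: 0.0
  theta_r: 1.0
  theta_p: 1.0
cohort:
  start_age: 40
  'n': 10000
  max_cycles: 70
  cycle_length_years: 1.0
mortality:
  type: gompertz_makeham
  makeham_a: 0.0005
  gompertz_b: 3.0e-05
  gompertz_eta: 0.095
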