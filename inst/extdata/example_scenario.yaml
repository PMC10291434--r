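# Example synthetic-community scenario: a reduced two-layer community for
# quick experimentation. All fields mirror scenario_config(); omitted fields
# keep their defaults (44 households, 4 hamlets, Gini targets 0.38/0.62).
n_households: 20
n_hamlets: 2
gini_wealth: 0.38
status_prev: 0.2
dev_prev: 0.35
layers:
  friendship_f:
    mode: single
    params:
      alpha: -2.5
      gamma: {log_wealth: 0.4, wealth_distance: -0.3,
              relatedness: 0.5, distance: -0.4}
      sigma_lambda: 0.7
      sigma_pi: 0.7
      sigma_delta: 1.0
      B_dev_group: [[0.0, 0.0], [0.0, 0.6]]
  food_sharing:
    mode: double
    cross: [friendship_f]
    params:
      alpha: -2.5
      gamma: {log_wealth: 0.4, wealth_distance: 0.0,
              relatedness: 0.5, distance: -0.4, friendship_f: 0.6}
      sigma_lambda: 0.7
      sigma_pi: 0.7
      sigma_delta: 1.0
    meas:
      recall_give: 0.9
      recall_receive: 0.85
      fp_give: 0.05
      fp_receive: 0.03
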