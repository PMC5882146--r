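# Classic two-stage task: drifting reward probabilities
common_transition_prob: 0.7
n_final_actions: 2
n_trials: 250
schedule:
  kind: drifting
  init_low: 0.25
  init_high: 0.75
  step_sd: 0.025
  bound_low: 0.25
  bound_high: 0.75
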