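# Fixed reward probabilities summing above one: 0.8 everywhere
common_transition_prob: 0.7
n_final_actions: 2
n_trials: 250
schedule:
  kind: fixed
  pink: 0.8
  blue: 0.8
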