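# Swap schedule (single final action): 0.8/0.2 swapped with prob 0.02
common_transition_prob: 0.7
n_final_actions: 1
n_trials: 250
schedule:
  kind: swap
  high: 0.8
  low: 0.2
  swap_prob: 0.02
  refractory: 10
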