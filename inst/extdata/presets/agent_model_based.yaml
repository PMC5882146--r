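class: model_based
alpha: 0.5
beta: 5.0
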