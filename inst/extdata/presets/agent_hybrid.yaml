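class: hybrid
alpha: 0.5
lambda: 1.0
beta: 5.0
w: 0.5
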