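kind: nulling-demo
seed: 1
ns_max: 4
n_periods: 1
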