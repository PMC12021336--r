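kind: dce-quant
seed: 1
matrix_size: 24
noise_sd: 0
ktrans_normal: 1.0
ktrans_defect: 0.3
with_defect: true
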