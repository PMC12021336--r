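kind: recon-demo
seed: 1
matrix_size: 64
Ns: 3
rays: 360
tb_mode: eq_spoil
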