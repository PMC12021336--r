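# Flow-tube error maps: peak and post-injection blood T1, velocities up to
# 30 cm/s, three transition-band options.
kind: flow-error
seed: 1
T1_ms: [63, 234]
velocities_cm_s: [0, 10, 20, 30]
tb_thicknesses_mm: [0, 7, 17.4]
n_excitations: 1428
TR_ms: 2.1
flip_deg: 12
pd_flip_deg: 2
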