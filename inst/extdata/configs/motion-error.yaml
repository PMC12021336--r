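# Sinusoidal through-plane motion at the vasodilation-stress heart rate:
# amplitude of one slice thickness, post-injection blood T1.
kind: motion-error
seed: 1
T1_ms: 234
heart_rate_bpm: 120
amplitude_mm: 7
use_tb: true
n_excitations: 1428
t1_grid_step_ms: 1
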