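# tbperf

Simulation and quantification toolkit for **ungated steady-state cardiac
perfusion MRI with transition bands**.

Ungated steady-state perfusion runs a continuous multiband radial FLASH
readout through the whole cardiac cycle and quantifies myocardial blood flow
by converting the proton-density-normalized signal to T1 (dictionary
matching), to gadolinium concentration (`1/T1 = 1/T1_0 + r[Gd]`), and to
Ktrans through the two-compartment model

    Ctis(t) = Cbld(t − Δt) ⊛ Ktrans e^(−kep t) + Vb Cbld(t − Δt).

The conversion assumes every voxel is in the sequence's magnetization steady
state — an assumption broken at the edge slices by through-plane cardiac
motion and by blood flowing into the left ventricle. The sequence
modification studied here excites a *transition band* on each end of the
imaged region, simultaneously with the slice groups and with identical
excitation history, so moving tissue arrives already in steady state. The
band's own signal is nulled by (i) gradient dephasing from the deliberate
B1-peak offset between early-asymmetric band and late-asymmetric image
pulses, and (ii) a band phase-cycling scheme — `e^(−iπm)` for odd multiband
factor Ns, `e^(−iπ(m+⌊(m−1)/Ns⌋))` for even Ns — whose demodulated weights
sum to exactly zero over any multiple of 2·Ns excitations.

The package is for sequence and reconstruction researchers who want a tested
desk-scale model of this mechanism: asymmetric multiband pulse design, the
CAIPI/band phase-cycling algebra and its nulling theorem, a longitudinal
Bloch simulator with inflow and through-plane motion, dictionary T1
estimation, a small exact-NUDFT golden-angle radial demo of artifact
localization and nulling, and the full T1 → [Gd] → Ktrans chain with AHA
16-segment summaries.

## Worked example

The six-excitation phase-cycling block for a three-slice group, and the
residual transition-band weight each reconstructed slice would see:

```r
library(tbperf)
tidy(phase_schedule(3, 6))
#> # A tibble: 6 × 5
#>       m slice_1 slice_2 slice_3    tb
#>   <int>   <dbl>   <dbl>   <dbl> <dbl>
#> 1     1       0    -120     120   180
#> 2     2       0     120    -120     0
#> 3     3       0       0       0   180
#> 4     4       0    -120     120     0
#> 5     5       0     120    -120   180
#> 6     6       0       0       0     0

sapply(1:3, function(b) abs(residual_weight(b, 3, 6, "off")))
#> [1] 6.000000e+00 7.228881e-16 1.556621e-15   # unspoiled: all on slice 1
sapply(1:3, function(b) abs(residual_weight(b, 3, 6, "eq_spoil")))
#> [1] 3.673940e-16 1.241801e-15 1.479340e-15   # spoiled: nulled everywhere
```

Without the band phase the residue lands entirely on the first slice of the
group (6 = 2·Ns); with it, every slice is nulled to machine precision.

The pharmacokinetic chain, fit on a synthetic gamma-variate arterial input:

```r
aif <- gamma_variate_aif()
fit <- fit_2cm(forward_2cm(aif, pk_params(1.0, 2.0, 0.05, 1)), aif)
fit
#> <tbp_pk_fit> Ktrans 1.000 /min, kep 2.000 /min, Vb 0.050, delay 1.00 s (RSS 0, n=91)
```

The through-plane motion experiment (heart rate 120 bpm, displacement of one
slice thickness, blood T1 234 ms) quantifies what the bands buy: the
edge-slice T1 error drops from ≈35% to below 1%:

```r
mot <- motion_model("sinusoidal", heart_rate_bpm = 120, amplitude_mm = 7)
edge_slice_error(motion_error_experiment(234, mot, sequence_params(use_tb = TRUE)))
#> [1] 0.8547009
edge_slice_error(motion_error_experiment(234, mot, sequence_params(use_tb = FALSE)))
#> [1] 35.04274
```

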