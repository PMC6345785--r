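# rgcspeed

Speed tuning and motion decoding in retinal ganglion cell (RGC)
populations under stimuli of graded spatial-frequency bandwidth.

Retinal ganglion cells are tuned to stimulus speed, and that tuning
depends on stimulus statistics: as a moving pattern goes from a drifting
sinusoidal grating (a single point in spatiotemporal frequency space) to
a broadband naturalistic texture, many cells narrow their speed tuning,
the population response becomes sparser, and stimulus speed can still be
decoded from the population at a lower spike cost. `rgcspeed` implements
the complete analysis chain for this phenomenon, exercised against a
synthetic linear–nonlinear–Poisson (LN-P) retina so every estimator can
be validated on data with known ground truth. It is aimed at
computational and sensory neuroscientists who want the machinery —
stimulus synthesis, receptive-field estimation, tuning quantification,
population statistics, and decoding — as tested, composable R functions.

## What it computes

**Stimuli.** Drifting gratings, band-limited random-phase motion
textures ("motion clouds") whose power spectrum is an envelope around the
constant-speed plane f_t = −v·f_x with radial log-Gaussian
spatial-frequency envelope (centre sf₀, bandwidth B_sf), and white-noise
checkerboards; all calibrated in mm and seconds, normalized to Michelson
contrast 1, with Weber-contrast diagnostics. The protocol grid crosses
six spatial frequencies × five speeds × three classes
(`condition_grid()`).

**Receptive fields.** Spike-triggered averages by reverse correlation
(chunked for long runs, merged exactly by spike-count weighting), 2-D
Gaussian spatial fits with the eccentricity discard rule
ε = √(1 − (b/a)²) > 0.9, and temporal fits to a difference of low-pass
filter cascades

    f(t) = p₁ (t/τ₁)ⁿ e^{−n(t/τ₁ − 1)} − p₂ (t/τ₂)ⁿ e^{−n(t/τ₂ − 1)},

with peak-time and zero-cross markers.

**Speed tuning.** PSTHs (200-ms onset discard), the standardized F1
modulation score zF1 = (F1 − mean FFT)/SD FFT, a Pearson zF1-vs-rate
screen, and skewed log-Gaussian tuning fits

    R(v) = A [ exp( −(log₂v − log₂V)² / (2(σᵥ + ζ(log₂v − log₂V))²) ) − e^{−1/ζ²} ],

peaking at the preferred speed V. Cells fitting with χ² < 0.05 at every
spatial frequency (and passing the screen) are *speed responsive*;
bandwidth change is Δσ = (σ₁ − σ₂)/(σ₁ + σ₂).

**Population statistics.** Size-corrected Treves–Rolls population
sparseness, per-condition population tuning with paired Wilcoxon
signed-rank comparisons, and flash-response (Fast/Slow ×
Transient/Sustained) classification.

**Decoding.** Linear stimulus reconstruction
I(x, i) = a + Σ_c ω_c Σ_j r^c_{i−j} RF^c_{x,j} from binned spike counts
and collapsed receptive fields, followed by a motion-energy cascade:
quadrature pairs of space-time slanted Gabors, squared and summed
(phase-invariant energy), opponent subtraction between directions, and a
winner-takes-all speed readout, with error-rate and accuracy-cost
(spikes per successful transmission) summaries.

## Worked example

A scaled-down end-to-end run: simulate 40 tuned cells on a 3 × 5 × 3
condition grid (10 trials of 3 s), screen for modulation, fit tuning per
cell/class/spatial frequency, classify speed-responsive cells, and
compare tuning widths across stimulus classes:

```r
library(rgcspeed)
res <- run_speed_analysis(speed_analysis_config(seed = 7))
print(res)
#> <speed_analysis_result> checksum 50992483
#>   40 cells; 12 pass modulation screen; 12 speed responsive
res$summary$median_delta_sigma
#>        kind delta_sigma
#> 1  mc_broad  0.30759238
#> 2 mc_narrow  0.09796026
res$summary$sparseness_by_kind
#>        kind sparseness_mean
#> 1   grating       0.2367982
#> 2  mc_broad       0.4429192
#> 3 mc_narrow       0.2893996
```

The median Δσ per class recovers the narrowing planted in the generator
(its per-class width multipliers 0.82 and 0.54 correspond to Δσ of 0.10
and 0.30), and the population response is sparsest for the
broad-bandwidth textures — the qualitative signature the analysis is
designed to measure. `write_report(res, "out/")` emits every per-stage
table plus a plain-text summary.

Individual stages are exported directly, e.g.:

```r
speeds <- c(0.25, 0.5, 1, 2, 4)
fit <- fit_speed_tuning(speed_tuning_curve(speeds, 18, 1.5, 1.2, 0.15), speeds)
#> V = 1.500 mm/s, sigma_v = 1.200, zeta = 0.150, chi2 = 2.5e-32
```

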