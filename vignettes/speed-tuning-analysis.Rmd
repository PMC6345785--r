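---
title: "Speed tuning and motion decoding in a synthetic retina: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed tuning and motion decoding in a synthetic retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcspeed)
```

## The scientific question

Retinal ganglion cells (RGCs) respond selectively to the speed of moving
stimuli, and that selectivity depends on how "naturalistic" the stimulus
is. A drifting sinusoidal grating concentrates all its power at a single
point in spatiotemporal frequency space; natural scenes spread power over
a broad band. Motion clouds — random-phase textures whose power spectrum
is a parameterized envelope around a plane of constant speed — interpolate
between the two with a single knob, the spatial-frequency bandwidth
`b_sf`. The empirical phenomenon this package is built to analyse is that
many RGCs *narrow* their speed tuning as stimulus bandwidth grows, the
population response becomes sparser, and yet stimulus speed remains
decodable from the population at a lower spike cost.

Because the analysis chain is long (stimulus synthesis, receptive-field
estimation, tuning fits, screening rules, reconstruction, decoding), each
stage here is implemented against a ground-truth simulator, so every
estimator can be validated on data whose true parameters are known.

## Stimulus models

**Drifting gratings.** A sinusoid translating along the horizontal axis at
speed `v` (mm/s) with spatial frequency `sf0` (cycles/mm); its temporal
frequency is `sf0 * v` Hz. All movies are affinely rescaled to `[0, 1]`,
i.e. Michelson contrast 1, which is what makes the three stimulus classes
comparable: they share peak contrast but differ in their Weber-contrast
distributions (bimodal for gratings, centrally concentrated for clouds).

**Motion clouds.** The spectral envelope is the product of

* a log-Gaussian radial envelope centred at `sf0` with width
  `log(1 + b_sf/sf0)`, carrying an additional `1/f` colour factor (the
  natural-image amplitude scaling used by the reference open-source
  formulation of these textures);
* a Gaussian around the constant-speed plane `f_t = -v f_x`, with
  standard deviation `b_v * sf0 * v` (default `b_v = 0.1`, i.e. roughly
  ±10% of the central temporal frequency, floored at the frequency
  resolution `1/duration`);
* a Gaussian orientation envelope about the motion axis with width 15°.

Phases are i.i.d. uniform, so a (parameters, seed) pair is bit
reproducible. The protocol grid (`condition_grid()`) crosses six spatial
frequencies (0.66–3.6 cycles/mm) with five speeds (0.25–4 mm/s) and three
classes. The narrow-bandwidth values per spatial frequency are a fixed
packaged table (0.24, 0.36, 0.54, 0.72, 1.08, 1.5 cycles/mm), chosen so
adjacent envelopes do not overlap — the non-overlap rule does not reduce
to a closed formula, so the table is authoritative. The broad preset sets
`b_sf = sf0`. Pixel calibration defaults to 240 px/mm; the rounded 4 µm/px
figure is the same constant and both are exposed as arguments.

One measurement subtlety: with 3-s trials the slowest grating temporal
frequency (0.165 Hz) falls between DFT grid points, so
`measure_temporal_frequency()` does not bin an FFT. It demodulates each
frame against the carrier by exact least squares and regresses the phase
across frames — exact to machine precision for a rigid translation.

**Checkerboards.** White-noise blocks (default 0.05 mm) are stored at one
pixel per block. For a blockwise-constant stimulus this is lossless, and
it keeps 20-minute receptive-field runs tractable.

## The ground-truth retina

The simulator's only job is statistical structure, not biophysics. Each
cell has

* an elliptical Gaussian spatial receptive field (equivalent radius
  `sqrt(a*b)` drawn around 0.1 mm, aspect ratio `b/a` in 0.6–1), unit L2
  norm, sign-flipped for OFF cells; the default ON fraction is 0.2,
  reflecting the low ON/OFF ratio of the retinas this emulates;
* a biphasic temporal kernel, the difference of two low-pass cascades
  `f(t) = p (t/tau)^n exp(-n(t/tau - 1))` (peak at `t = tau`, in frames);
* a half-wave rectifying output with additive baseline and Poisson
  spiking, trials independent (the experimental protocol's 3-s exposures
  with blank intervals justify ignoring adaptation).

The printed form of the cascade model in the source literature is
dimensionally inconsistent (`exp(-n t/(tau - 1))`); the canonical
parameterization above is adopted instead, which is well posed and peaks
at `tau` with amplitude `p`.

A second generator (`simulate_tuned_spike_trains()`) inverts the tuning
model: spikes are drawn so the mean rate follows the skewed log-Gaussian
curve

R(v) = A [ exp( −(log2 v − log2 V)² / (2 (σᵥ + ζ(log2 v − log2 V))²) ) − exp(−1/ζ²) ],

whose maximum over `v > 0` sits at the preferred speed `V` with value
`A (1 − exp(−1/ζ²))`. Per-class multipliers on `σᵥ` (defaults 1, 0.82,
0.54 for grating / narrow / broad, matching the ratios of the example
tuning widths 1.76 → 1.45 → 0.95) emulate bandwidth-dependent narrowing
for end-to-end demonstrations. By default this generator is homogeneous
Poisson within a condition; the pipeline enables an optional sinusoidal
rate modulation at the stimulus temporal frequency (`f1_modulation`,
default 0.8 in `speed_analysis_config()`) because a strictly homogeneous
train carries no F1 component and would fail the modulation screen by
construction — the modulation is the minimal addition that gives the
screening stage something to measure.

## Receptive-field estimation

The spike-triggered average is plain reverse correlation on the
mean-subtracted checkerboard, 18 lags (0.3 s) deep by default. Long runs
are processed in seeded chunks and merged through the exact identity
"STA of pooled spikes = spike-count-weighted mean of chunk STAs".

The spatial fit is a 2-D elliptical Gaussian at the lag of maximum
absolute amplitude (ties → earliest lag), initialized at the peak pixel
with widths from the second moments of the half-maximum lobe, optimized
by BFGS with the correlation parameterized through `tanh` to keep the
covariance positive definite. The 1-s.d. ellipse gives semi-axes
`a >= b`, equivalent radius `sqrt(a b)` and eccentricity
`sqrt(1 - (b/a)^2)`; fits with eccentricity above 0.9 are flagged invalid
rather than raised, implementing the noisy-STA discard rule.

The temporal fit takes the time course at the pixel of maximal variance,
subtracts the mean of the last three lags as baseline, flips OFF profiles
and normalizes the peak to 1. Numerically the difference-of-cascades
family is treacherous: letting `tau2 -> tau1` with exploding amplitudes
mimics a cascade derivative and traps naive optimizers. Three choices
make the fit reliable, all visible in `fit_temporal_profile()`:

1. *Variable projection* — for fixed `(tau1, tau2, n)` the model is linear
   in the amplitudes, so they are solved in closed form inside the
   3-parameter search;
2. a *small ridge* (1e-5 of the trace norm) on the amplitudes, which
   leaves genuine solutions untouched but penalizes the degenerate
   derivative direction;
3. a *free intercept* in the linear solve, absorbing whatever the
   last-three-lags baseline estimate missed when the rebound lobe has not
   fully decayed inside the STA window — without it the truth is not in
   the model family and parameter estimates bias by ~20%.

Fitted amplitudes are therefore defined up to the peak normalization;
recovery is assessed on `tau1`, `tau2`, `n` and the ratio `p2/p1`. The
markers compared between cell classes are the peak time of the leading
lobe and the first zero crossing after it (root-bracketed on the
continuous fitted curve; absent for monophasic fits, detected as
`p2 <= 1e-3 p1`).

## Tuning quantification and screening

PSTHs start 200 ms after stimulus onset (discarding the onset transient)
with 50-ms bins — the bin width is not dictated by the protocol and is
exposed as a parameter. The response measure per condition is the mean
PSTH rate over the analysis window.

The modulation statistic is the standardized F1,
`zF1 = (F1 - mean(FFT)) / SD(FFT)` over the band from `1/T` to Nyquist
(DC excluded, so the score is shift invariant). The stimulus frequency is
matched to the nearest analysed bin; whether it fell within half a bin is
recorded, since the slowest protocol conditions sit below the 1/2.8 Hz
resolution of a 2.8-s window. Cells whose zF1 does not correlate with
their mean rate across the 30 grating conditions (Pearson, p > 0.05) are
discarded; the pairing set across all grating conditions is a package
choice, as is two-sidedness.

The tuning fit is bounded multi-start least squares in log2 speed
(`V` within [min speed/2, max speed × 2], `σᵥ` in (0.05, 10], `ζ` in
[−1, 1]; starts at every tested speed and three skew values; ties go to
the smallest width; width terms crossing zero inside the fitted range are
penalized). χ² is defined as the sum of squared residuals on
peak-normalized responses — the definition is not unique ("normalized
response" admits several readings) but SSR on a [0,1] scale matches the
0.05 threshold's magnitude. A cell is *speed responsive* (SR) when it
passes the screen and fits with χ² < 0.05 at **every** tested spatial
frequency. Bandwidth change between conditions is the normalized
difference `Δσ = (σ₁ − σ₂)/(σ₁ + σ₂)`.

## Population measures

Population sparseness is the size-corrected Treves–Rolls measure; it is
0 for uniform responses, 1 for a one-hot population, scale and
permutation invariant. Per-condition sparseness is computed per trial on
spike counts, then averaged over trials. Class comparisons use two-sided
Wilcoxon signed-rank tests over the same cells (exact below n = 25,
normal approximation with continuity correction above; all-zero
difference vectors return p = 1 by convention). The flash latency /
transience classification is a reimplementation choice (the original
index formulas are in literature not restated here): latency = time to
peak within 0–400 ms, transience = 1 − mean late rate (400–800 ms) /
peak rate, median splits on both.

## Reconstruction and decoding

The linear reconstruction is
`I(x, i) = a + Σ_c ω_c Σ_j r^c_(i−j) RF^c(x, j)` with 16.66-ms bins.
Weights stay at `ω = 1` and the offset at the stimulus mean: the readout
has no access to the true signal, so no weight fitting is performed. The
3-D receptive field is collapsed over the axis orthogonal to motion by an
unweighted mean across the rows intersecting the field's 2-s.d. vertical
extent, which preserves separable structure exactly.

Speed is decoded by a bank of quadrature pairs of space-time slanted
Gabors (slant = preferred speed), squared and summed for phase-invariant
motion energy, opponent-subtracted between directions, winner-takes-all
on the magnitude of the net signal with the sign giving direction. A
static pattern cancels exactly at the opponent stage and returns a
no-decision flag (counted as incorrect). Channel energies are averaged
per valid filter position so channels with different kernel sizes are
comparable.

Two geometry choices matter and were fixed after explicit robustness
checks (both are exposed as arguments):

* *Temporal extent*: each channel targets two carrier periods but is
  capped at a 1-s half-extent. Slow channels would otherwise need 9-s
  kernels inside 3-s trials; and even a 1.25-s cap leaves only a 0.5-s
  valid correlation window, which made 0.25 vs 0.5 mm/s discrimination
  unstable. With the 1-s cap the closed loop decoded 50/50 simulated
  grating runs over ten independent populations.
* *Population density*: the closed-loop demonstrations use 60 cells over
  a 3.2-mm field. Biological patches carry hundreds of RGCs; sparser
  random populations (~25 cells) leave coverage gaps that corrupt the
  reconstruction enough to flip adjacent slow channels.

Decoding quality is summarized as the error rate (1 − fraction of
correct trials) per condition and class, and the *accuracy cost* =
success rate × (total spikes / number of cells) — the spike expenditure
per unit of successfully transmitted speed.

## What the synthetic data do and do not establish

The generators reproduce the statistical structure the estimators assume:
Poisson variability, elliptical Gaussian fields, cascade temporal
kernels, skewed log-Gaussian tuning, per-class tuning narrowing, and a
linear encoding model for the decoding loop. Passing tests therefore
demonstrate *estimator correctness* — that each stage recovers what was
planted, at the stated tolerances — not biological truth. Real recordings
add everything the simulator deliberately omits: adaptation, noise
correlations, surround suppression and other nonlinearities, cell-type
diversity beyond ON/OFF, eye-movement artefacts. In particular the
headline biological numbers of the motivating study (SR-cell counts,
specific σᵥ shifts, spikes-per-cell costs) depend on the recorded
population and are not reproduction targets here; the package reproduces
the *machinery* and its analytic invariants.

## Problem sizes

The default `speed_analysis_config()` runs 40 cells on a 3 × 5 × 3
condition grid with 10 trials (~40 s on one core). The validation suite
uses 300–1200-s checkerboard runs for receptive-field recovery (chunked,
16×16 blocks), 200-trial runs for the χ² screening rates, 1000 simulated
cells for the screen's false-positive rate, and the full five-speed
closed decoding loop at 128 px and 60 cells; these sizes were chosen so
each statistical claim has comfortable sampling margin while a complete
run stays in the tens of seconds to minutes range.

## Known limitations

* The modulation screen needs periodic structure in the spike trains; for
  strictly homogeneous generators it rejects everything (by design — see
  `f1_modulation`).
* zF1 is ill-resolved for conditions whose temporal frequency falls below
  the PSTH window's frequency resolution; the nearest-bin match is
  recorded so such conditions can be excluded downstream.
* The amplitude parameters of the temporal cascade fit are identified
  only up to the peak normalization of the trace.
* Reconstruction fidelity, and hence decoding at the two slowest speeds,
  degrades with sparse or strongly clustered populations; this mirrors
  the coverage limits of the underlying linear decoding framework rather
  than a numerical defect.
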