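---
title: "Models and methods behind retinaspeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retinaspeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaspeed)
```

## The scientific problem

ON direction-selective ganglion cells (ON DSGCs) feed the accessory optic
system and drive the optokinetic reflex, which only needs to correct *slow*
global retinal slip. Correspondingly, ON DSGCs spike most strongly for
gratings drifting at about 150 µm/s on the retina (~5°/s) and fall silent at
speeds a few times faster. Their excitatory synaptic drive, however, peaks
near 710 µm/s, and their inhibitory drive near 1220 µm/s and it is much
larger in absolute charge — so the speed cutoff of the *output* is set by
the excitation/inhibition balance, not by the tuning of excitation itself.
The inhibition at fast speeds is mostly glycinergic, and its anatomical
source is the VGluT3 amacrine cell, a dual-transmitter interneuron whose
dendrites respond preferentially to fast motion.

`retinaspeed` implements the quantitative pipeline that supports this
picture — speed-tuning metrics from spikes and voltage-clamp charge
transfer, optogenetically evoked current quantification, calcium-imaging
selectivity and area-response analysis, and connectomic synapse
tabulation — together with a seeded synthetic-recording generator that
emulates each signal so the whole pipeline can be exercised and tested at
desk scale.

## Speed-tuning analysis

A *response* is the total spike count (cell-attached) or the
baseline-subtracted charge transfer (voltage clamp) over the 5 s stimulus.
Charge uses the mean current over the 0.5 s immediately preceding the
stimulus as baseline and integrates the remainder trapezoidally; pA·s are
reported as pC and the sign of the current is preserved (tuning analyses
use magnitudes).

Per-cell curves are trial means with SEM over trials. Three conventions
matter and are fixed package-wide:

* **Optimal speed** is the argmax of the trial-averaged curve; exact ties
  break toward the *slowest* speed (conservative for a slow-tuned cell
  class; the convention is otherwise arbitrary).
* **Half-maximum speed** scans from the global maximum toward faster
  speeds and returns the first linearly interpolated downward crossing of
  half the maximum. Curves that never descend to half within the tested
  range return `Inf` ("beyond range"), which propagates through shifts as
  a partial result rather than a fabricated number. For multi-peaked
  curves we fix the global-maximum convention; crossings before the global
  maximum are ignored.
* **Windows** are half-open `[on, off)` for counting; integrals span the
  closed window so adjoining windows tile additively. Missing trials are
  averaged over what exists, never imputed.

Population averages interpolate each cell onto the union of all cells'
stimulus values restricted to the range *every* cell covers — interpolation
only, never extrapolation — and carry a `measured_mask` marking grid points
where at least one cell had a real measurement. Cells are normalized by
their own maximum, except in drug/CNO comparisons where both conditions are
normalized by the cell's *control* maximum, so treated responses are
directly interpretable as fractions of control. The speed-range shift
between conditions is the difference of the two 0.5-crossings on those
control-normalized curves.

The E/I ratio interpolates the absolute excitatory and inhibitory charge
curves of one cell onto a common grid and reports `|E|/|I|` pointwise;
points with inhibition below a 1 pC floor are masked rather than reported
as unbounded ratios.

## Optogenetic current quantification

Evoked-current sweeps (20 kHz) are processed in a fixed order: average the
3–5 repeated trials, smooth with a centered 10 ms boxcar (edge-truncated),
subtract the mean of the 2 s pre-stimulus baseline, then take the extremum
in the response window — the maximum at +20 mV (outward IPSC), the minimum
at −65 mV with magnitude reported positive (inward EPSC). The *noise
level* is twice the SD of the smoothed baseline (population SD, divisor
*n*; at 20 kHz × 2 s the distinction from the sample SD is irrelevant).

A caveat we quantify rather than hide: comparing a *window extremum*
against a 2 × SD band is anti-conservative for pure noise. At a fixed,
stimulus-locked time the false-positive rate is the one-sided Gaussian tail
(≈2.3%), but the maximum over a window containing *m* effectively
independent smoothed samples exceeds the band with probability about
`1 − pnorm(2)^m` — tens of percent for a 1 s window at 10 ms smoothing. The
test suite measures this by Monte Carlo against the closed form. The
`above_noise` flag is therefore a descriptive label matching the figure
convention (peak vs noise band), not a calibrated significance test.

Pharmacology summaries normalize per-condition mean peaks by the
reference-condition peak and report fractional reductions. Cells with
trial-to-trial peak CV above 0.8 in the reference condition are flagged for
exclusion — a numeric stand-in for the qualitative "atypical or
inconsistent currents" exclusion, with the threshold exposed in
configuration and the flag carried in reports rather than silently applied.

## Calcium-imaging analysis

ΔF/F is computed per presentation: F₀ is the mean brightness over exactly
`floor(0.5 × 15 Hz) = 7` frames immediately before stimulus onset, never a
global baseline. Time-averaged responses use the full presentation, the
first 2 s (spots, whose transient dominates), or the first 5 s (gratings).
ROIs qualify for analysis when their time-averaged response *strictly
exceeds* a threshold (0.3–0.6 ΔF/F) in at least 3 (or 6) of 24
presentations; both knobs are arguments, and thresholds outside the usual
band warn rather than fail.

Direction and orientation selectivity use the standard normalized circular
harmonics over 8 equally spaced directions:

$$\mathrm{DSI} = \frac{\left|\sum_k R_k e^{i\theta_k}\right|}{\sum_k R_k},
\qquad
\mathrm{OSI} = \frac{\left|\sum_k R_k e^{2i\theta_k}\right|}{\sum_k R_k},$$

with the preferred direction the argument of the first-harmonic sum and the
preferred orientation half the argument of the second-harmonic sum, mod
180°. The exact formulas are pinned by closed-form tests (a pure cosine
tuning `1 + cos(θ − θ₀)` gives DSI = 0.5 exactly on 8 directions, and
OSI of any pattern equals DSI of the same pattern at doubled angles).
Negative direction means are clipped to zero before the sums so both
indices stay in [0, 1]; clipping is reported. Classification uses
index ≥ 0.2 (the figure-caption convention; a strict `>` variant is a
switch — the difference only touches boundary values). Mean trial responses
per direction enter the sums (pooling trials instead is a configuration
choice with no effect on noiseless data).

Circular statistics double orientation angles before averaging and halve
the result; dispersion is the circular SD `sqrt(−2 ln R̄)` scaled by
`1/sqrt(n)`. Area-response profiles report the argmax diameter and the
*suppression index*, the response at the largest tested diameter as a
fraction of the maximum (1 = no surround suppression).

Pixel-level ROI segmentation is out of scope: masks or extracted traces are
the input, matching a workflow where ROIs are drawn on a standard-deviation
projection.

## Connectomic tabulation

Synapse tallies count annotated contacts per presynaptic type; percentages
use either the identified-only denominator (excluding `unidentified`
fragments — the headline convention, e.g. 40 VGluT3 of 438 identified
contacts → 9%) or all rows. Percentages always sum to 100 before rounding.

Depths are normalized to the two starburst (ChAT) plexuses to remove the
tilt and curvature of the tissue block: with fiducial surfaces
`z_off(x, y)` and `z_on(x, y)` fitted to band node annotations by
least-squares low-order polynomials (degree 1 by default; the fitting rule
is our choice, as is the OFF = 0 / ON = 1 convention — both bands are used
because stratification is displayed against both),

$$\text{depth}_\text{norm} = \frac{z - z_\text{off}}{z_\text{on} - z_\text{off}},$$

with linear extrapolation outside the bands. Tilt invariance is tested by
construction: synapses at a fixed normalized offset above tilted planes get
position-independent normalized depths.

## The synthetic-recording generator

The generator is first-class, tested code. Its defaults *are* the study
conditions: they reproduce the printed population summary values, and the
analyses recover them end to end. What it emulates, and how:

**Speed tuning.** Charge tuning is log-Gaussian,
`A · exp(−(ln v − ln v₀)² / 2σ²)` — not a mechanistic claim, just the
simplest unimodal form on a log-speed axis consistent with the printed
optima and half-maxima. Excitation: peak 710 µm/s, amplitude 490 pC, width
0.995 (set by the printed descending half-maximum of 2290 µm/s).
Inhibition: peak 1220 µm/s, amplitude 2200 pC, width 0.85 (so its
half-maximum falls beyond 2900 µm/s, as observed). Within a sweep,
excitation oscillates with one peak per grating cycle (temporal frequency
`v / 377 µm`); inhibition combines an anti-phase modulated component with a
sustained plateau whose weight is a logistic in ln v with midpoint at the
E/I crossover (700 µm/s) — fast gratings recruit a continuous inhibitory
conductance, slow ones a modulated one. Trial-to-trial variability is a
multiplicative gain (CV 0.1) plus white current noise (5 pA/sample), which
reproduces realistic ~10% charge variability over 3 trials.

**Spiking.** Expected count = `gain · max(0, E(v) − w·I(v))` with w = 0.745
and gain 1.41 chosen so the drive peaks at 150 µm/s with ~96 spikes per
stimulus; spikes are drawn as an inhomogeneous Poisson process locked to
the excitatory modulation. This encodes the circuit-level claim that the E/I
balance, not intrinsic spike-generation machinery, sets the cutoff. Two
known consequences of this deliberately simple drive: the simulated spike
half-maximum (~225 µm/s) is steeper than the recorded population value
(360 ± 23 µm/s), and the strychnine-induced range extension (~300 µm/s) is
smaller than the recorded 1500 ± 500 µm/s. Only the three optima and the
component fractions are calibration targets; these two emergent numbers are
reported as computed.

**Pharmacological conditions.** Inhibition is an additive partition:
glycinergic fraction 0.57, GABAergic 0.43. Strychnine scales inhibition by
(1 − 0.57), SR95531 by (1 − 0.43), the combination to zero, and CNO by
(1 − 0.75 × 0.57) — the chemogenetically silenceable share of the
glycinergic component is 0.75, giving the printed 43% decrease. The
measured single-drug decreases are sub-additive in the recordings
(57% + 17% < 100%), which an additive two-component model cannot reproduce;
we carry the glycinergic value exactly (it is the headline number and the
direct contract of the condition algebra) and accept that the simulated
SR95531 effect (43%) overstates the printed 17 ± 7%.

**Optogenetics.** Evoked currents rise as a saturating exponential during
the pulse and decay exponentially after it. A single rise time constant,
0.1078 s, makes one amplitude parameter (43 pA) reproduce both printed
IPSC peaks — 43 pA for 1 s pulses and 26 pA for 0.1 s pulses, since
`43·(1 − e^{−0.1/0.1078}) = 26.0`. EPSCs (−65 mV) use 9 pA. Glutamate
blockade removes the disynaptic 21% of the IPSC and all of the EPSC;
glycine blockade leaves a 1% residue; the full cocktail leaves noise.
Raw noise is 8 pA/sample white Gaussian at 20 kHz.

**Calcium signals.** Fluorescence rides on baseline 100 with 2-unit frame
noise at 15 Hz. Responses ramp with a 1 s time constant (barely detectable
in the first second, near asymptote by ~2 s) and decay with τ = 0.5 s. The
noiseless amplitude factorizes as `S(v) · D(θ) · A(diam)`:

* `S` — log-Gaussian peaked at 1520 µm/s (width 1.0), monotone rising over
  the tested range;
* `D(θ) = 1 + k_DS cos(θ − θ_pref) + k_OS cos(2(θ − θ_ori))` with
  `k = 2 × index`, so the noiseless vector-sum indices equal the configured
  DSI (0.28) and OSI (0.38) *exactly* (the two harmonics are orthogonal
  over 8 equally spaced directions). Population preferred angles default to
  198° (direction) and 56° (orientation) with 10° per-ROI jitter. Per-ROI
  selectivity strengths scatter as independent mean-1 lognormal factors
  (sdlog 0.5) on the two harmonics: this keeps the population-mean indices
  at their calibrated values while letting a realistic minority of ROIs
  fall below the 0.2 criterion — the closed form gives
  `P(0.28g ≥ 0.2) ≈ 66%` direction-selective and `P(0.38g ≥ 0.2) ≈ 85%`
  orientation-selective, with independence yielding ~56% "both" and ~5%
  "neither", close to the printed classification fractions.
* `A(d)` — a difference of two saturating Gaussian area integrals
  `(1 − e^{−(d/σ_c)²}) − w_s (1 − e^{−(d/σ_s)²})`, with per-stimulus-kind
  parameters solved once so that spots peak at 219 µm and are suppressed to
  8% of maximum at 936 µm (σ_c = 149, σ_s = 356, w = 0.954) while grating
  patches peak at 330 µm and retain 20% (σ_c = 234, σ_s = 476, w = 0.916).

**Synapse tables.** Requested per-type counts are placed uniformly in the
volume footprint with normalized depths from type-specific Gaussians (SAC
and widefield at the ON plexus, VGluT3 mid-way between the bands) and
converted to raw depths through tilted fiducial planes, so depth
normalization has real work to undo. The default counts are those of the
reconstructed cell: 363 SAC, 30 widefield, 40 VGluT3 (from 16 cells),
5 other, 22 unidentified.

**Determinism.** Every `simulate_*` call derives all randomness from one
seed (its own argument, defaulting to `params$seed`) through a
save/restore-scoped RNG; identical parameters and seed give bit-identical
output, and no global RNG state leaks.

### What the generator does *not* emulate

Within-trial current waveforms are qualitative (the recordings' cycle-locked
shapes are richer); noise is white, not 1/f or synaptic; optogenetic drive
does not covary across cells, so cross-cell IPSC–EPSC correlation is not a
meaningful generator output; calcium indicator nonlinearity and
photobleaching are absent; there is no photoreceptor–bipolar cascade,
conductance-based biophysics, or pixel-level optics. Passing tests
therefore validate the *analysis* pipeline and the stated statistical
structure — they do not certify performance on raw experimental data with
artifacts outside this structure.

## Statistics and reporting

Comparisons use Student's t — paired and one-sided for within-cell
condition effects, unpaired for ROI ensembles chosen independently per
movie (pooled variance by default, Welch by switch). No multiplicity
adjustment is applied, matching the source convention; star annotations at
0.05/0.01/0.001 always accompany the raw p value. Zero-variance inputs are
guarded: identical pairs are an error, constant nonzero differences report
`t = ∞`, `p ≈ 0` with an explicit degenerate flag. `run_pipeline()` logs
every configuration value and seed; identical configuration yields
byte-identical metrics JSON.

## Problem sizes

The shipped analyses and the acceptance script use the study's own
population sizes where printed — 63/11/12 cells for spike/excitatory/
inhibitory tuning (7 speeds × 3 trials), 3–4 cells per pharmacological
comparison, 8 + 5 optogenetic cells (3 trials averaged), 245 ROIs in 6
fields of view for direction analysis, 4 fields of view for area-response
profiles, and the 460-synapse reconstruction. These sizes run in well under
a minute in total; the test suite uses smaller populations where the
property under test allows it.
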