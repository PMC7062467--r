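---
title: "Methods: models, parameters and design choices in fictloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fictloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

fictloc analyses three modalities recorded during drug-induced fictive
locomotion in isolated spinal cord preparations: extracellular ventral-root
discharge, GCaMP fluorescence from identified interneurons, and whole-cell
current/voltage-clamp sweeps from motoneurons. The pipeline starts from
per-channel time series (CSV or HDF5); image-stack processing, ROI
delineation and vendor acquisition formats are out of scope. Every stage has
a seeded synthetic counterpart with recorded ground truth, so correctness is
established by parameter recovery rather than by comparison against
non-deposited experimental recordings.

# Ventral-root burst analysis

## Rectification and integration

Population discharge is full-wave rectified and smoothed with a discrete
leaky integrator. We use the exponential-Euler coefficient
`a = 1 - exp(-Δt/τ)` rather than the forward-Euler `Δt/τ`: under a
zero-order-hold reading of the samples the discrete step response is then
exactly `1 - exp(-t/τ)` at sample boundaries, which is the contract the test
suite enforces to 1e-3 at 1 kHz; the two coefficients agree to first order
and converge as the sampling rate grows. τ defaults to 50 ms, matching the
online integration used during acquisition of such signals. The integrator
is seeded with `y[1] = |x[1]|` so the trace start is not an artificial onset.

## Burst detection

Interactive burst cursors in acquisition software are not reproducible, so
detection is re-specified as a robust threshold rule on the integrated
trace: a burst opens where the trace exceeds `B + k·MAD` and closes where it
falls back below, with defaults k = 4, minimum duration 0.3 s, merge gap
0.5 s. Two numerical choices matter:

* **Baseline statistics.** `B` is the median of the sub-median half of the
  trace, which tracks the inter-burst floor even at the ~50% burst duty
  cycles of 0.23 Hz rhythms with 2 s bursts; the spread is the scaled median
  absolute deviation of the *whole* trace about `B`, so that a burst-free
  noise trace keeps a full-width MAD and stays sub-threshold (a
  half-distribution MAD underestimates spread and produced false positives
  on pure noise).
* **Lag compensation.** A first-order integrator delays threshold crossings
  asymmetrically (rise by `τ·log((P-B)/(P-thr))`, fall by
  `τ·log((P-B)/(thr-B))` for a burst plateau `P`). Because τ is known, both
  crossings are backdated analytically. Without this, 2 s bursts measured
  ~8% too long; with it, recovered durations are within ~1.5% of truth
  across signal-to-noise ratios of 5–20.

Burst amplitude is the mean rectified raw signal inside `[onset, offset)`
minus the mean rectified inter-burst baseline; the peak-based variant is
available (`mode = "peak"`). The mean-based definition is gain-robust:
scaling the raw trace by c scales amplitudes by c and leaves onsets and
durations untouched, a property the suite tests. Frequency uses inter-onset
intervals, `(n-1)/(last-first onset)`, which is unbiased under partial
windows.

## Time courses and epoch comparisons

Per-burst metrics are averaged in 0.5-min bins and normalized to the mean
over a 10-min pre-control epoch (empty bins are missing, never zero).
Statistical comparisons use the raw per-preparation means over the final
5 min of each epoch (steady state), fed to the repeated-measures machinery.

# Calcium analysis

The ΔF/F₀ conversion is `100·(f - f₀)/f₀`. The baseline `f₀` automates the
usual manual choice of a quiet period: the minimum over all 10-consecutive-
frame window means within the first minute (checked against a brute-force
enumeration oracle).

Bleach correction divides by a mono-exponential-plus-offset fit to the
rolling 10th-percentile envelope (which tracks baseline, not transients),
renormalized so the first-minute level is preserved. It engages only when
the fitted decay exceeds 1% per minute — a cheap linear pre-screen skips
stable traces entirely — and a non-convergent fit passes the trace through
unchanged with a warning.

Transient detection at 5 Hz with ~1.5 s indicator decay has to separate
events that overlap within a locomotor cycle period. Detection operates on a
centred 3-frame mean (noise suppression without onset bias) and admits two
candidate types: (i) an upward threshold crossing (default 20% ΔF/F₀)
sustained ≥ 2 frames whose rise exceeds threshold/2 above the immediately
preceding local level — the prominence gate that rejects noise re-crossings
during decays; and (ii) while still above threshold, a local minimum
followed by a rise of ≥ threshold/2, which catches a transient stacked on
its predecessor's tail. Events closer than 1 s merge, keeping the larger
peak. On the generator's stated world (rise 0.2 s, decay 1.5 s, amplitudes
30–100%, noise 5% ΔF/F₀) this achieves recall ≥ 0.95 with ≤ 0.05 false
events/min and a mean onset error within one frame. Events from a
refractory-free Poisson stream (the generator's *uncoupled* cells) can
overlap arbitrarily closely and are not resolvable by any 5 Hz threshold
detector; the recall contract is therefore stated over cycle-separated
(coupled-cell) events.

# Phase coupling

Cycle onsets are flexor-related burst onsets; an event at `t` in cycle
`[oᵢ, oᵢ₊₁)` has phase `2π(t-oᵢ)/(oᵢ₊₁-oᵢ)`. Events outside the covered
span are excluded and counted. Transient *onsets* are phased by default
(peaks optional): with a slow indicator, onsets track firing more closely.
A cell's events are pooled across cycles into one circular sample.

The Rayleigh statistic is `Z = nR̄²` with the series approximation
`p ≈ e^{-Z}[1 + (2Z - Z²)/(4n) - (24Z - 132Z² + 76Z³ - 9Z⁴)/(288n²)]`
clipped to (0, 1]; samples with n < 4 are flagged underpowered with p = 1.
The series is validated against a 10⁵-resample Monte-Carlo null (agreement
within 0.01) and calibrated type-I error (rejection rate within
[0.04, 0.06] at n = 12). Cells with p < α (default 0.05) are "coupled"; no
multiplicity correction is applied across cells, matching standard practice
for this analysis.

# Patch-clamp features

All spike measures hang off two primitives: peak detection (local maximum
above −10 mV, 1 ms refractory) and the dV/dt onset criterion — central
differences on the raw, unfiltered ≥ 10 kHz trace, walking back from the
peak to the earliest sample of the final contiguous run with
dV/dt ≥ 10 mV/ms. No smoothing precedes the criterion, to keep it literal.
Half-width is measured at `onset_mV + (peak_mV - onset_mV)/2` with linear
interpolation between samples.

Choices where the field convention is not unique:

* Inter-spike AHP is referenced to the *preceding spike's onset voltage*
  (trough minus onset), which is offset-robust; it is computed over the last
  five intervals of the maximum-rate step, with a warned fallback to fewer.
* "Establishment of repetitive firing" before a depolarizing block is
  quantified as ≥ 2 spikes with inter-spike intervals < 100 ms; the block
  requires a subsequent spike-free period ≥ 100 ms before step end.
* mAHP uses a 5–200 ms post-spike search window on the 15-sweep average,
  excluding the fast AHP; sweeps with 0 or ≥ 2 spikes are dropped.
* Cells that never fire or never block report an explicit censored marker,
  never a fabricated numeric.

# Statistics

Test selection is a pure function of a D'Agostino–Pearson K² gate at
α = 0.05 (the gating level is our choice; the source analyses do not state
one): skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983)
transforms, `K² = Zs² + Zk² ~ χ²₂`, requiring n ≥ 8 — smaller samples are
flagged "assume non-normal". The implementation agrees with an independent
reference to 10 decimal places on frozen draws, rejects ~5% of normal
samples, and detects log-normality in ≥ 95% of n = 50 samples.

Paired comparisons use the gate on the differences (paired t vs Wilcoxon
signed-rank; exact p for n ≤ 25 without ties, normal approximation with
continuity correction otherwise; zero differences dropped, mid-ranks for
ties). Three-condition designs require complete blocks and use
repeated-measures ANOVA with Tukey HSD on the within-subject error term
(both sphericity-uncorrected and Greenhouse–Geisser-corrected p reported,
since source analyses rarely state which was used) or Friedman with Dunn's
post-test, Bonferroni-corrected over the three pairwise comparisons. An
unpaired branch (t vs Mann–Whitney) serves between-genotype designs.

# Synthetic data: the stated world

The generators are first-class, tested code. Their defaults *are* the
recording conditions the analysis chain targets:

* Ventral root: 0.23 Hz burst rate, 2.0 s mean burst duration, sampled at
  2 kHz (acquisition used 6 kHz; burst structure is three orders of
  magnitude slower, and 2 kHz keeps multi-preparation cohorts inside CPU
  budgets). Inter-onset intervals are Gamma(shape 10) — realistic but
  controllable rate variance — with ≥ 1 s enforced quiescence between
  bursts, and burst durations get Gamma jitter with CV 0.15: locomotor
  bursts are not clocked, their duration variance is itself an analysed
  quantity, and a zero-variance world would let millisecond-scale detection
  biases masquerade as condition effects. The raw trace is zero-mean
  Gaussian noise whose standard deviation is `baseline_gain +
  burst_gain·envelope` (default gains 1 and 4); epoch multipliers scale
  gain, rate and duration, and are exact in ground truth.
* Calcium: 5 Hz frames, kernel rise 0.2 s / decay 1.5 s, amplitudes
  30–100% ΔF/F₀, noise 5% ΔF/F₀. Coupled cells emit ≤ 1 transient per cycle
  (probability 0.8) at von Mises phases (Best–Fisher sampler, validated
  against the `I₁(κ)/I₀(κ)` resultant); uncoupled cells emit a rate-matched
  Poisson stream.
* Patch: 10 kHz sweeps; rest −60 mV, threshold −45 mV, R = 100 MΩ, f-I gain
  0.08 Hz/pA above a 110 pA rheobase, phenomenological hard block above
  510 pA (initial 3-spike burst then ≥ 100 ms silence — no conductance
  model is implied), voltage noise 0.15 mV RMS (typical whole-cell
  current-clamp noise). Spike cores are piecewise-linear (rise 0.8·hw, fall
  1.2·hw): with linear interpolation of half-amplitude crossings the
  measured half-width and the dV/dt onset are then *exact* functions of the
  parameters, which is the entire point of a parametric waveform — an
  exponential core would add interpolation error to every recovery target.
  AHPs are alpha-function (mAHP, trough exactly the configured depth at
  τ = 20 ms) or V-shaped (inter-spike trough) segments.

What a green test does **not** establish: the generators contain no
electrode drift, no seizure-like or non-stationary rhythms, no
calcium-indicator saturation or motion artifacts, no bridge-balance or
access-resistance errors, and the depolarizing block is a caricature.
Recovery guarantees transfer to real data only insofar as real recordings
resemble this world.

# Numerical and interface choices

Time is in seconds with half-open windows `[start, end)` and 0-based sample
times (`t_i = start + i/rate`); voltages in mV, currents in pA,
fluorescence in arbitrary units, ΔF/F₀ in percent. CSV carries metadata in
`# key=value` comment lines; HDF5 uses one group per channel with a
`values` dataset and rate/start/units attributes. Round trips preserve
values to 1e-9 relative. The printed ΔF/F₀ formula is implemented as the
standard `100·(f - f₀)/f₀`; the literal alternative `f - f₀/f₀` is
dimensionally incoherent. Degenerate inputs prefer explicit flags (censored
markers, underpowered Rayleigh, NA-with-warning) over silent numerics.

# Known limitations

* Left–right / flexor–extensor alternation statistics between roots are out
  of scope.
* The burst-detection threshold rule replaces, and cannot reconstruct, the
  interactive criteria used in the original acquisition software; the same
  holds for the transient-detection criterion.
* The bleach model is mono-exponential; multi-component photobleaching is
  only partially removed.
* Wilcoxon exact p-values are unavailable with ties (the usual limitation);
  the continuity-corrected approximation is used there.
* `run_patch_study` summarizes one sweep family per cell and condition; it
  does not model within-cell sweep-family replication.
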