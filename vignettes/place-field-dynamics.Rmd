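---
title: "Models and methods behind pfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfdyn)
```

`pfdyn` quantifies how hippocampal place fields emerge and evolve on a
lap-by-lap timescale in calcium-imaging recordings from head-fixed mice
running unidirectional virtual linear tracks. This vignette documents the
models and procedures it implements, the choices that were genuinely open,
and what the synthetic validation does and does not establish.

## The recording paradigm the package assumes

A session is a set of repeated traversals ("laps") of a linear track
(default 300 cm). After each traversal the animal pauses briefly (default
1.5 s) and is teleported back to the start, so position is a sawtooth and a
lap boundary is a large negative position discontinuity. Imaging runs at an
effective per-plane rate near 11 Hz (default 10.7 Hz), and activity arrives
as one ΔF/F trace per segmented neuron. Immobility (instantaneous velocity
slower than 0.2 cm/s, strictly) and backward movement are excluded from all
spatial binning; velocity is computed by centered finite differences with a
0.5 s boxcar, since the differentiator is not critical at these speeds.

## Significant-transient extraction

Slow drift is removed by subtracting, at every sample, the 8th percentile
of the trace in a ±5 s window. Two numerical choices matter here:

* the percentile is evaluated on a strided grid (every 5th sample) and
  linearly interpolated, which is indistinguishable from the dense
  computation at a 107-sample window and an order of magnitude faster;
* after subtraction the trace still sits slightly above zero (the 8th
  percentile of noise lies below its median), so the baseline level and
  the noise σ are estimated jointly: median and scaled MAD over samples
  outside provisional >2σ excursions, iterated three times. σ is floored
  at 10⁻³ ΔF/F so that noise-free simulated traces remain analyzable by
  the same thresholding code path.

Events start when the centered trace exceeds 2σ and end on return within
0.5σ. The same detector runs on the sign-flipped trace; negative-going
events cannot be real transients and estimate the false-positive content
of each (minimum amplitude in σ) × (minimum duration) class on a
5 × 5 grid ({2, 2.5, 3, 3.5, 4}σ × {0.2, …, 1.0} s, spanning GCaMP6f event
shapes at ~11 Hz). Classes with a negative/positive ratio below 1% are
accepted, acceptance is closed under "stricter", and only positive events
falling in an accepted class survive. Events that begin above threshold at
frame 1 are kept with onset 0 rather than dropped, so first-lap activity is
not silently lost. The "significant-transient-only" trace (corrected trace
inside surviving events, zero elsewhere) is the input to everything
downstream.

## Place-field definition

Per cell, mean ΔF/F is accumulated into a lap × 50-bin matrix over running
samples. Candidates are maximal runs of bins exceeding
`baseline + 0.15 (peak − baseline)` on the session-mean map, with baseline
the mean of the 12 lowest bins; no wraparound is allowed across the track
ends, since the teleport breaks spatial continuity there. A candidate must
be wider than 20 cm and narrower than 150 cm, contain a mean-map value
above 0.1 ΔF/F, have an in-field mean more than three times the out-field
mean, and carry in-field transients on at least 15 laps. The lap criterion
counts laps whose significant transients *peak* inside the extent — the
assignment of an event to a field is by its peak-sample position, a rule
the package applies consistently wherever transients are masked to a field.
The 15-lap requirement is a fixed default with a config override; it is
calibrated to sessions of roughly 30+ laps and should be lowered for
shorter recordings.

Significance comes from a bootstrap in which each lap's 50-bin vector is
circularly shifted by an independent uniform offset and the entire
candidate-plus-criteria pipeline is rerun; a null success is a qualifying
field whose in-field mean matches or exceeds the observed one, and
p = (1 + successes)/(1 + iterations), 1000 iterations by default. Circular
per-lap shifts were chosen as the null because they destroy the place code
while preserving within-lap transient structure (event count, width,
amplitude) exactly. The loop stops early once enough successes have
accumulated that p must exceed the significance threshold; this changes
only the reported magnitude of clearly non-significant p-values, never the
classification. Cells with several qualifying candidates are treated as
independent fields ranked by track position.

## Per-field metrics

With `DF_i` the ΔF/F in bin *i* at center `x_i`:

* COM per traversal: `COM_n = Σ DF_i x_i / Σ DF_i`, over the bins of the
  field-masked matrix. Because masking keeps whole transients (by peak
  position), a retained transient's spatial footprint may extend past the
  extent edge; the COM therefore integrates over all bins of the masked
  matrix. Truncating at the extent would bias the COM of drifting fields
  toward the extent center and attenuate measured drift by 20–30% at
  realistic widths.
* Weighted COM: `COM_w = Σ A_n COM_n / Σ A_n`, with `A_n` the traversal's
  peak in-field ΔF/F.
* Spatial precision: `SP = 1/√(Σ A_n (COM_n − COM_w)² / Σ A_n)`; zero
  variance returns `Inf` rather than an error so population summaries can
  filter the degenerate case.
* Skewness per lap: the third standardized moment of the masked profile;
  laps with fewer than three active bins are excluded.
* Width per lap: the inclusive first-to-last active in-field bin span times
  6 cm — inclusive so a single-bin lap has width 6 cm, not 0 — plus the
  series normalized to its own mean.
* Onset lap: scanning from lap 1, the first lap with an in-field transient
  such that at least 3 of the 6 laps starting there are active; laps beyond
  the session end count as inactive (the conservative reading). The 2-of-6
  and 4-of-6 variants are available, and the validated invariant is that
  they preserve the ordering of instant-rich vs delayed onset
  distributions. By default pre-onset transients are kept in all other
  analyses; masking them is a documented option rather than the default
  because it couples the onset definition into every metric.
* Edge clipping: a field whose COM is at least one bin closer to a track
  edge than half its width is flagged and excluded from shift, skewness,
  and width analyses.

## Shifting dynamics

Per field, an ordinary least-squares regression of the raw `COM_n` series
on lap number gives the drift slope, with significance from the regression
F test (p < 0.05 classifies backward/forward by sign; fewer than five
active laps excludes the field). The raw series is the default — the
five-lap smoothed variant is available — because smoothing inflates serial
correlation in the residuals and the F test's nominal level is then no
longer trustworthy; the type-I calibration in the test suite applies to
the raw-series default. Negative slopes are *backward* (against running),
a convention fixed here once for all outputs.

The session shift compares amplitude-weighted COMs over the five laps at
onset and the last five active laps, divided by the distance between the
two windows' amplitude-weighted mean laps. That denominator (rather than
last-minus-onset lap) makes the estimator exact under linear drift, which
is also what its validation asserts. A population-level null is built by
permuting each field's lap labels and recomputing the session shift.

The population shift curve computes, per field, the five-lap sliding
amplitude-weighted COM (current plus next four laps, truncated and flagged
at the session end) and subtracts its value at the reference lap 12, so
every field passes through zero there by construction. Only fields active
at the reference lap with onset before lap 20 are included; sessions
shorter than 17 laps refuse the analysis rather than silently rebasing to
a different reference. The pooled regression treats every (field, lap)
point as an observation, and condition comparisons resample the larger
population without replacement at the smaller population's size (80% of
the smallest for three or more conditions), refitting 1000 times.

## Stability and decoding

Spatial correlations are Pearson r between 50-bin mean maps: session
halves (by lap count) or first-10/next-10 laps within a session, and last
10 laps of day 1 vs first 10 of day 2 across days, with r > 0.5 counting
as stable (exactly 0.5 is unstable). Bins without occupancy enter mean
maps as zero, consistently with the field-detection matrices. Day-2 onset
laps are compared between stable (re-emerging) and newly formed fields
with a rank-sum test.

The decoder follows the position-based data layout: 100 fine bins (3 cm)
per lap per cell, targets collapsed to 50 classes by pairing fine bins,
training on laps 6–35, validation on 36–40, scoring on lap 1 as the mean
absolute difference between predicted class center and true position.
The likelihood is Gaussian per (class, cell) — the natural family for
continuous ΔF/F — with a uniform class prior (near-constant traversal
speed) and a 10⁻⁴ ΔF/F² variance floor to keep silent cells from producing
degenerate likelihoods. Cells recorded in different sessions are pooled by
bin-aligned concatenation of their columns on the shared (lap, fine-bin)
grid; this is an interpretation of how per-animal data can share one
decoder, made explicit here. Chance level for independent uniform
positions on a 300 cm track is L/3 ≈ 100 cm, which label-shuffled training
reproduces.

## The synthetic generator

The generator exists so every stage above can be tested against known
ground truth; it emulates the paradigm, not the imaging physics. Behavior:
per-lap speeds are lognormal around 25 cm/s (CV 0.15), position advances
linearly within a lap, and the pause/teleport is instantaneous. Cells: each
field is a skew-normal spatial envelope (symmetric Gaussian at shape 0,
sd = width/4, location-shifted so its mean stays at the nominal center)
centered at `center + drift × (laps since onset)`, expressed with
probability `reliability` on each post-onset lap, scaled to the field
amplitude, and convolved with a GCaMP6f-like kernel (50 ms linear rise,
0.4 s exponential decay — durations at half peak then fall inside the
detector's accepted classes). The kernel is mean-centered in time at
convolution, so a symmetric envelope keeps its COM at the true center;
a causal kernel would drag every COM forward by roughly τ × speed ≈ 10 cm
and make center-recovery claims meaningless. Out-of-field transients are a
Poisson process of kernel-shaped events (the distributional form of
out-of-field firing is an assumption exposed as a rate knob), and Gaussian
noise is added last. One master seed derives per-cell child seeds, so
appending a cell never perturbs earlier ones.

Two presets fix the study conditions used throughout the validation:
an instant-rich phenotype (30% lap-1 onsets with a geometric tail, drift
−0.5 ± 0.1 cm/lap, across-day stable fraction 0.5, day-2 re-emergence
instant with probability 0.3) and a delayed phenotype (9% lap-1 onsets,
uniform remainder up to lap 18, drift −0.1 ± 0.05 cm/lap, stable fraction
0.8, re-emergence instant with probability 0.6). Shared settings — widths
40–80 cm, lognormal amplitudes around 0.8 ΔF/F, reliability 0.9,
out-of-field rate 0.01 Hz, noise σ 0.05 ΔF/F, 40-lap sessions (46 laps and
matched drift for the decoding contrast, where only the onset distribution
should differ) — were chosen once as realistic for GCaMP6f somatic imaging
at this field of view, with onset caps low enough that a 0.9-reliability
field can still satisfy the 15-lap occupancy criterion. Paired days reuse
day-1 centers for stable cells (fresh early onsets), redraw centers for
remapping cells, and silence silent ones; a stable cell's day-2 center is
its *initial* day-1 center, so after day-1 drift the day-2 field starts
back where it began — the offline "reset" signature.

What passing on this generator shows: the estimators are unbiased and
correctly calibrated on data whose ground truth obeys the model
(parameter recovery, type-I control, oracle equivalence), and the
pipeline's qualitative orderings track the generator's. What it does not
show: robustness to neuropil contamination, photon shot noise, motion
artifacts, speed-modulated firing, or segmentation errors — none of which
the generator produces.

## Problem sizes and other fixed choices

The validation suite runs noiseless recovery at 100 fields × 30 laps over
four drift values, null calibration at 200 cells/fields, oracle
equivalence on 250 randomized instances exercising seven estimators each,
preset phenomenology at 90 cells × 40 laps (70 × 40 × 2 days for
stability), and decoding at 220-cell populations with 20 repeats of
200-cell draws — sizes at which every Monte-Carlo margin in the suite is
comfortable on a single core. Sessions serialize to plain CSV matrices
with a JSON sidecar for configuration and ground truth, and configurations
round-trip through YAML. The run/simulate entry points are plain R
functions (`pf_run()`, `pf_simulate()`); the package is a library, not a
shell tool.

## Known limitations

Per-field bootstrap p-values are computed per candidate without multiplicity
correction across a cell's candidates (fields are "treated independently"
by design). The FPR grid is a documented approximation to transient-class
analysis whose exact historical class boundaries are not standardized. The
occupancy criterion and the reference lap are absolute lap counts, so very
short sessions need explicit reconfiguration. Spatial information metrics,
directional tuning, and recurrent-network models of remapping are out of
scope.
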