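# pfdyn: lap-by-lap place-field dynamics from calcium imaging

Hippocampal place cells fire in restricted regions of an environment, and
their fields are anything but static: during familiarization to a new linear
track, fields emerge on different laps ("instant" fields on the very first
traversal vs delayed ones), drift backward against the running direction
from lap to lap, change width and skewness, and either reinstate or remap
when the animal returns a day later. `pfdyn` implements the full analysis
chain needed to quantify these dynamics from two-photon GCaMP ΔF/F
recordings of head-fixed mice on virtual linear tracks — and a synthetic
session generator with known ground truth so that every stage can be
validated end to end.

The package is aimed at systems neuroscientists analyzing lap-structured
calcium-imaging data, and at anyone who wants a tested reference
implementation of the underlying estimators.

## The analysis chain

1. **Significant transients.** Traces are drift-corrected by subtracting a
   rolling 8th percentile (±5 s window); events start when ΔF/F exceeds
   2σ of the corrected baseline and end on return within 0.5σ. A grid of
   minimum-amplitude × minimum-duration classes is calibrated against
   negative-going (sign-flipped) events so that retained transients have a
   false-positive rate below 1%.
2. **Place fields.** Activity is averaged into a lap × 50-bin matrix
   (6 cm bins on a 300 cm track, running periods ≥ 0.2 cm/s only).
   Candidate fields are contiguous bins above 15% of the peak-to-baseline
   range (baseline = mean of the 12 lowest bins), must be 20–150 cm wide,
   exceed 0.1 ΔF/F, have an in/out activity ratio > 3 and in-field
   transients on ≥ 15 laps, and survive a bootstrap built from per-lap
   circular shifts (p < 0.05).
3. **Per-field metrics.** For each traversal *n*, the center of mass
   COM*ₙ* = Σᵢ DFᵢ·xᵢ / Σᵢ DFᵢ, the across-lap amplitude-weighted
   COM_w = Σₙ Aₙ·COMₙ / Σₙ Aₙ, spatial precision
   SP = 1/√(Σₙ Aₙ(COMₙ − COM_w)² / Σₙ Aₙ), the third standardized moment
   (skewness), the lap-wise field width, the out/in firing ratio, and the
   onset lap (first lap with in-field transients on ≥ 3 of the next 6 laps).
4. **Shifting dynamics.** Per-field OLS regression of COMₙ on lap number
   with an F-test; session shift from five-lap amplitude-weighted end vs
   onset windows; a lap-label shuffle null; the population shift curve
   (five-lap sliding COM relative to lap 12) with a pooled regression; and
   sample-size-matched resampled slope comparisons between populations.
5. **Stability & decoding.** Pearson correlations of 50-bin mean maps
   within session, across environments, and across days (stable if
   r > 0.5); onset laps of re-emerging vs newly formed day-2 fields; and a
   Gaussian naive-Bayes position decoder on a 100-bin grid (trained on
   laps 6–35, validated on 36–40, scored on the first lap).

## Worked example

```r
library(pfdyn)

s <- simulate_preset("ca1_day1", n_cells = 8, n_laps = 30, seed = 80)
ana <- pf_analyze(s, seed = 81)
summary(ana)
#> 8 cells, 8 place cells with 8 significant fields
#>   instant (lap-1 onset) fraction: 0.12; median onset lap: 3.5
#>   mean width: 65.2 cm; mean session shift: -0.484 cm/lap
#>   significantly shifting: 100% (backward 8, forward 0)

curve <- analysis_shift_curve(ana)
curve
#> pf_popcurve: 6 fields, slope -0.4345 cm/lap (p = 4.95e-65), reference lap 12
```

The preset emulates an instant-rich population whose fields drift backward
at about −0.5 cm/lap: every field's COM regression here is significantly
backward, the mean session shift is −0.48 cm/lap, and the population curve
(five-lap sliding COM relative to lap 12) recovers the generating drift;
with only 8 cells the draw of onset laps is noisy (1 of 8 on lap 1), while
the 90-cell runs of the acceptance script recover the designed 30%
instant fraction.
`plot(ana)` shows the mean maps sorted by field position;
`plot(curve)` the population shift curve; `field_metrics(ana)` returns the
long per-lap table (COM, peak, skewness, width) behind them.

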