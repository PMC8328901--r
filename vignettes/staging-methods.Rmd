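---
title: "Markerless staging of facial palsy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless staging of facial palsy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceshift)
```

## The problem and the measurement model

Unilateral peripheral facial palsy (UPFP) weakens one hemiface. Clinical
scales such as House-Brackmann (HB) grade the weakness ordinally but
subjectively. `faceshift` implements an objective alternative: a short
frontal video of the patient performing a fixed protocol — stay still, frown
the forehead, return to rest, smile — is reduced to 68 facial landmark
trajectories by a pretrained detector (pluggable; the package never trains
one), and the palsy is staged from the *kinematics* of two scored movements.

For each hemiface the package tracks two axis-projected feature distances,
in the plane in which each movement actually unfolds:

* **forehead**: the vertical gap between the eyebrow point (ids 20/25) and
  the upper-eyelid point (38/45), which grows when the forehead frowns in
  astonishment;
* **mouth**: the horizontal gap between the mouth corner (49/55) and the
  mouth centre (63), which grows when smiling.

Projected rather than Euclidean distances are the default (a switch exposes
the Euclidean variant) so that, e.g., a purely horizontal tremor of the
eyebrow cannot masquerade as frowning. Pixel measurements become
millimetres through a single scale factor `t = f[mm] / f[px]` obtained from
any reference of known physical size (historically a 5 mm punched marker;
`scale_from_marker()`, `scale_from_reference()`, or an explicit `--scale`).

The per-side **shift** of a movement is

> shift = max(distance over the movement window) − mean(distance at rest),

so a flaccid side can legitimately score zero or slightly negative. For a
subject with a declared affected side the two sides combine into

* the **shift difference** SD = healthy shift − affected shift (mm,
  increases with severity), and
* the **asymmetry index** AI = affected shift / healthy shift
  (dimensionless, ≈ 1 in normals, → 0 with severity; the affected shift is
  clamped at zero before the ratio and a near-zero healthy shift leaves the
  ratio undefined rather than exploding).

Sides are labelled geometrically A/B; healthy versus affected is resolved
*only* from subject metadata, never guessed from the data. Totals sum the
two shift differences and average the two indices — the mean (rather than
the sum) keeps the total index on the same 0–1.2 scale as the partial
indices and as published normal ranges (0.99–1.2). The choice is
configurable and has no effect on cohort ANOVA statistics, which are
invariant under affine rescaling.

## Staging calibration

The packaged `default_grade_ranges()` table maps each of six features
(forehead/mouth/total SD and AI) to closed intervals per HB grade II–V,
taken from the Min/Max rows of a published 40-patient calibration cohort
(ten per grade). Two deliberate deviations from the accompanying prose:

* interval bounds come from the per-patient tables, because the prose
  ranges contain internal inconsistencies (e.g. a frontal-AI grade-IV range
  incompatible with every grade-IV patient value);
* the forehead-SD grade-II lower bound is extended from 0.40 to 0.39 mm so
  that every calibration patient lies inside their own grade's interval.

Total-AI intervals are not published; they are derived as per-grade extrema
of the per-patient means of the two partial indices. Interval monotonicity
(SD increasing, AI decreasing with grade, no overlap) is asserted whenever
a table is loaded, including user-supplied recalibrations (`--ranges`).

`assign_grade()` classifies a value as *in-range*, *nearest-range* (in the
gap between adjacent grades; the nearer boundary wins and ties go to the
more severe grade — clinically conservative, with a `refuse` mode that
reports `unclassifiable` instead), or *out-of-range* (milder than grade II
reports `better-than-II`; beyond the grade-V extreme reports V). Grades I
and VI are outside the calibrated cohort and are never extrapolated.
`grade_patient()` grades all six features; the combined grade follows the
total shift difference when measurements are in mm, else the (scale-free)
total asymmetry index, and the rationale text records every per-feature
grade and any disagreement. Applied back to the 200 printed calibration
values, the packaged table reproduces each patient's clinical grade for all
six features (the acceptance script recomputes this concordance).

## Window detection

The calibration protocol implies manual frame selection; the package
therefore treats explicit window annotations (JSON, 0-based half-open frame
intervals) as authoritative and auto-detection as a convenience:

* **rest** is the maximal initial interval in which all four series stay
  within `k = 3` MADs of their initial-second median. MAD here is the
  sigma-consistent estimator (`stats::mad`, constant 1.4826); with the raw
  median absolute deviation the band is ≈ 2 sigma and baseline jitter ends
  rest spuriously. An excursion must persist for 3 consecutive frames to
  terminate rest, so an isolated spike cannot truncate the baseline. The
  MAD is floored at a relative 1e-6 so noise-free recordings do not produce
  a zero-width band. Rest shorter than 0.5 s is an error, not a warning.
* **movements** are 1 s windows centred on the post-rest global maximum of
  the healthy side's forehead (frown) and mouth (smile) series, and the
  protocol order — frown before smile — is enforced.

Only the initial pre-movement segment forms the baseline by default;
returns-to-rest between movements are excluded to avoid carry-over.
Excursion uses the true maximum (the calibration was built on maxima); a
95th-percentile robust mode exists for noisy detectors but is off by
default, as is an optional 3-frame moving-median smoother — both documented
deviations from the reference procedure.

## The simulator

`simulate_track()` generates what the pipeline consumes, with ground truth:
a bilaterally symmetric schematic 68-point face on a 640 × 480 canvas
performs the protocol at 30 fps for 18 s (inside the protocol's 15–20 s),
3 s of initial rest, with raised-cosine activations (1 s rise, 0.5 s
plateau, 1 s fall) so the true maximum is attained exactly on a plateau.
The affected side executes the same movement scaled by the target AI —
amplitude attenuation only; latency and synkinesis are out of scope.
Detector jitter is additive Gaussian noise per coordinate in pixel space,
before calibration (default 0.3 px, a plausible landmark-regressor
uncertainty at this resolution). Healthy amplitude defaults, 12 mm frown
and 10 mm smile, sit at the upper end of the calibrated severe-grade shift
ranges, as expected of an intact hemiface. All randomness flows through a
mandatory seed and the generator restores the caller's RNG state, so
identical parameters give byte-identical trajectory files.

`simulate_cohort()` plants graded subjects: per grade it draws partial AIs
uniformly inside the calibrated AI intervals and partial SDs inside the SD
intervals, rejects joint draws whose total SD leaves the total interval,
and back-solves the healthy amplitude as SD / (1 − AI), capped at 30 mm.

What the simulator does *not* emulate — head motion, perspective, detector
bias and dropouts, synkinetic co-movement, expression variability — bounds
what passing tests show: they validate the measurement chain and the
staging arithmetic, not detector robustness on real video.

## Numerical choices and problem sizes

* Display rounding is half-away-from-zero at 2 decimals (matching the
  calibration tables' convention), with a 1e-9 nudge compensating binary
  representation of decimal halves; raw values are always retained.
* `one_way_anova()` delegates the decomposition to `stats::lm()`/`anova()`
  and reports eta-squared (SS_between/SS_total) as R². Degenerate inputs
  resolve by convention: all-identical data give F = 0 with a note;
  zero within-group variance with unequal means gives F = Inf.
* Of the 80 published summary cells, 62 are reproduced exactly by
  recomputation from the per-patient values; the other 18 differ by one
  unit in the last printed digit (several are exact .xx5 halves) and are
  treated as printed-value discrepancies, as is the published smiling-
  movement F statistic, which is not recoverable from the printed
  per-patient values by a standard one-way ANOVA.
* Test and acceptance workloads are sized for a laptop-class single core:
  10 subjects per grade per cohort, 10 cohort replicates plus 100
  single-track runs for the stochastic checks (~400 full pipeline runs,
  a few seconds in total).

## Known limitations

* The staging intervals are calibrated on 40 patients from a single centre;
  `--ranges` accepts recalibrated tables but the package ships only this one.
* Eye-closure movements are deliberately not analysed (no stable asymmetry
  index across severities); the lower-eyelid points remain in the data
  model only for completeness.
* Without a scale calibration, shift differences are reported in pixels and
  flagged non-comparable to the millimetre-calibrated intervals; staging
  then rests on the asymmetry indices alone.
* Auto-detected windows can fail on atypical recordings (no still baseline,
  movements out of protocol order); annotations always take precedence.
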