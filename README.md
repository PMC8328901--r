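# faceshift

Objective, markerless staging of **unilateral peripheral facial palsy
(UPFP)** from 68-point facial-landmark trajectories.

Clinicians grade facial palsy with ordinal scales (House-Brackmann, HB)
that are quick but subjective. `faceshift` implements a video-based
alternative for clinicians and facial-kinematics researchers: a short
frontal recording of a fixed protocol — rest, forehead frown, rest, smile —
is reduced by any pretrained 68-point landmark detector to per-frame
coordinates, and the palsy grade is computed from the movement kinematics
of the two hemifaces.

## The method

For each side *s* and movement, the package measures an axis-projected
feature distance per frame — forehead: |y(eyebrow) − y(upper eyelid)|,
mouth: |x(mouth corner) − x(mouth centre)| — converted to millimetres by a
scale factor *t* = *f*[mm]/*f*[px] from any reference of known size. The
per-side movement **shift** subtracts the rest baseline:

```
shift_s = max( d_s(t), t in movement window ) − mean( d_s(t), t in rest window )
```

With the affected side declared in metadata, each movement yields

* **shift difference** `SD = shift_healthy − shift_affected` (mm; grows
  with severity), and
* **asymmetry index** `AI = shift_affected / shift_healthy` (≈ 1 in
  normals, → 0 with severity),

plus totals (summed SDs, averaged AIs). Six features (forehead/mouth/total
× SD/AI) are mapped to HB grades II–V through calibrated, non-overlapping
per-grade intervals packaged with the package (`default_grade_ranges()`),
derived from a 40-patient calibration cohort (ten per grade) whose
per-patient values ship in `calibration_cohort()`. Cohort statistics
(per-grade mean/max/min/SD and one-way ANOVA with eta-squared) reproduce
the published calibration tables.

## Worked example

Simulate a moderate (grade III) palsy with detector jitter and run the full
pipeline — in practice `read_track_csv()` or the `detect_landmarks()`
adapter replaces the simulator:

```r
library(faceshift)

p <- simulation_params(frown_amp = 10, frown_ai = 0.6, smile_amp = 9,
                       smile_ai = 0.65, noise_sd_px = 0.3, seed = 42)
sim <- simulate_track(p, subject_id = "demo-01")

report <- analyze_track(sim$track, scale = scale_calibration(0.5))
print(report)
#> <palsy_report> subject demo-01
#> <asymmetry_result> affected side A (unit mm)
#>  expression  feature healthy_shift affected_shift shift_difference
#>       FROWN FOREHEAD     10.367008       6.457603         3.909405
#>       SMILE    MOUTH      9.427465       6.235967         3.191498
#>  asymmetry_index
#>        0.6228994
#>        0.6614680
#> total shift difference: 7.101 mm; total asymmetry index: 0.642
#> <grade_assignment> combined HB grade: III (from TOTAL_SD)
#>      feature     value grade   status
#>  FOREHEAD_SD 3.9094048   III in-range
#>     MOUTH_SD 3.1914983   III in-range
#>     TOTAL_SD 7.1009031   III in-range
#>  FOREHEAD_AI 0.6228994   III in-range
#>     MOUTH_AI 0.6614680   III in-range
#>     TOTAL_AI 0.6421837   III in-range
```

The healthy side frowned 10.4 mm and the affected side 6.5 mm, so the
forehead shift difference is 3.9 mm and its asymmetry index 0.62 — close to
the simulator's planted targets (amplitude 10 mm, AI 0.6; the small excess
is the expected maximum-statistic bias under jitter). All six features fall
inside the grade-III calibration intervals, so the combined grade is III
with no disagreement.

A shell interface wraps the same functions
(`system.file("cli", "faceshift", package = "faceshift")`):

```sh
faceshift simulate --seed 1 --frown-ai 0.5 --smile-ai 0.5 -o track.csv
faceshift analyze track.csv --affected-side A --scale 0.5 -o report.json
faceshift cohort inst/extdata/cohort_printed.csv -o stats/
faceshift ranges show
```

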