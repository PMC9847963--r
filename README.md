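# iadct

Measurement and validation tooling for the **inter-arytenoid distance
(IAD)** on 4D dynamic laryngeal CT.

The IAD — the minimum distance between the two arytenoid cartilages — is a
quantitative marker of laryngeal adduction during phonation, of interest
e.g. in Parkinson's disease, where group differences of under 1 mm matter.
It can be measured manually (an observer places one fiducial marker per
cartilage; **IAD_M** is the anisotropically scaled 3-D Euclidean distance
between the markers) or automatically (a detector draws bounding boxes
around each cartilage on every axial slice; **IAD_A** is the minimum
facing-edge x gap over the stack, and **IAD_S** is that gap on exactly the
slice the observer chose). Validating the automated route against the
manual one is a repeated-measures method-comparison problem.

`iadct` provides:

* **Geometry** — `iad_manual()`, `iad_auto()`, `iad_same_slice()` and
  `pair_timepoints()` turn annotation tables on an anisotropic voxel grid
  (default 512 × 512 px, 0.222 × 0.222 × 0.5 mm³ voxels) into millimetre
  IAD estimates with explicit missing-data semantics.
* **Agreement statistics** — a modified Bland–Altman analysis for
  repeated measures. Paired differences `d_ij = IAD_M − IAD_auto` follow a
  one-way random-intercept model

  ```
  d_ij = μ + b_i + e_ij,   b_i ~ N(0, σ_b²),  e_ij ~ N(0, σ_w²)
  ```

  fit by REML (in-package, cross-checked against `lme4` and a
  method-of-moments oracle in the tests). The bias is μ, the total SD is
  √(σ_b² + σ_w²), and the 95% limits of agreement are
  μ ± 1.96·√(σ_b² + σ_w²). `mixed_regression()` adds the per-participant
  random-slopes regression of IAD_M on the automated estimate.
* **Synthetic cohorts** — `simulation_config()` / `generate_dataset()`
  emit fully synthetic detector and observer annotation tables (no imaging
  data involved) with configurable phonation kinematics, marking and
  slice-selection bias components, noise, rest-phase artifacts and
  detector-miss rates, plus a truth table for recovery studies.
* **Pipeline** — `pipeline_simulate()` → `pipeline_measure()` →
  `pipeline_agree()` → `pipeline_report()` over documented CSV/JSON files,
  with seeds and config hashes embedded in every output; `exec/iadct` is a
  thin command-line wrapper (verbs `simulate`, `measure`, `agree`,
  `report`).

## Worked example

Simulate a default 12-participant cohort (5 s at 100 ms, five phonations),
measure all three IAD estimates, and run both agreement comparisons:

```r
library(iadct)

cfg <- simulation_config(seed = 42)
ds <- generate_dataset(cfg)
measurements <- pair_timepoints(ds$boxes, ds$fiducials)
measurements[1:3, ]
#> # A tibble: 3 × 7
#>   participant_id timepoint_ms iad_m_mm iad_a_mm iad_s_mm s_excluded argmin_slice
#>   <chr>                 <int>    <dbl>    <dbl>    <dbl> <lgl>             <int>
#> 1 P01                       0    13.8      10.7     12.4 FALSE                10
#> 2 P01                     100    12.4      10.2     10.2 FALSE                10
#> 3 P01                     200     9.77     10.2     12.0 FALSE                10

agreement_report(measurements, comparison = "A")
#> Bland-Altman comparison (IAD_A vs IAD_M), repeated measures
#>   Number of paired measurements      600
#>   Mean bias (mm)                     1.69
#>   95% limits of agreement (mm)       -1.9 to 5.3
#>   Within participant SD (mm)         1.63
#>   Between participant SD (mm)        0.82
#>   Total SD (mm)                      1.8

agreement_report(measurements, comparison = "S")
#> Bland-Altman comparison (IAD_S vs IAD_M), repeated measures
#>   Number of paired measurements      551
#>   Mean bias (mm)                     0.65
#>   95% limits of agreement (mm)       -2.3 to 3.6
#>   Within participant SD (mm)         1.29
#>   Between participant SD (mm)        0.77
#>   Total SD (mm)                      1.5
#>   (49 rows without IAD_S dropped)
```

Reading the output: the automated minimum-over-slices estimate reads on
average 1.69 mm *below* the manual one on this cohort (the configured
truth is 0.52 mm of within-slice marking bias plus 1.0 mm of
slice-selection bias, plus rest-phase artifacts; single-cohort estimates
scatter around that truth with SE ≈ σ_b/√12). Restricting the comparison
to the manually chosen slice (IAD_S) removes the slice-selection
component: the bias drops to 0.65 mm and the limits of agreement narrow.
49 timepoints lose their IAD_S because the simulated detector missed the
observer's slice, mirroring how same-slice comparisons shed data in
practice.

The single-participant random effects, regression view, and plots:

```r
mixed_regression(measurements, "A")
#> Mixed regression IAD_M ~ IAD_A (n = 600)
#>   fixed slope     0.813
#>   fixed intercept 3.038
#>   random effects  intercepts (fallback)

plot_bland_altman(measurements, "A")    # needs ggplot2
```

The same workflow from the shell:

```sh
exec/iadct simulate --out-dir run1 --seed 42
exec/iadct measure  --out-dir run1
exec/iadct agree    --out-dir run1
exec/iadct report   --out-dir run1 --plots
```

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end: it
generates a cohort under the given seed, measures IAD_M / IAD_A / IAD_S,
fits the repeated-measures agreement models for both comparisons, and
writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Path | Contents |
|---|---|
| `R/geometry.R`, `R/annotations.R`, `R/measure.R` | voxel geometry, annotation containers, IAD estimators |
| `R/agreement.R`, `R/regression.R` | variance components, limits of agreement, mixed regression |
| `R/simulate.R` | synthetic cohort generator |
| `R/pipeline.R`, `R/io.R`, `exec/iadct` | pipeline verbs, CSV/JSON interchange, CLI |
| `vignettes/iad-agreement.Rmd` | methods: model, conventions, generator design, limitations |
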