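---
title: "Measuring and validating the inter-arytenoid distance on 4D laryngeal CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and validating the inter-arytenoid distance on 4D laryngeal CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

The inter-arytenoid distance (IAD) — the minimum distance between the two
arytenoid cartilages — is a quantitative marker of laryngeal adduction that
can be read off dynamic (4D) CT of the larynx during phonation. Two
measurement routes exist:

* **Manual (IAD_M)**: an observer scrolls through the axial image stack,
  places one fiducial marker on the most medial aspect of each arytenoid
  cartilage, and the IAD is the Euclidean distance between the paired
  markers. On an anisotropic voxel grid (0.222 × 0.222 mm in plane, 0.5 mm
  between slices by default) each axis must be scaled by its own spacing.
* **Automated (IAD_A)**: a detector places bounding boxes around each
  cartilage on every axial slice where it can find them; per slice, the
  IAD estimate is the x-axis distance between the facing box edges, and
  IAD_A is the *minimum* of those per-slice gaps over the whole stack.
* **Same-slice automated (IAD_S)**: the automated gap evaluated on exactly
  the slice the manual observer chose. Comparing IAD_S (rather than IAD_A)
  with IAD_M removes the bias component due to the two routes choosing
  different slices, isolating within-slice marking differences.

`iadct` implements the geometry of all three estimates, the
repeated-measures agreement statistics used to compare them, and a
synthetic annotation generator so the full pipeline can be validated
without any imaging data.

## Geometric conventions

Pixel coordinates are 0-based and boxes use the half-open convention
`[min, max)`, so a box's pixel width is exactly `x_max - x_min`; this
avoids off-by-one ambiguity in gap computations. Decisions that the
measurement definitions leave open are resolved as follows:

* **Contact clamps to zero.** If the two boxes touch or overlap in x
  (possible under arytenoid hyperadduction, where a vocal fold can cross
  beneath its partner), the gap is 0 mm: a distance cannot be negative,
  and overlap means contact.
* **Side relabeling.** Before a gap is computed, the box with the smaller
  x centroid is treated as "left". The measurement is therefore robust to
  whether the annotation source labels sides anatomically or by image
  orientation.
* **Argmin ties break low.** When several slices share the minimal gap,
  the lowest slice index is reported, so reruns are reproducible.
* **Edge-to-edge gaps.** The automated distance uses the facing box edges
  in x. The box interior carries no landmark information, so this is the
  only definition the annotation supports.
* **Missing vs erroneous.** A detector miss on the manually chosen slice
  is a *data state*: IAD_S is recorded as missing and flagged
  `s_excluded`, mirroring how same-slice comparisons lose data points in
  practice (e.g. 515 usable same-slice pairs out of 560). A slice index
  outside the annotated stack, by contrast, is a validation *error*.
* IAD_M is computed as a full 3-D distance even though markers usually
  share a slice; with `dz = 0` it reduces to the in-plane distance.

All distances are converted to millimetres exactly once, at computation;
reporting layers round bias and SDs to 2 decimals and limits of agreement
to 1, matching conventional reporting precision.

## The agreement model

Repeated measures violate the independence assumption of the classic
Bland–Altman method: each participant contributes dozens of paired
timepoints, and their differences share a participant-level component. The
package therefore fits the one-way random-intercept model to the paired
differences \(d_{ij} = \mathrm{IAD}_{M,ij} - \mathrm{IAD}_{A,ij}\) (or
\(-\mathrm{IAD}_{S,ij}\)):

\[
d_{ij} = \mu + b_i + e_{ij}, \qquad
b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_w^2),
\]

with \(i\) indexing participants. The mean bias is \(\mu\); the total SD is
\(\sqrt{\sigma_b^2 + \sigma_w^2}\); and the 95% limits of agreement are
\(\mu \pm 1.96\sqrt{\sigma_b^2+\sigma_w^2}\). The sign convention
\(d = \mathrm{IAD}_M - \mathrm{IAD}_{\mathrm{auto}}\) makes the bias
positive when the automated route reads lower than the manual one.

```{r}
library(iadct)
d <- simulate_differences(12, 47, mu = 1.52, sigma_b = 0.73,
                          sigma_w = 1.45, seed = 1)
vc <- fit_variance_components(d)        # REML
limits_of_agreement(vc)                 # bias +/- 1.96 * total SD
```

Numerical choices:

* **Estimator.** The default is REML, maximized on the log-variance scale
  with `nlminb`, multi-started from the ANOVA (method-of-moments)
  estimate, convergence tolerance `1e-8` on the restricted log-likelihood.
  The `sigma_b = 0` boundary is always evaluated explicitly (its profiled
  REML residual has the closed form \((SS_W + SS_B)/(N-1)\)), and negative
  components are never returned: estimates are truncated at zero and the
  truncation is flagged and warned about. `method = "moments"` exposes the
  ANOVA-type estimator with the unbalanced-design correction
  \(\hat\sigma_b^2 = (MSB - MSW)/c_0\),
  \(c_0 = (N - \sum_i n_i^2/N)/(k-1)\), as an independent cross-check; on
  balanced designs with interior optima the two coincide (a property the
  test suite asserts at `1e-6`, and cross-checks against `lme4`).
* **LoA multiplier.** Fixed at the normal quantile 1.96 with no
  small-sample t correction: reference Table-1-style arithmetic
  (e.g. \(1.52 + 1.96 \times \sqrt{1.45^2 + 0.73^2} \approx 4.70\)) is
  reproducible only under 1.96. The multiplier is a visible argument, not
  a constant buried in code.
* **Degenerate data.** All-identical differences yield
  \(\sigma_b = \sigma_w = 0\) with a classed warning; a single participant
  is an identifiability error (between-participant variance cannot be
  estimated), surfaced as `iadct_identifiability_error`.
* **Not modeled.** Successive 100 ms timepoints are autocorrelated in real
  acquisitions; the two-component model ignores this, in line with
  standard practice for this design. Estimated SDs therefore absorb the
  serial correlation into \(\sigma_w\); bias is unaffected.

The regression view (`mixed_regression()`) fits
`IAD_M ~ IAD_A` with per-participant random slopes and intercepts via
`lme4`. On non-convergence it falls back to random intercepts only, and
from there to an ordinary least-squares line; the level used is recorded
in the returned object (`model`, `fallback`), never silently.

## The synthetic cohort generator

No imaging data ships with (or is consumed by) the package: the generator
emits the *annotation* tables a detector and a manual observer would
produce, with the statistical structure the agreement analysis assumes.
Defaults describe a 12-participant cohort scanned for 5 s at 100 ms
intervals (≤ 600 timepoints, the scale of a typical validation study)
producing five phonations.

**Trajectory.** The true IAD alternates between a rest baseline
(`rest_iad_mm`, default 10 mm, arytenoids abducted) and phonation troughs
(`phonation_iad_mm`, default 4.7 mm, midway between reported
patient/control group means of 4.24 and 5.21 mm) as a train of
raised-cosine adduction pulses — one per phonation, smooth,
parameter-light, and covering the realistic IAD range from a few mm to
above 10 mm. No published kinematic model exists for this trajectory; the
pulse train is a stated modelling choice, not an inference. Timepoints
with adduction depth ≥ 0.5 are labeled `phonation` (the central half of
each pulse segment), the rest `rest`. A participant-level offset
(`participant_sd_mm`, default 1 mm) represents anatomical size variation.

**Difference structure.** The manual-vs-automated difference is built from
mechanistically distinct parts:

* a **within-slice marking bias** (`marking_bias_mm`, default 0.52 mm):
  the manual observer systematically marks slightly wider than the
  detector's box edge;
* a **slice-selection bias** (`slice_selection_bias_mm`, default 1.0 mm):
  the observer does not always pick the slice where the cartilages are
  truly closest. Mechanism: per-slice gaps follow a convex through-slice
  profile `true + curvature * (z - z*)^2` (curvature 0.4 mm/slice²); the
  manual slice is displaced by δ slices, where δ ∈ {−m, 0, +m} with
  P(±m) calibrated so that E[curvature · δ²] equals the configured bias
  *exactly* (m = ⌈√(bias/curvature)⌉). This reproduces the ordering
  IAD_M ≥ IAD_S ≥ IAD_A by construction rather than by decree;
* a **participant-level difference offset** (`between_bias_sd_mm`, default
  0.73 mm), the generator's \(\sigma_b\);
* **within-timepoint noise** (`within_noise_sd_mm`, default 0.8 mm,
  roughly a 3–4 pixel marking jitter), drawn independently for the manual
  marking and for the automated gap profile;
* **rest-phase artifacts** (`artifact_rate`, default 0.05): with the
  configured probability, and only during vocal rest (where automated
  outliers are observed in practice), one random slice's gap collapses to
  `artifact_magnitude_mm` below the stack minimum, so the
  minimum-over-slices IAD_A severely underestimates. Collapsing *relative
  to the minimum* is deliberate: reducing an arbitrary slice by a fixed
  amount would often leave the minimum — and hence IAD_A — untouched;
* **detector misses** (`exclusion_rate`, default 0.08, matching a
  45-in-560 missing fraction): the box pair on the manually chosen slice
  is dropped, which downstream turns into an excluded IAD_S.

Voxel quantization is applied last — marker and box-edge coordinates are
snapped to integer pixels — so a ≤ 1-pixel (0.222 mm) error floor is part
of every generated measurement, as it is in real annotations.

**Determinism.** Every participant draws from substreams derived from the
master seed, so cohorts are reproducible under participant-count changes,
and identical configurations give byte-identical output files.

**What a green test establishes — and what it does not.** The generator
matches the analysis model's *assumed* structure (normal components,
no serial correlation, symmetric slice-offset distribution, a
deliberately calibrated three-point δ). Recovery of the generating
parameters therefore validates the estimator and the pipeline plumbing,
not the model's adequacy for real laryngeal CT, where slice-selection
error is plausibly asymmetric, marking noise is heavier-tailed, and
successive timepoints are strongly autocorrelated. Equally, the published
headline numbers for the real cohort cannot be reproduced here — no
imaging data is deposited — so the test suite checks internal consistency
of that arithmetic and parameter recovery on synthetic cohorts instead.

## Pipeline and provenance

`pipeline_simulate()`, `pipeline_measure()`, `pipeline_agree()` and
`pipeline_report()` (also exposed by the `exec/iadct` Rscript) run the
workflow over documented CSV/JSON files in one directory:

```{r}
dir <- tempfile()
pipeline_simulate(NULL, dir, seed = 7)   # boxes.csv, fiducials.csv, truth.csv
pipeline_measure(NULL, dir)              # measurements.csv
pipeline_agree(NULL, dir)                # agreement_report.json, ba_points.csv
pipeline_report(NULL, dir)               # report.md (+ plots on request)
```

Every analysis output embeds the seed and a hash of the resolved
simulation configuration, so a report can always be traced to the dataset
that produced it. Configuration merges three layers with increasing
precedence: package defaults, a JSON config file, explicit overrides.
Classed conditions separate user-input problems
(`iadct_validation_error`) from statistical identifiability failures
(`iadct_identifiability_error`); the command-line wrapper maps them to
exit codes 2 and 3.

## Known limitations

* The agreement model ignores serial correlation between 100 ms
  timepoints (see above); fitted \(\sigma_w\) is an effective, not a
  purely independent-error, quantity.
* Finite-sample note: duplicating a dataset changes \(\hat\sigma_w\) by
  O(1/N) (REML denominators), so "pooling invariance" holds only
  approximately at realistic sizes.
* The generator does not rasterize annotations into image volumes, does
  not simulate CT physics or detector confidence, and does not model
  disease-group differences in trajectory shape; group contrasts should
  be injected through the configurable means if needed.
* Vertical (z-axis) motion metrics and rotational arytenoid kinematics
  are out of scope: the IAD captures sliding adduction only.
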