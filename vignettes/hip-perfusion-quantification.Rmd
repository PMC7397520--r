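---
title: "Quantifying femoral-head perfusion from SPECT/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying femoral-head perfusion from SPECT/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipspect)
```

## The measurement model

Bone SPECT/CT yields a 3-D photon-count volume whose voxel values are
proportional to local tracer uptake, co-registered with CT anatomy. The
absolute scale of the counts depends on the injected activity, the
injection-to-scan interval and the patient's renal and hepatic clearance,
so the perfusion of a femoral head is quantified *relative to a reference
site in the same scan*:

* **head-to-head ratio**: mean ROI uptake of the affected head divided by
  that of the contralateral head — usable only when the contralateral hip
  is healthy;
* **head-to-acetabulum ratio**: affected-head uptake divided by the
  ipsilateral acetabular dome's — the substitute reference when the
  contralateral hip carries an implant, its own osteonecrosis, or
  osteoarthritis.

Both ratios are invariant under global rescaling of the count volume,
which is the property the relative method exists for; the test suite
checks it explicitly.

### ROI protocol

Mean uptake is measured in a spherical ROI of fixed physical diameter:
30 mm at the femoral head (centered on the head, maximizing cancellous
content), 10 mm at the acetabular dome (the dome is aspherical and hemmed
in by pelvic cortex, so only a small sphere fits every pelvis). Voxels
labeled cortical bone are excluded from all samples — cortical uptake
reflects the shell, not the perfusion of the cancellous interior being
assessed.

The protocol averages "on the coronal, axial, and sagittal planes". We
interpret this as: take the ROI's central cross-sectional disc in each of
the three orthogonal planes — the single voxel slice whose center is
nearest the ROI center along the plane's fixed axis — average the
non-excluded voxels whose centers fall inside the disc, and average the
three plane means into the combined value. The alternative reading (a
full 3-D sphere mean) is implemented as `mode = "sphere"` in
`roi_mean_uptake()`; the mode used is recorded in the result's metadata so
the two can never be conflated. On a homogeneous region the two modes
agree exactly; on heterogeneous data they differ, and the three-plane
average is the default because it mirrors the described workstation
procedure of three independently measured per-plane values.

Geometric conventions, applied identically everywhere:

* voxel membership is by voxel center: a voxel belongs to a disc or ball
  when its center lies within the radius, boundary included (closed
  ball); the only tolerance is a `1e-9` epsilon absorbing floating-point
  error in the squared-distance comparison;
* world coordinates are mm, axis order (x = left–right,
  y = anterior–posterior, z = inferior–superior), voxel `(i, j, k)`
  (1-based) centered at `(i−1, j−1, k−1) × spacing`;
* ROIs that extend past the volume edge are clipped to in-bounds voxels
  and the reduced voxel count is reported (dome ROIs near the pelvic edge
  may clip); an ROI entirely outside the volume is an error.

### Classification

A ratio at or below the cutoff predicts perfusion loss (`predicted_onfh`):
low uptake is the diseased direction. The tie at exactly the cutoff is
classified as predicted necrosis — the conservative choice for a screening
question where the costly error is a missed avascular head.

## Diagnostic evaluation

From a 2×2 table (`tp` = predicted loss and observed ONFH, `tn` =
predicted viable and union):

* sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
  `(tp+tn)/n`;
* likelihood ratios `LR+ = sens/(1−spec)` and `LR− = (1−sens)/spec`, with
  confidence intervals by the log method:
  `exp(log LR ± z·SE)`,
  `SE(log LR+) = sqrt(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn))`,
  `SE(log LR−) = sqrt(1/fn − 1/(tp+fn) + 1/tn − 1/(fp+tn))`.
  The normal critical value is `qnorm(1 − α/2)`, not a rounded 1.96.
  Degenerate cases are reported as such: perfect specificity gives an
  infinite LR+ with the CI omitted, perfect sensitivity gives LR− = 0
  with the CI omitted. An optional Haldane correction (+0.5 to every
  cell, CI computation only, flagged in the output) is available for
  zero-cell tables and off by default.
* A simulation in the test suite checks that the log-method LR+ interval
  has near-nominal conditional coverage (90–99% band around the nominal
  95%) at the study's n = 30 with its observed sensitivity and
  specificity, excluding tables where the LR+ or its CI is undefined.

### ROC, cutoff derivation, AUC comparison

ROC curves sweep the distinct score values as thresholds with the
lower-is-positive orientation (a case is test-positive when its ratio is
≤ the threshold); ties enter at a single threshold; the curve runs from
(0, 0) to (1, 1) and the AUC is the trapezoidal area, which equals the
Mann–Whitney pair-count AUC `(concordant + tied/2)/(n_pos·n_neg)` exactly
— the package computes both and the identity is a standing test.

The operating cutoff maximizes Youden's J = sensitivity + specificity − 1,
with ties broken toward higher specificity and then the lower threshold.
The *reported* cutoff is the midpoint between the optimal threshold's
score and the adjacent distinct score: any value between two adjacent
observed scores classifies identically, and the midpoint is the natural
representative (for groups fully separated around 0.5 it returns clean
values near 0.5 rather than an arbitrary observed ratio). The observed
threshold form is returned alongside.

AUCs of the two ratios are compared with DeLong's placement-value
(structural components) method: per-case placements `V10`/`V01` with ties
contributing ½ (midrank convention), sample covariance of the placements
between markers, `z = (AUC_a − AUC_b)/sqrt(var_a + var_b − 2cov)`,
two-sided normal p. The paired form is the default (both ratios exist for
every patient here); an unpaired form (covariance 0, separate outcome
vectors) is provided for partially overlapping cohorts, since a clinical
series may only measure the head-to-head ratio in patients with a
comparable contralateral hip. Identical score vectors short-circuit to
z = 0, p = 1; a zero variance of the difference with unequal AUCs is an
error rather than a silent division. The implementation is cross-checked
in the tests against `pROC`'s independent DeLong implementation, and its
single-curve variance against a 10,000-resample patient-level bootstrap.

## The synthetic cohort and phantom

No patient volumes ship with the package; a generator supplies inputs
with the statistical structure the analysis assumes.

### Cohort-level generator

`cohort_spec()`/`simulate_cohort()` draw per-patient "true" ratios from
truncated normal distributions, one per outcome group and ratio. Defaults
encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_onfh`, `n_union` | 6, 24 | the study cohort's outcome split |
| head-to-head, ONFH | mean 0.33, sd 0.0625, bounds [0.18, 0.45] | group mean 0.33 (95% CI 0.28–0.38); sd back-computed from the CI half-width as `half·√n/1.96` |
| head-to-head, union | mean 1.30, sd 0.675, bounds [0.55, 2.50] | group mean 1.30 (95% CI 1.03–1.57), same back-computation |
| head-to-acetabulum, ONFH | mean 0.22, sd 0.05, bounds [0.10, 0.40] | group mean 0.22 (CI 0.18–0.26); upper bound deliberately crosses the 0.3 cutoff — the observed operating point there was not perfectly sensitive |
| head-to-acetabulum, union | mean 0.93, sd 0.525, bounds [0.35, 2.20] | group mean 0.93 (CI 0.72–1.14); lower bound above 0.3, matching the observed perfect specificity |
| `fraction_incomparable_contralateral` | 0.2 | 6 of 30 patients lacked a comparable contralateral hip (implant : contralateral ONFH : osteoarthritis in a 4 : 1 : 1 mix) |

The head-to-head bounds sit on opposite sides of 0.5 because the observed
sample was perfectly separated at that cutoff (100%/100%); the generator
reproduces that separation rather than inventing overlap the data did not
show.

Two design points deserve emphasis. First, each distribution's `mean` is
the mean of the **truncated** distribution — the quantity a clinical table
reports — not the parent normal's location. Asymmetric truncation shifts a
truncated normal's mean (for the union group's parameters, a parent
location of 1.30 would yield a realized mean near 1.41), so the generator
solves for the parent location by `uniroot` such that the truncated mean
equals the stated group mean; the closed-form truncated mean is verified
against numerical integration in the tests. Second, the `sd` is kept on
the parent scale as the CI back-computation yields it; truncation
therefore shrinks the realized spread somewhat, which is accepted — the
acceptance-relevant quantities are the group means and the separation.

Draws use the inverse-CDF method (exact, no rejection loop), seeds are
mandatory and explicit — `simulate_cohort()` is a pure function of its
spec — and drawn ratios never leave the truncation bounds.

### Voxel phantom

`build_hip_phantom()` renders two femoral heads (cancellous core of
radius 22 mm inside a 3 mm cortical shell), two 10 mm-radius acetabular
domes, and uniform background on a configurable grid, default 96³ voxels
at isotropic 2.95 mm (the CT reconstruction interval; desk-scale rather
than the 512×512 acquisition matrix). Tissue rates default to the
cohort-level mean uptakes (66.3 affected / 201.3 unaffected cancellous,
319.1 acetabular), with a hot cortical shell (400) and low background
(20). Voxel class assignment is voxel-center-inside-analytic-sphere with
no partial-volume blending. `noise_model = "poisson"` draws each voxel
from a Poisson with its class rate; `"none"` returns the rates exactly,
which makes noiseless ROI means equal the configured rates *exactly* — the
anchor for the pipeline's cross-mode consistency check. In phantom mode
the pipeline sets each patient's affected-head and dome rates so the
rendered volume realizes that patient's drawn ratios, measures the ROIs on
the volume, and carries the measured ratios forward.

What the phantom does **not** emulate: gamma-camera acquisition, iterative
reconstruction, attenuation correction and metal artifacts (the reason
postoperative scans were unusable in practice), partial-volume effects,
anatomical asphericity of the dome, or spatially varying background.
Passing tests therefore demonstrate the correctness of the quantification
and statistics on idealized reconstructed data, not robustness to
reconstruction artifacts — on real scans the structure labels would come
from CT segmentation or an intensity threshold, both outside this
package's scope (no registration, segmentation or head detection; ROI
centers come from manifest landmarks, as the clinical centers were
human-placed).

## Problem sizes and numerical checks

The test suite runs entirely on generated data: phantoms at 64³ voxels
(the default 96³ is exercised by the examples), ROI oracles on ≤ 32³
fixtures by brute-force per-voxel enumeration with integer counts so
comparisons are exact, 500 random score fixtures (n ≤ 50, with ties) for
the AUC identity, 50 paired fixtures of n = 30 against a 10,000-resample
bootstrap for the DeLong variance, 200 seeded cohorts for group-mean
recovery, and 2,000 simulated tables for LR-CI coverage. These sizes give
stable Monte-Carlo behavior at interactive runtimes.

## Known limitations

* The three-plane averaging is an interpretation (single central
  cross-sections, not slabs); the full-sphere mode quantifies the
  difference on any given volume.
* Whether the study's headline head-to-head statistics included the six
  contralateral-incomparable patients is ambiguous; the generator keeps
  both ratios for every patient and `fraction_incomparable_contralateral`
  free, and the scoring layer reports both forced-ratio and
  reference-selected classifications.
* Group CIs use the normal approximation (z = 1.96), not a t quantile —
  consistent with the CI back-computation that sets the generator's sds;
  at n = 6 a t-based interval would be noticeably wider.
* Predictive values (PPV/NPV) and prevalence-adjusted metrics are out of
  scope, as are postoperative-scan analyses.
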