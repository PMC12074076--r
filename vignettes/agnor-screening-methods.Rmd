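---
title: "Methods: synthetic AgNOR smears, dot counting, and screening statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic AgNOR smears, dot counting, and screening statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnorscreen)
```

## Background

Argyrophilic nucleolar organizer regions (AgNORs) are silver-stained
protein complexes at ribosomal gene loci. In an exfoliative cytology smear
they appear as near-black dots inside the nucleus, and the mean number of
dots per nucleus tracks cell proliferation: control oral mucosa sits near
2.9 AgNORs/nucleus while squamous cell carcinoma smears sit near 4.1.
That separation makes the per-patient mean a candidate screening marker,
with a decision threshold ("cut-off") chosen on the ROC curve.

Validating an automated counter requires images where the true count of
every nucleus is known — which no stained smear can provide. This package
therefore builds the whole chain on synthetic data with exact ground
truth: a cohort generator reproducing the published group-level
statistics, a smear renderer with per-nucleus truth, a classical-operator
counter, and the downstream summary, diagnostic and agreement statistics.

## The cohort generator

Each of the four study arms (CG, EG, OPMDG, OSCCG) is parameterized by a
between-patient mean and SD of mean AgNORs/nucleus and by the probability
that a cell carries 1, 2, 3, 4 or 5+ NORs (`default_group_params()`;
printed percentages are renormalized to sum to 1 — the control row sums
to 100.2 as printed).

Two published summaries must be coupled: patient-level means and
cell-level class percentages. The generator does this with the fewest
extra assumptions:

* a latent patient mean $m_p \sim N(\mu_g, \sigma_g)$, truncated to
  $[1, 13]$ because recorded counts live on that scale;
* per-cell class probabilities exponentially tilted,
  $p_k(\theta) \propto p^0_k e^{\theta k}$, with $\theta$ solved
  (Brent root-finding, tolerance $10^{-12}$) so the patient's expected
  count equals $m_p$;
* cells in the 5+ class draw their count from $\{5,\dots,13\}$ with
  geometric decay (ratio 0.5), giving the 5+ class a mean of about 5.98.

The tilt can only realize expected counts strictly between 1 and the 5+
tail mean, so latent means outside $(1, 5.98)$ are clamped before the
root solve. At the reference parameters (means 2.89–4.08, SDs at most
1.03) the clamp fires with probability below 2% in the worst arm and is
immaterial to group-level recovery, which tests verify to within
$3\sigma_g/\sqrt{n}$.

The within-patient dispersion is not published; the tilted-categorical
coupling is this package's choice and should be read as a modeling
convention, not an estimate.

## The renderer

A scene is a list of elliptical nuclei (center, semi-axes, rotation) with
disk-shaped dots of a common radius (default 2.5 px). Gray levels default
to background 230, nucleus 150, dots 30 on the 8-bit scale — dark dots on
a mid-gray nucleus against a light background — with additive Gaussian
noise of SD 8. The ground-truth count of a nucleus is the number of
connected groups of its dots, where two dots connect when their disks
intersect: a fused pair counts once, matching the counting convention
that overlapping or fused dots are a single structure.

`simulate_scene()` lays nuclei on a jittered grid with spacing computed
from the largest nucleus, places well-separated dot groups (centre
separation $2r + 3$ px so disjoint groups stay disjoint after
rasterization, even under 8-connectivity), and optionally adds fused
pairs, overlapping companion nuclei and small background artifacts.
Overlapping nuclei and artifacts are rendered but never annotated,
mirroring the practice of not bounding-boxing overlapped cells; they are
flagged in the ground truth. Nucleus axes grow as $\sqrt{c/5}$ with the
target count $c$ so that up to 13 separated groups always fit.

Annotations use the LabelMe rectangle dialect (0-based inclusive pixel
corners); rendering is byte-identical under a fixed seed. One user seed
feeds a named-stream splitter (cohort, geometry, noise, per-slide), so
stages are independently reproducible.

## The quantifier

The reference study counted with a CNN; its architecture is out of scope
here, and the downstream statistics depend only on per-nucleus counts.
The package instead uses deterministic classical operators:

1. **Nucleus segmentation** — Otsu's threshold on the box crop (nucleus
   and dots are darker than background); the largest connected dark
   component is the nucleus mask.
2. **Quality control** — `no_nucleus_found` if the largest component is
   under 50 px; `overlapping_nuclei` if a second component reaches 50% of
   the largest; `touches_box_edge` if the mask covers at least 25% of the
   crop border. These ratios are numeric stand-ins for visual criteria
   and are exposed in `quantify_config()`.
3. **Dot counting** — a second Otsu threshold restricted to the nucleus
   pixels separates dots from nucleus body; components under 3 px are
   discarded as noise; remaining 8-connected components are counted
   (8-connectivity is what merges diagonally touching fused dots), capped
   at 13. Because Otsu always returns a split, a dot-free nucleus would
   have its noise split into a spurious "dot"; a contrast guard
   (`dot_contrast_min`, 40 gray levels between the dark and light sides)
   reports such nuclei as having zero dots instead.
4. **Exclusion** — any flag, or a zero count, excludes the nucleus with a
   named reason; an unstained nucleus is an inadequate cell, not a zero
   observation. Counted plus excluded always equals the number of boxes,
   and the missed fraction is reported to two decimals.

Thresholds are computed per crop, not globally, since illumination varies
across smears. On noise-free renders the counter reproduces ground truth
exactly; under the default noise the test suite requires at least 95%
agreement (observed: 100%).

## Summaries

The unit of analysis is the patient: per-patient mean AgNORs/nucleus and
class percentages (classes 1–4 exact, 5+ as count ≥ 5; they sum to 100),
then per group the mean and sample SD (n−1) of patient means — not pooled
cell-level SD — and the mean of patient percentages, with the
highest-frequency class marked (ties, never observed at the reference
parameters, go to the lower class). Because the 5+ bin truncates at 5,
the expected count implied by the percentages is a lower bound on the
true mean; at the reference parameters the control bound is 2.867 against
a mean of 2.89. CSV is the canonical output format (means to 2 decimals,
percentages to 1); the full 1–13 histogram is kept internally but only
the 5-bin report is written.

## Diagnostics

* Positivity direction is fixed: higher counts are more suspicious, so a
  patient tests positive when the mean is at or above the threshold.
* ROC thresholds are midpoints between consecutive distinct values plus
  ∓∞ sentinels, so (Se, Sp) endpoints (1,0) and (0,1) are always present.
* AUC uses the Mann–Whitney midrank estimator (ties count ½), which the
  tests verify equals both exhaustive pair enumeration and the
  trapezoidal area under the curve to $10^{-12}$.
* The optimal cut-off minimizes $(1-Se)^2 + (1-Sp)^2$, the point closest
  to perfect sensitivity and specificity; ties break to higher
  sensitivity, then lower threshold (the reference software's tie rule is
  undocumented, so this package fixes its own and states it). On
  degenerate curves the optimum can sit at a sentinel; 2×2 metrics are
  then computed at that sentinel, while the exported
  `confusion_metrics()` keeps its finite-cutoff contract.
* The reference analysis fit logistic models before reading off
  sensitivity and specificity; with a single monotone predictor the
  logistic fit is a monotone transform of the marker, so ROC and AUC are
  identical to direct thresholding, and the logistic step is therefore
  not implemented separately.
* Sample size uses the classical normal-approximation two-means formula
  with two-sided α; with Δ = 0.59, SDs 0.56/0.58, α = 0.05, power 0.80 it
  gives 15 per group, and 17 recruited at 10% drop-out.
* Under the Gaussian patient-mean model the AUC has the closed form
  $\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2}\big)$, about
  0.938 (CG vs OSCCG), 0.742 (CG vs EG) and 0.856 (OPMDG vs OSCCG) at the
  reference parameters — within printing precision of the published
  0.93 / 0.75 / 0.85. The acceptance script verifies the simulated
  recovery at 20,000 patients per arm, and estimates the sampling
  distribution of the CG-vs-OSCCG cut-point at the study's own arm sizes
  (15 vs 14) across 1,000 replicates; it concentrates around 3.5–3.6 and
  its central 80% easily brackets the published 3.69. With only 29
  patients the cut-point is a noisy statistic; a published value inside
  the replicate distribution is the appropriate check, not equality.

## Agreement

The human-vs-system comparison is between two specific raters whose
absolute counts must match, so the default ICC form is ICC(A,1): two-way
model, single measures, absolute agreement, computed from the mean
squares $MSR$, $MSC$, $MSE$ with $k = 2$ raters, with F-based confidence
intervals (McGraw–Wong). A consistency form ICC(C,1) is available by
option, and the form used is always reported. The 0.75 "good
reliability" boundary is applied inclusively. The unit of agreement
defaults to the individual nucleus (system count vs ground-truth count of
the same bounding-boxed cell); aggregating to patients first is a
caller-side choice. When agreement is exact the F interval degenerates
and is reported as the point value.

## What the synthetic testbed does and does not show

The generator reproduces the published group structure (means, SDs, class
mixes), the fused-dot and overlapping-nucleus phenomena, and annotation
practice. It does not emulate staining variability, debris and microbial
background, focus blur, non-monolayer regions or color — so a perfect
score on synthetic renders (and the resulting ICC of 1.0 in pipeline
runs) demonstrates correctness of the counting logic, not expected
performance on stained smears. Published agreement on real material
(ICC ≈ 0.9 overall, 0.57–0.78 within groups) should be read as the
real-world ceiling; reproducing it would require the study's raw paired
counts, which are not public.

## Problem sizes and numerical conventions

Default pipeline runs use 15 patients per group and 50 cells per patient,
the study's own design size; cohort-statistics checks use larger sizes
(up to 1,000 patients per group, 200 cells) where Monte Carlo bounds need
to be tight, and the Gaussian AUC recovery uses 20,000 patient means per
arm. Root-finding tolerances are $10^{-12}$; image determinism is exact
(integer images, seeded noise); all group comparisons use the sample SD.
Degenerate inputs (empty cells, one-class contrasts, constant rater
pairs, boxes outside the image) raise errors rather than returning
conventions.
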