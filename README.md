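# agnorscreen

Quantification of argyrophilic nucleolar organizer regions (AgNORs) in oral
exfoliative cytology smears, and the statistics needed to turn those counts
into a screening decision.

AgNORs are silver-stainable protein complexes at ribosomal gene loci that
appear as well-defined black dots inside the nucleus; their number per
nucleus rises with cell proliferation and is therefore a candidate marker
for oral squamous cell carcinoma (OSCC) screening. This package is for
researchers developing or validating automated AgNOR counting: it provides
a fully synthetic, ground-truth-controlled testbed for the complete
analysis chain —

1. **`synthetic cohorts`** — per-cell NOR counts for four study arms
   (control CG, tobacco/alcohol-exposed EG, potentially malignant disorder
   OPMDG, carcinoma OSCCG). Each patient draws a latent mean
   m_p ~ N(μ_g, σ_g) truncated to [1, 13]; per-cell counts come from the
   group's 1–5+ class distribution exponentially tilted
   (p_k ∝ p⁰_k e^{θk}, θ solved so E[count] = m_p), with the 5+ class
   spread over 5–13 with geometric decay.
2. **`synthetic smears`** — rendered grayscale smear images (elliptical
   nuclei, disk-shaped dots, Gaussian noise) with exact per-nucleus ground
   truth, including fused-dot and overlapping-nucleus cases, plus
   LabelMe-style rectangle annotations of every analyzable nucleus.
3. **`quantification`** — per-box nucleus segmentation (per-crop Otsu +
   largest component) and dot counting (second Otsu restricted to the
   nucleus, 8-connected components, minimum dot size), applying the
   classical counting convention: overlapping or fused dots count as a
   single structure; nuclei with no nucleus found, overlapping nuclei,
   edge-clipped masks or zero dots are excluded with a named reason.
4. **`summaries`** — per-patient mean AgNORs/nucleus and 1–4 / 5+ class
   percentages (the patient is the unit of analysis), and group tables
   (mean ± SD of patient means, mean class percentages, highest-frequency
   class).
5. **`diagnostics`** — ROC curves with the "value ≥ threshold ⇒ positive"
   convention, Mann–Whitney AUC (= trapezoidal area), the optimal cut-off
   as the ROC point minimizing (1−Se)² + (1−Sp)², 2×2 metrics
   (Se, Sp, PPV, NPV, accuracy), and the two-means sample-size formula
   n = ⌈(z_{1−α/2}+z_{1−β})²(σ₁²+σ₂²)/Δ²⌉.
6. **`agreement`** — human-vs-automated intraclass correlation ICC(A,1)
   (two-way, absolute agreement, single measures) with F-based confidence
   intervals; ≥ 0.75 is labeled good reliability.

## Worked example

```r
library(agnorscreen)

sample_size_two_means(0.59, 0.56, 0.58, alpha = 0.05, power = 0.80, dropout = 0.10)
#> Two-means sample size: delta 0.59, SDs 0.56/0.58, alpha 0.05, power 0.80
#>   15 participants per group (17 recruited at 10% drop-out)

run <- run_pipeline(default_run_config(n_per_group = 15, cells_per_patient = 50),
                    seed = 42, out_dir = "results")
print(run$groups)
#> Mean AgNORs/nucleus and cell-class percentages by group
#>  group  n   mean ± SD   %1    %2    %3   %4   %5+
#>     CG 15 2.71 ± 0.74 20.9 31.3*  21.9 15.9    10
#>     EG 15 3.70 ± 1.16 13.3  16.8  18.7 18.1 33.1*
#>  OPMDG 15 3.11 ± 0.96 18.8  18.8 28.8* 18.1  15.5
#>  OSCCG 15 3.93 ± 0.43  4.1  16.1  23.3 26.4   30*
#> * highest-frequency class

d <- run$diagnostics
round(d[d$reference == "CG" & d$case_group == "OSCCG",
        c("auc", "cutoff", "sens", "spec", "accuracy")], 3)
#>    auc cutoff  sens spec accuracy
#> 3 0.92   3.36 0.867  0.8    0.833

print(run$agreement)
#> ICC(A,1) two-way, absolute agreement, single measures
#>   ICC 1.000 (95% CI 1.000-1.000), n = 2875 units: good reliability
```

The group table shows the simulated cohort behaving like the reference
populations: control smears peak at 2 NORs/cell, carcinoma smears at 5+,
and group means rise from CG to OSCCG. The CG-vs-OSCCG contrast yields an
AUC near 0.93 (sampling noise at 15 patients/arm moves it by a few
hundredths) and a cut-off between about 3.4 and 3.8 AgNORs/nucleus. The
ICC of 1.0 reflects the clean synthetic renders, on which the classical
counting operators recover the ground truth exactly; on real smears
(staining variation, debris, focus) agreement is necessarily lower.

A command-line wrapper with subcommands (`run-all`, `simulate-cohort`,
`render`, `quantify`, `summarize`, `diagnose`, `agree`) is installed at
`system.file("cli/agnor-screen", package = "agnorscreen")`.

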