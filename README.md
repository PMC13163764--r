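# gastromorph

Quantitative annotation analysis and prognostic scoring for gastric biopsy
whole-slide images.

When a gastric biopsy slide is exhaustively annotated — every gland, every
focus of dysplasia, every patch of carcinoma outlined as a polygon — the
diagnosis stops being a qualitative impression and becomes arithmetic over
pixel counts. `gastromorph` implements that arithmetic end to end for
pathologists and computational-pathology engineers:

* **Quantification.** ASAP-style XML polygon annotations are rasterized to a
  per-pixel label mask (pixel-center, even-odd rule), cut into 256 × 256
  slices, and reduced to exact per-class pixel compositions. Slices with
  more than 10% unannotated area are excluded; pixel counts are conserved
  exactly through every stage.
* **Rule-based diagnosis.** A slide composition is mapped to one of four
  ICD-10 codes with the diagnostic precedence

  C16.9 (any invasive carcinoma) ≻ D00.2 (high-grade dysplasia, no
  invasion) ≻ D13.1 (low-grade dysplasia only) ≻ K29.7 (non-neoplastic),

  to a WHO histotype (with the Carneiro rule: ≥ 90% signet-ring cells →
  poorly cohesive carcinoma, signet-ring subtype), to a Lauren type, and to
  a tumor grade from the high-grade component fraction
  *f*<sub>HG</sub> = HG-class pixels / invasive pixels (WHO mode: high if
  *f*<sub>HG</sub> > 0; prognostic mode: high if *f*<sub>HG</sub> > 0.70).
  A tumor fraction > 20% of annotated tissue flags molecular-testing
  adequacy.
* **Ensemble aggregation.** Tile-level labels (ground truth or a simulated
  noisy classifier) are triaged into cancer / other pathology / normal;
  isolated tumor tiles — connected components smaller than 2 under
  8-connectivity — are treated as outliers and ignored before the
  scan-level ICD-10 call, suppressing false-positive C16.9 calls.
* **Prognostic index.** Five one-point criteria — age > 65, high-grade
  component > 70%, ulceration (> 1% fibrin/granulation tissue), absence of
  intestinal metaplasia, absence of dysplasia — give a 0–5 score with a
  three-tier (0–2 / 3 / 4–5) and a two-tier (0–3 / 4–5) risk
  stratification.
* **Statistics.** Kaplan–Meier curves, restricted mean survival, two-group
  log-rank tests, a 1–99% high-grade threshold sweep, Cohen's kappa,
  Yates-corrected χ², and sensitivity/specificity under diagnostic code
  consolidation (C16.9 + D00.2 vs D13.1 + K29.7).
* **Synthetic data.** Seeded generators for annotated slides (random blob
  polygons with exact post-rasterization ground truth), clustered tile
  lattices with isolated-tile contamination, and survival cohorts whose
  exponential hazard depends on the prognostic criteria — so every stage is
  testable without image data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on results.

## Worked example

Generate a synthetic annotated slide, quantify it, and call the diagnosis:

```r
library(gastromorph)

sl <- gen_slide(c(NG = 0.5, TACG1 = 0.2, TACG3 = 0.1, IM = 0.05),
                width_px = 512, height_px = 512, seed = 42)
composition_fractions(sl$composition)
#> # A tibble: 5 × 4
#>   slide_id  class_code  pixel_count fraction
#> 1 synthetic IM                13075   0.0593
#> 2 synthetic NG               129365   0.587
#> 3 synthetic TACG1             52064   0.236
#> 4 synthetic TACG3             25953   0.118
#> 5 synthetic unannotated       41687  NA

classify_slides(sl$composition)
#> # A tibble: 1 × 11
#>   slide_id  icd10 who_histotype lauren     grade hg_fraction ...
#> 1 synthetic C16.9 TAC-LG        intestinal low         0.333 ...
```

The slide carries invasive carcinoma (so C16.9), tubular adenocarcinoma
dominated by its low-grade component (TAC-LG, intestinal by Lauren), and a
high-grade fraction of 0.333 — below the 0.70 prognostic cut-point, hence
grade `low` in prognostic mode. The tumor fraction of 0.354 (> 0.20) makes
the sample adequate for molecular testing.

Score and analyze a simulated survival cohort under the default
calibration (142 patients, two-tier hazards 0.0285 vs 0.0764 per month):

```r
co <- gen_cohort(n = 142, seed = 42)      # features -> score -> tiers -> times
km <- km_fit(co, group = "tier2")
survival_at(km, 12)
#>   group  time survival
#> 1 high     12    0.48
#> 2 low      12    0.684
restricted_mean(km, 28)
#>   group horizon rmean
#> 1 high       28  11.5
#> 2 low        28  18.6
glance(logrank_test(co, "tier2"))
#>   statistic    df   p_value
#> 1      16.4     1 0.0000504
```

High-risk patients (score 4–5) show markedly worse one-year survival (48%
vs 68%) and restricted mean survival (11.5 vs 18.6 months over 28 months),
and the tier difference is highly significant by the log-rank test.
`hg_threshold_sweep()` repeats the log-rank dichotomy at every high-grade
threshold from 1% to 99% and flags the best-separating cut-point;
`autoplot()` draws any of these results.

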