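---
title: "Methods: from annotated gastric biopsies to diagnoses and prognoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from annotated gastric biopsies to diagnoses and prognoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastromorph)
```

`gastromorph` turns exhaustive polygon annotations of gastric biopsy
whole-slide images into per-class pixel compositions, and compositions into
diagnostic codes, histotypes, prognostic scores and survival statistics.
This vignette documents the models and conventions behind each stage, the
tunable parameters and their defaults, what the synthetic generators do and
do not emulate, and the design choices that were genuinely open.

## 1. Quantification

**Coordinates and rasterization.** Annotation coordinates are 0-based
continuous pixel coordinates; pixel `(i, j)` is the half-open cell
`[i, i+1) × [j, j+1)`. A pixel belongs to a polygon when its *center*
`(i + 0.5, j + 0.5)` lies inside the polygon under the even-odd rule.
Overlapping polygons are resolved last-drawn-wins in file order. These
conventions are arbitrary but deterministic; the tests pin them down and
the rasterization error against the shoelace area of a simple polygon is
bounded by its perimeter (in pixels) plus a small constant, which the suite
checks property-wise against random star-shaped polygons.

**Tiling and exclusion.** The mask is cut into `tile_size` × `tile_size`
slices (default 256 px, the standard patch size for slice classifiers).
Border tiles keep their true, smaller pixel budget rather than being
padded, so per-tile counts conserve the mask totals exactly — conservation
(mask totals = Σ tile totals = retained + excluded composition totals) is
the central invariant of this stage. A tile is excluded exactly when its
unannotated fraction strictly exceeds `max_unannotated_frac` (default
0.10): a tile at exactly 10% is retained. Retained tiles are labelled by
their majority annotated class; ties are broken by ontology order, which
makes labelling deterministic. A purity threshold (label only when the
majority class holds at least that share of the annotated pixels) is
available but off by default, since majority labelling is the simpler
convention and the choice is not observable in the composition totals. A
caller-supplied per-tile veto list stands in for exclusions that require
human judgment (annotations inconsistent with the underlying histology).

**Molecular adequacy.** Tumor fraction is invasive-carcinoma pixels over
all annotated pixels; a sample is adequate for molecular testing when the
fraction strictly exceeds `min_tumor_frac` (default 0.20, the conventional
tumor-to-nontumor requirement).

## 2. The class ontology

The default ontology carries 16 invasive-carcinoma codes (TACG1–3, PACG1–2,
MPAC, PCC, PCC-NOS, MAC1–2, ACLS, HAC, ACFG, SCC, NDC, NED), the two
dysplasia grades (GINH, GINL), the ulceration markers fibrin (F) and
granulation tissue (GT), and non-neoplastic mucosal classes (NG, IM, LT,
and generic gastritis/foveolar classes). Display colors follow the group:
carcinoma red, dysplasia and ulceration blue, non-neoplastic green.

Two columns of the ontology are *conventions*, deliberately editable
rather than hard-coded:

* `grade_class` — which carcinoma codes count as high grade. Default:
  G3 tubular, both poorly cohesive classes, and the undifferentiated/rare
  aggressive types (TACG3, PCC, PCC-NOS, NDC, NED, SCC, HAC, ACFG, MPAC,
  MAC2). Whether PACG2 (papillary, second grade tier) is high grade is
  ambiguous in routine nomenclature; the default keeps it low and a user
  who reads PACG2 as high-grade papillary carcinoma can flip the column.
* `lauren_family` — default: tubular/papillary/micropapillary →
  intestinal; poorly cohesive → diffuse; mucinous and the rare types →
  indeterminate. Published Lauren tables differ on mucinous carcinoma;
  keeping it indeterminate is the conservative choice and, like the grade
  set, it is a column, not code.

## 3. The rule engine

**ICD-10 precedence.** C16.9 when any invasive-carcinoma class exceeds
`min_invasive_frac` (default 0: a single tumor pixel decides, matching the
diagnostic rule that one tumor-bearing slice determines the code); else
D00.2 when GINH is present at any positive fraction (mirroring the
any-presence logic); else D13.1 when GINL is present; else K29.7. The
precedence is total and order-independent — permuting composition rows
never changes the call.

**Grading.** `hg_fraction` is high-grade-class pixels over invasive
pixels. WHO mode calls a tumor high grade at any positive high-grade
component (a predominantly low-grade tumor with a focal high-grade
component is a mixed tumor and graded high); prognostic mode requires the
fraction to strictly exceed `threshold` (default 0.70, the cut-point whose
prognostic value the threshold sweep below is designed to probe). The
boundary is strict in both modes, consistent with "exceeding 70%".

**WHO histotype.** Subtype codes fold into family bins (TACG1+TACG2 →
TAC-LG, TACG3 → TAC-HG, analogously for PAC via the ontology's grade
column; PCC + PCC-NOS → the poorly cohesive family; MAC1+MAC2 → MAC; NED →
NEC; single-code families otherwise). In `who` mode a slide gets the single
dominant family code only when every other family stays strictly below
`minor_component_min` (default 0.10) of the invasive area, and `Mixed`
otherwise; the exact mixing threshold used in diagnostic practice is not
standardized, so 10% — a common minor-component convention — is a package
default, not a fact. In `predominant` mode the largest family wins
outright, which by construction cannot produce `Mixed`. The poorly
cohesive family is refined by the Carneiro consensus rule: ≥ 90%
signet-ring cells → PCC-SRC, ≥ 90% non-signet-ring → PCC-NOS, otherwise
PCC-combined; the 90% boundary belongs to the pure subtype because the
consensus wording is "at least 90%".

**Lauren type.** Within the invasive area: intestinal or diffuse when that
family reaches `dominance` (default 0.90), mixed when both reach
`minor_component_min` (default 0.10), indeterminate otherwise.

**Presence features.** Dysplasia (GINH+GINL), intestinal metaplasia (IM),
ulceration (F+GT), normal glands (NG) and lymphoid aggregates (LT) are
flagged when their share of the annotated area strictly exceeds
`presence_threshold` (default 0.01, the > 1% reporting dichotomy).

## 4. Ensemble aggregation and the outlier filter

Tile labels are triaged into three first-level groups (cancer / other
pathology / normal) by a deterministic group projection. Because the
any-tumor-pixel rule is maximally sensitive to label noise, isolated tumor
tiles are removed before the scan-level call: "isolated, discrete" is
formalized as connected components of cancer tiles smaller than
`min_component_size` (default 2) under 8-connectivity (default). Ignored
tiles are *removed from the denominator*, not relabelled as normal —
ignoring means not counting, and relabelling would bias compositions
toward benignity. With `min_component_size = 1` no tile is removed and the
ensemble call provably equals the rule engine applied to the tile-count
composition, which the suite asserts as an oracle-equivalence property.

The slice classifiers themselves are out of scope; a pluggable label
source replaces them. `simulate_classifier()` keeps each tile's true label
with a per-class recall (the packaged default profile spans 0.91 for
G3 tubular carcinoma down to 0.05 for low-grade dysplasia, the spread a
slice classifier realistically exhibits) and spills errors either
uniformly, within the first-level group (`within_group`, the more
realistic confusion structure), or per a user confusion table.

## 5. The prognostic index

Five one-point criteria: age > 65 years; high-grade component > 70% of the
tumor area; ulceration (> 1% fibrin or granulation tissue); *absence* of
intestinal metaplasia; *absence* of dysplasia. Absence criteria are the
negation of the 1%-presence flags, so the same dichotomy drives both
feature reporting and scoring. All boundaries are strict (> 65, > 0.70);
an age of exactly 65 scores no point. Missing features are an error —
with a 5-point integer index there is no defensible imputation. Tiers:
three-tier low 0–2 / intermediate 3 / high 4–5; two-tier low 0–3 / high
4–5 (the two-tier low group is exactly the union of the three-tier low
and intermediate groups). The suite enumerates all 2⁵ criterion
combinations against a brute-force truth table.

## 6. Survival analysis

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package (product-limit estimator with the simultaneous
risk-set tie convention; unweighted log-rank with hypergeometric variance
and no continuity correction, χ² with 1 df). The package layer adds the
tidy accessors, the restricted mean, and the sweep. The independent checks
in the test suite — a brute-force product-limit recomputation and a
vectorized 10⁵-label-permutation null on n ≤ 20 cohorts — are written
against the definitions, not against `survival`.

"Mean survival" is the *restricted* mean: the area under the KM step
function up to a horizon (default: the largest observed time per group),
because the unrestricted mean is undefined while the curve has not reached
zero under censoring.

The high-grade threshold sweep dichotomizes patients at every threshold
from 1% to 99% (`hg_fraction > t/100`) and runs the log-rank test at each;
degenerate dichotomies (an empty arm) are marked not evaluable rather than
raising, and the evaluable threshold with the smallest p-value is flagged.
The permutation-oracle tolerance (|Δp| ≤ 0.03) reflects Monte-Carlo error
plus the χ² approximation error at n = 20; it was fixed from that error
scale, not fitted to outcomes.

## 7. Synthetic generators: what they emulate

All generators are pure functions of their arguments plus a seed.

**Slides.** Random convex-ish blobs (perturbed ellipse polygons, 12
vertices) are placed class by class until target area fractions are
approximately reached, with placements that would mostly overwrite other
classes rejected and up to three top-up passes; the returned ground truth
is the *exact* rasterized count of the final polygon sequence, so
rasterize → tile → compose reproduces it bit-for-bit (the suite asserts
equality, not approximation). Real annotations are free-form and
concave; blobs keep the rasterization oracle simple. No pixel data, stain
or texture is modelled.

**Tile lattices.** A background class plus random discs gives spatially
clustered labels; contamination flips tiles whose 8-neighbourhood is
tumor-free with a stated probability, producing exactly the isolated
false-positive pattern the outlier filter exists to remove (and a clean
binomial expectation for testing the generator itself).

**Cohorts.** Ages are truncated-normal (mean 60, sd 13, on [18, 93], the
age structure of a gastric biopsy service population); ulceration,
metaplasia and dysplasia are Bernoulli with prevalences 28.2%, 18.9% and
15.7%; the high-grade fraction is uniform on [0, 1] (so the > 0.70
criterion has prevalence 0.30 and every sweep threshold is populated).
Death times are exponential with hazard `h0 · exp(β · risk)` where the
risk summary is the two-tier indicator (default), the raw score, or a
high-grade change-point indicator for sweep studies; censoring is
administrative at `horizon` months. The default calibration — `h0` =
0.0285/month, tier log-hazard ratio log(0.0764/0.0285) ≈ 0.986, horizon
28 months, n = 142 — emulates a registry-linked biopsy cohort in which
one-year survival is about 71% (low risk) vs 40% (high risk) and 28-month
restricted means are near 19 vs 11 months; these targets fix the two rates
analytically via `S(12) = exp(−12 h)`. The exponential (constant-hazard)
model is the default because its closed forms make test expectations
exact; a Weibull shape is available behind a parameter.

What passing tests therefore show: the pipeline's arithmetic, rules,
filters and statistics are correct on data with the assumed structure.
What they do not show: performance on real slides — real annotation
geometry, scanner artefacts, inter-annotator variability, non-proportional
hazards and informative censoring are all outside the generators.

## 8. Problem sizes and numerical conventions

The test suite runs at deliberately modest sizes — canvases up to 2048²
for the slide-generator accuracy check (±0.05 tolerance on target
fractions), 256–320 px canvases for conservation loops, n = 300 cohorts
with 200 seeds for the power check (hazard ratio 2.5, expecting ≥ 90%
rejections) and size check (type-I error within three binomial standard
errors of α = 0.05), and 100 replicates for the 70%-change-point recovery
check (best threshold within ±10 points in ≥ 80% of replicates). Reported
percentages are rounded half-up to one decimal; all internal arithmetic is
double precision with integer pixel counts.

Degenerate inputs have defined behavior throughout: empty compositions,
zero-tumor grade calls, zero PCC-family subclassification, one-armed
log-rank tests and out-of-range scores raise errors; sweep thresholds with
an empty arm are marked not evaluable; Cohen's kappa on a single-cell
diagonal table is defined as 1; the Yates statistic is clamped at zero
when the correction overshoots.

## 9. Known limitations

* The WHO-mode minor-component threshold (10%) and the Lauren dominance
  threshold (90%) are package conventions where diagnostic practice is
  unstandardized; both are parameters.
* The rule engine's any-presence triggers (C16.9, D00.2) are
  noise-intolerant by design; they are meant to be fed human annotations
  or filtered ensemble output, not raw noisy tile labels.
* Neuroendocrine differentiation genuinely requires immunohistochemistry;
  the NED/NEC class here only reflects what was annotated.
* No Cox modelling: the package stratifies and tests; it does not estimate
  adjusted hazard ratios.
* The interface runs on compositions, not images; reading `.svs` pyramids
  and producing annotations is upstream of this package.
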