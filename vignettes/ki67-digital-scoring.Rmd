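---
title: "Digital Ki-67 scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital Ki-67 scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67flow)
```

## The problem

The Ki-67 proliferation index — the fraction of tumour-cell nuclei staining
positive for the Ki-67 antigen — guides prognosis and treatment decisions in
breast cancer. It is scored either visually (a pathologist counts
100-cell increments under the microscope in the most proliferative
"hotspot") or digitally, by detecting and classifying every nucleus in a
scanned slide and counting in algorithmically identified hotspots. The two
routes do not return the same numbers: digital hotspot counting tends to
find higher values, and values fall as more cells are counted outward from
the hotspot. Because Low/Intermediate/High categories are derived from the
in-house cohort median (the St. Gallen convention: Low below median − 10
percentage points, High above median + 10), a laboratory that switches
methods without recalibrating its cut-offs will silently reclassify
patients. `ki67flow` implements the full digital pipeline, the scoring and
cut-off machinery, the cohort statistics used to compare methods, and a
synthetic data generator so that every stage is testable without slide
data.

## The imaging model

Brightfield H-DAB immunohistochemistry is modelled with Beer–Lambert
transmission. Per pixel and RGB channel $c$,

$$ I_c = I_0 \cdot 10^{-\sum_s a_s v_{s,c}}, $$

where $I_0 = 255$ is the white point, $a_s \ge 0$ the stain concentration
(hematoxylin and DAB) and $v_s$ the unit optical-density vector of stain
$s$. `rgb_to_od()` inverts this with
$OD_c = -\log_{10}(\max(I_c, 1)/I_0)$, flooring intensities at one 8-bit
quantization unit so a zero pixel stays finite, and clipping negative OD at
zero. With this convention a noise-free rendered scene deconvolves back to
its generating concentrations at numerical precision, which the tests
exploit as an exact oracle.

`deconvolve()` solves the 3×3 linear system per pixel. The default basis is
the widely used published H-DAB pair, H ≈ (0.65, 0.70, 0.29) and
DAB ≈ (0.27, 0.57, 0.78); the third "residual" vector is the normalized
cross product of the two. The residual is a mathematical complement, not a
dye, and it must be left orthogonal: forcing it nonnegative places it
almost on top of the hematoxylin direction and makes the matrix
near-singular (condition number from 3.0 to far beyond 100), at which point
counterstain pixels with any noise deconvolve into nonsense.

`estimate_stain_vectors()` re-estimates the basis from the image itself:
foreground pixels (OD sum > 0.15) are assigned to their dominant stain
under the default basis, and each stain vector is re-estimated as the
unit-normalized trimmed mean direction of its group (1% trimmed per
channel, at least 50 pixels per group, with a warned fallback to the
default). The exact pixel-selection rule inside interactive
digital-pathology tools is not published; this rule is our documented
stand-in, and on synthetic renders it recovers the generating basis to
within about 1.5 degrees and tracks a 5-degree perturbation of the basis.

## Nucleus detection

`detect_nuclei()` runs a QuPath-style watershed detection on the OD-sum
channel with the standard parameterization, all distances in micrometres:
resample to 0.4 µm/px; rolling-ball background subtraction (morphological
opening, radius 8 µm) with exclusion of pixels whose background estimate
exceeds 3.0 (dense artefacts); median filter (1.5 µm); Gaussian smoothing
(σ = 1.5 µm); global threshold 0.02; marker-controlled watershed; area
filter 10–350 µm² (read as areas, the convention of the tools that use
these numbers). Two implementation details are underdetermined by that
parameter list and are fixed here as follows:

* **Markers.** Watershed markers are 3×3-neighbourhood regional maxima of
  the smoothed channel, thinned by greedy non-maximum suppression at a
  4 µm minimum separation. A plain 4 µm maximum filter looks innocuous but
  suppresses the peak of any small nucleus lying within roughly the
  neighbour's radius plus 4 µm of a denser one, and systematically merges
  adjacent nuclei of unequal intensity.
* **Boundary refinement.** At threshold 0.02 the σ = 1.5 µm smoothing
  spreads every nucleus 3–4 µm past its true edge, displacing centroids
  and diluting per-nucleus stain means. Each watershed segment is therefore
  tightened to the half-peak-height level set of the smoothed channel
  (largest connected fragment): for a blurred compact object the 50%
  contour sits on the true boundary. The nucleus area is the pixel-count
  area of this refined mask.

On synthetic scenes with the default morphology, detection achieves
F1 ≥ 0.93 against ground truth at a 3 µm match radius with mean centroid
error below 0.6 µm.

`expand_cells()` grows each nucleus by up to 5 µm, with ties between
neighbours resolved on the equidistant line (a distance-limited Voronoi
partition), so cell polygons never overlap. `measure_features()` computes
shape features (area; perimeter and circularity $4\pi A/P^2$ from a
moving-average-smoothed contour, because the raw chain length of a
pixel-traced outline overestimates perimeter; eccentricity from mask second
moments) and per-stain intensity statistics over the nucleus and cell-ring
masks. The single measurement that drives everything downstream is
`nucleus_dab_od_mean`, the mean deconvolved DAB OD over the nucleus mask.
`smooth_features()` adds Gaussian-weighted neighbourhood means at radii 25,
50 and 100 µm with weight $\exp(-d^2/(2(r/2)^2))$; the $\sigma = r/2$
convention is recorded here and reused by the heat map so the two stages
agree.

## Classification and positivity

`train_classifier()` fits a two-class (tumour vs other) ensemble of
randomized decision trees (200 trees) on the full feature set, with the
"equally spaced" 67/33 train/test split implemented literally: every third
object by row index, with a seeded offset, forms the held-out set. The
held-out accuracy is stored in the model metadata; `augment_training()`
pools new annotations and retrains under the same split rule. On synthetic
scenes the class morphologies (large round-to-oval tumour nuclei, elongated
stromal nuclei, small dense lymphocytes) are separable and accuracy is
essentially perfect — the 85% figure quoted for real tissue should be read
as a floor that synthetic data clears easily, not a property the generator
tries to reproduce.

`call_positivity()` is a single inclusive threshold: a nucleus is Ki-67
positive iff `nucleus_dab_od_mean` ≥ 0.15. The threshold is applied to the
raw (unsmoothed) measurement, on all nuclei; tumour filtering happens in
scoring. The boundary is taken as inclusive ("set to 0.15" names no
operator) and the rule is monotone by construction.

## Hotspot identification and increment counting

`build_heatmap()` lays a 25 µm grid over the tumour region and fills each
cell with the Gaussian-weighted mean (σ = 25 µm, i.e. radius 50 µm under
the r/2 convention) of `nucleus_dab_od_mean` over tumour-classified
nuclei — all tumour nuclei, not only positive ones, matching a smoothed
measurement map rather than a positive-cell density map. Cells with no
nucleus within twice the radius are masked, as are cells inside artefact
exclusion polygons (`exclude_artefacts()`, idempotent); masked cells
neither seed hotspots nor contribute member nuclei.

`select_increments()` replaces the manual delineation of counting fields
with a deterministic greedy rule: seed at the hottest unmasked cell, take
the 100 nearest unassigned tumour nuclei, count positives, rebuild the
heat map from the still-unassigned nuclei, repeat until five disjoint
100-cell sets exist (an explicit error names the shortfall if fewer than
500 eligible tumour nuclei remain). Rank 1 is the hotspot count. For
emulating visual assessment on ground truth, each seed can be jittered
with isotropic Gaussian noise (default SD 25 µm in the pipeline's VA arm),
standing in for a pathologist's imperfect hotspot localisation, and
positives can be counted from the stored ground-truth flags instead of the
measurement threshold.

## Scoring, cut-offs and reclassification

`cumulative_percentages()` computes the running percentage after each
increment in exact arithmetic (rounding to one decimal only in reports);
the 500-cell value is the mean of the five per-increment percentages.
`derive_cutoffs()` encodes the St. Gallen median convention (Low below
median − 10 pp, High above median + 10 pp) with boundaries inclusive to
Intermediate; a median outside [10, 90] warns and clips. When the VA and
DIA category schemes printed for a real cohort are fed back through this
arithmetic — medians 22.3% and 30.0% — the implementation reproduces the
published cut-off pairs (12.3, 32.3) and (20.0, 40.0) exactly, and the
published visual-assessment reclassification flows conserve the category
counts through `transition_from_flows()`. `transition_table()`
cross-tabulates per-case categories between two increments with exact
marginals.

## Cohort statistics

The comparison layer wraps the field-standard estimators behind tidy
interfaces: Pearson's uncorrected χ² (`pearson_chi2()`), Bland–Altman
agreement with the difference-on-mean slope for proportional bias
(`bland_altman()`), the Aalen–Johansen cumulative incidence treating death
from other causes as a competing event (`cumulative_incidence()`, with
log(−log) pointwise intervals and `cif_at()` for the 5- and 10-year
values), Gray's K-sample test at ρ = 0 (`gray_test()`), cause-specific Cox
models with Efron tie handling, switchable to Breslow (`cox_ph()`), and
Harrell's C on the cause-specific censored data, with an all-cause switch
(`harrell_c()`). Where the estimators reduce to closed forms the tests
check exact agreement: with no competing events the Aalen–Johansen curve
equals 1 − Kaplan–Meier at every event time, a three-subject instance
matches hand-computed values (1/3, 1/3), and the Cox partial likelihood
matches a grid-search oracle on a four-subject instance to 1e-4.

## The synthetic generator: what it emulates and what it does not

`simulate_nuclei()` places elliptical nuclei by a hard-core point process
(per-class minimum centre spacing, with morphology drawn first so that
centre distances below 0.8× the sum of semi-major axes are also rejected —
touching pairs survive, pathological double-nucleus merges do not). Class
morphology defaults: tumour 55 ± 12 µm², axis ratio 1–1.6; stroma
30 ± 7 µm², ratio 2.2–3.5; lymphocyte 16 ± 2.5 µm², ratio ≤ 1.25. Tumour
positivity is Bernoulli from a field of a uniform base plus Gaussian
hotspot bumps (peak at the hotspot centre, σ = radius/2). Stains:
hematoxylin ~0.5–0.8 OD by class; DAB 0.6 ± 0.12 (min 0.3) in positive
nuclei, whose hematoxylin is reduced to 5% — strongly DAB-stained nuclei
are brown, not blue-brown, and without such near-pure DAB pixels no
image-based stain estimator could identify the DAB direction. Rendering is
the exact transmission model plus optional additive Gaussian RGB noise
(default SD 2).

The generator reproduces the features that matter for this pipeline —
separable nuclear morphology, spatially heterogeneous positivity with
hotspots, touching nuclei, stain mixing — and deliberately omits texture
(chromatin patterns, cytoplasmic background), out-of-focus and fold
artefacts, partial-volume edge pixels and scanner colour calibration
drift. Passing tests therefore demonstrate that the algorithms are
implemented correctly and recover known ground truth under controlled
conditions; they do not certify performance on real slides, where the
classifier and the 0.15 threshold would need retraining and recalibration.

`simulate_cohort()` generates patients whose grade, mitotic count and
cause-specific hazards all depend on a latent true Ki-67 fraction: a grade
component (probabilities 0.065/0.528/0.407, matching a three-grade
population series), Beta-distributed Ki-67 within grade, negative-binomial
mitoses with mean 1.5 + 28·Ki-67, and exponential cause-specific hazards
log-linear in Ki-67 (breast-cancer death baseline 0.03/year with slope
2.5; other-cause death 0.05/year, slope 0; administrative censoring at 30
years). These defaults give roughly 44% breast-cancer deaths and 50%
other-cause deaths over follow-up, the regime of a long-follow-up
population cohort, and make Cox and Gray recovery analytically checkable.

`simulate_score_cohort()` is the fast cohort-level harness: per-case
random base positivity (0.05–0.45) and one random hotspot, increments run
directly on ground truth for an idealized digital arm and a seed-jittered
visual arm. Across such cohorts the digital arm shows the qualitative
signature of hotspot-seeded counting: cohort medians decline monotonically
from the 100-cell to the 500-cell value, and more cases are High at 100
cells than at 500.

## Problem sizes and numerical choices

The shipped tests run scenes of 150–500 µm square (up to ~1,500 nuclei;
the classifier-floor check pools four 360 µm scenes, ~3,400 labeled
nuclei) and 100 simulated cohorts of 20 cases for the reclassification
property; these sizes were chosen as the smallest at which the binomial
and simulation tolerances in the checks are comfortably resolved.
Remaining numerical conventions: all coordinates are physical micrometres,
origin top-left, y downward, polygons counterclockwise and closed on
write; ties in the equally spaced split are resolved by the seeded offset;
negative deconvolved concentrations are clipped to zero with the clipped
fraction logged in the result; the pipeline's global seed fans out to
per-stage seeds as (seed + 104729·stage) mod 2³¹−1, recorded in the run
manifest so any stage can be reproduced in isolation.

## Known limitations

Detection quality degrades for deeply overlapping nuclei (the generator
limits, and real tissue does not); the heat map's normalized Gaussian
weighting makes sparsely populated cells noisy, so increments in sparse
regions inherit single-nucleus variance; the greedy increment rule is a
reproducible stand-in for manual field delineation, not a reconstruction
of it; and the cohort generator's proportional-hazards structure is the
analysis model, so hazard-recovery checks validate the estimator plumbing,
not robustness to model misspecification.
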