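---
title: "Models and methods behind pvstopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pvstopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pvstopo` measures how enlarged perivascular spaces (EPVS) distribute in
space relative to white matter lesions (WML), and models how that
distribution varies with disease stage and lesion burden. This vignette
explains the geometry, the statistical models, the synthetic-data
generator that validates them, and the numerical choices that an
analyst may want to inspect or change.

## Geometry

All computations take place in axis-aligned index space scaled by the
voxel spacing: a voxel at 0-based index `(i, j, k)` has its center at
`(i, j, k) * spacing_mm`. The rotational part of the NIfTI affine is
deliberately ignored — distances between structures on a single
subject's coregistered, same-grid masks are invariant under rigid
reorientation, and masks from different grids are rejected rather than
resampled (shapes must match exactly; spacings within 1e-4 mm per
axis). Default spacing is 1 mm isotropic.

**Connected components.** EPVS and WML are labeled under 26-connectivity
by default: EPVS are thin, obliquely oriented tubules that fragment
under face-only (6-) adjacency. Connectivity is a parameter (6, 18, 26)
everywhere. Labels are assigned in array order, so results are
deterministic.

**Boundary shell.** The lesion boundary is `mask AND NOT erode(mask)`
with the 6-connected cross structuring element, i.e. the inner
one-voxel surface layer. Voxels outside the array count as background,
so a mask touching the array border keeps its border voxels in the
shell; brain masks do not reach the border in practice.

**Distances.** Each EPVS is represented by its centroid (unweighted
mean of voxel indices — masks are binary, so there is nothing to
weight). The distance to the lesion boundary is the minimum Euclidean
distance from the centroid to any boundary voxel center. The
implementation expands a cubic (Chebyshev) window around the centroid's
nearest voxel; crucially, a first hit at Chebyshev radius `r` need not
be the Euclidean nearest voxel (a corner voxel at radius 2 is farther
than a face voxel at radius 3), so the window keeps growing until the
current best distance is at most `(r + 0.5) * min(spacing)` — beyond
that no outside voxel can win. This makes the search *exactly* equal to
the exhaustive minimum, which the test suite verifies against an
independent brute-force implementation on 1000 random mask/point pairs,
including anisotropic spacings, with zero tolerance. No sub-voxel
surface interpolation is attempted; distances are between voxel
centers, matching the voxel-level boundary construction.

An EPVS whose centroid, rounded to the nearest voxel index, lies inside
the WML mask is classed *within* the lesion at distance 0 and excluded
from the search. The centroid rule (rather than any-voxel overlap)
keeps the distance analysis a true partition of components. Subjects
with no lesion voxels at all get infinite distances, binned into the
terminal category, with a `has_wml` flag so the statistical layer can
exclude them explicitly; they are included by default, since dropping
them would bias the distal bins.

**Bins and proximity.** Distances are grouped into 5 mm bins from 0
(within the lesion) to 30 mm plus a terminal `> 30 mm` bin, and into
three penumbra categories: within (0 mm), near (`0 < d <= 5` mm,
approximating the rim of microstructurally damaged tissue around a
lesion), far (`> 5` mm). Bins are half-open above, `(b - 5, b]`: an
exact 5.0 mm falls in the lower bin, so bin `B5` and the near category
agree by construction. The proximity categories are exactly a
coarsening of the bins, which is tested.

**Regional counts.** Regional EPVS metrics intersect the EPVS mask with
the region mask and then count components *of the intersection*. This
is not a partition: a component straddling the lesion border
contributes a piece to both WML and non-WML regions, and a component
whose intersection with a region splits in two is counted twice there.
The cleaner alternative — assigning each whole component to the region
containing its centroid — is available (`rule = "centroid"`) and is the
rule the distance analysis effectively uses; the intersection rule
remains the default for regional burden because it is the conventional
reading of mask-intersection pipelines. The inequality
`count(WML) + count(non-WML) >= count(whole brain)`, with equality iff
no component straddles the border, is asserted on constructed cases.

Basal ganglia and white matter are defined from an integer label volume
using the FreeSurfer `aseg` color-table convention by default (BG:
caudate 11/50, putamen 12/51, pallidum 13/52, accumbens 26/58, thalamus
10/49; WM: 2/41), fully overridable. WM and BG masks are used as
provided — lesion voxels are not excluded from them unless requested
(`exclude_wml_from_tissue`), since the upstream parcellation defines
them independently of the lesion segmentation.

## Statistical models

EPVS counts are overdispersed, so group and association models use
negative-binomial regression with a log link (`MASS::glm.nb`, dispersion
estimated by maximum likelihood); effects are reported as `beta_exp =
exp(coefficient)`, the multiplicative ratio of expected counts, with
Wald 95% intervals on the same scale. For counts inside lesions, where
a majority of subjects have none at all, a zero-inflated NB is used
(`glmmTMB`, `nbinom2` with an intercept-only zero component): the
zero-inflation probability needs no covariates because the structural
zeros are a property of the subject, not of measured predictors.

Volumes are strictly positive and right-skewed, so volume models take
the natural log of the ICV-normalized volume and fit a Gaussian GLM.
Coefficients are standardized: the log outcome and all continuous
predictors are z-scored, while binary/categorical predictors stay as
indicators — so a group effect is in pooled-SD units of the log
outcome. (Whether to standardize outcome, predictors, or both is a
genuine convention choice; this one makes group contrasts directly
comparable to correlation-scale effect-size conventions: small < 0.1,
medium < 0.3, large > 0.5.) Subjects with zero regional volume are
excluded from that region's volume model (the log is undefined) and
counted in an exclusion report; an epsilon offset of half the smallest
positive observed volume is available as a sensitivity option.

Age and sex enter all adjusted models as fixed covariates. Count models
carry no exposure offset by default (counts are not volume-normalized
upstream); a log-ICV offset is available as an option. Sequential stage
contrasts (e.g. CU vs MCI, MCI vs AD) are Wald tests on coefficient
differences using the fitted covariance — algebraically identical to
re-leveling and refitting, which the tests confirm. Multiplicity is
controlled by Benjamini–Hochberg FDR *within each family* of tests,
one family per output table (group counts, group volumes, per-bin
models, ...); the step-up adjustment is delegated to `p.adjust` and
verified against a direct implementation of the formula on random
p-vectors. Heteroscedasticity of the log-volume models can be checked
with the Breusch–Pagan test (LM statistic `n * R^2` of the auxiliary
regression of squared residuals on the design, chi-squared with one df
per design column; degenerate constant-residual input returns statistic
0 rather than an unstable 0/0 R-squared).

Wald rather than profile-likelihood intervals are used throughout
(convergence tolerance 1e-8, at most 200 IRLS iterations);
non-convergence is flagged on the result row, never silently replaced.
Coverage of the Wald interval (92–98% for a true count ratio of 1.5 at
500 per group over 200 replicates) and type-I error of the group test
(3–7% at nominal 5% over 1000 null replicates of 200 per group) are
asserted in the acceptance suite.

## Segmentation agreement

Three Dice variants are computed. *Overall* Dice is the whole-image
`2TP / (|pred| + |truth|)`. *Voxel-wise* Dice scores each ground-truth
lesion `L` against the union `P_L` of predicted components overlapping
it, `2|P_L ∩ L| / (|P_L| + |L|)`, averaging over truth lesions (no
overlap contributes 0). *Lesion-wise* Dice counts lesions: a truth
lesion with at least one predicted voxel is a hit, a predicted
component overlapping nothing is a false positive, and the score is
`2TP / (2TP + FP + FN)`. The per-lesion averaging order admits more
than one reading in common prose descriptions; these two formulas are
the standard, testable ones and both reduce to 1 exactly when the
component sets coincide voxel-for-voxel. Count/volume agreement uses
Spearman's rho (average ranks) and Lin's concordance correlation with
population (1/n) moments per Lin's original definition; the
attenuation property `|CCC| <= |Pearson r|` is tested.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be tested against
known ground truth. It emulates, at desk scale, the structure of an
AD-continuum imaging cohort; it does **not** emulate MRI intensities,
scanner effects, segmentation error, or realistic brain anatomy, so
passing tests demonstrate the correctness of the *measurement and
modeling machinery*, not robustness to real segmentation noise.

Anatomy is a shared template on a 96^3 grid at 1 mm: an ellipsoidal
brain, a mid-radius white-matter shell (label 2), cortical/deep gray
matter (label 3), and two ellipsoidal basal-ganglia blobs (labels 11
and 50). ICV is the brain voxel volume. Three groups (CU/MCI/AD) follow
the demographic profile of a typical aging cohort: fractions
0.55/0.34/0.11, mean ages 73.0/74.7/77.1 (SD ~8), female fractions
0.59/0.44/0.43, amyloid-positive fractions 0.27/0.45/0.82 and mean WML
burdens 0.51/0.69/0.83% of ICV.

Per subject:

* **Lesions** grow from 1–4 random white-matter seeds by stochastic
  6-neighbor dilation (acceptance probability 0.6 per sweep) to a
  lognormal target volume (sdlog 0.7 around the group mean); a small
  per-group probability of having no lesion at all (3/2/1%) exercises
  the no-WML code path. A target exceeding half the white matter is an
  error.
* **Counts** are negative binomial with dispersion alpha = 0.5, log
  mean `log(40) + group offset + 0.1 * (age - 74)/8 + 0.1 * male +
  0.3 * (log WML% - log 0.6)`; group offsets are 0, log 1.23 and
  log 1.1. The positive lesion-burden coefficient mirrors the robust
  count–burden association seen in such cohorts; the intercept of 40
  keeps per-subject work tractable on a 96^3 grid.
* **Placement** samples EPVS centers over white matter, basal ganglia
  and lesion voxels with intensity `lambda(d) = 1 + A exp(-d / tau)`,
  `A = 4`, `tau = 5` mm, where `d` is an exact Euclidean distance
  transform of the lesion boundary (Felzenszwalb–Huttenlocher, also
  anisotropic-aware). Each EPVS is stamped as a 3–8 voxel tubule along
  a uniformly random orientation, radius one voxel. Tubules centered
  outside the lesion are clipped against it so EPVS and WML masks stay
  disjoint except for deliberately placed within-lesion EPVS.
* **Structural zeros.** With probability pi = 0.41 a subject's
  within-lesion EPVS centers are relocated outside the lesion
  (re-sampled from the non-lesion placement distribution), preserving
  the subject's total count. The value 0.41 was calibrated once, before
  the acceptance checks were frozen, from the natural zero rate of the
  unforced generator (about 30% of lesion-bearing subjects place no
  EPVS inside their lesion at the default intensity): with
  `share = p_noWML + (1 - p_noWML) * (pi + (1 - pi) * q)`, pi = 0.41
  yields an overall within-lesion zero share of about 60%, the level at
  which a zero-inflated count model becomes clearly preferable to a
  plain NB.
* **Truth** distances and bins are computed from the *final* masks by
  the exhaustive-minimum oracle (not the expanding window, and not the
  distance transform used for placement), so "truth bins equal pipeline
  bins" is a genuine cross-implementation test of the geometry, and is
  asserted for every simulated subject.

Reproducibility: subject `i` of a cohort runs under its own RNG
substream seeded as `(seed + 7919 * i) mod (2^31 - 1)`, so cohorts are
bit-identical across runs and insensitive to evaluation order. Cohorts
are kept in memory as sparse foreground-index lists (two 96^3 masks per
subject would otherwise cost ~7 MB each), or written to NIfTI + CSV
with `dir =`, in which case the manifest drives `run_metrics()`
unchanged.

## Problem sizes in the test suite

The shipped tests run the full 500-subject default cohort once for the
zero-share check, a 100-subject cohort for conservation, 50 replicate
cohorts of 30 subjects on a 64^3 grid for the coupling-gradient
recovery, 200 replicates of 500-per-group count fits for CI coverage
and 1000 replicates of 200-per-group fits for type-I error, and 1000
random mask/point pairs for distance-oracle equality. Smaller 48^3
cohorts back the bookkeeping and determinism tests. These sizes were
chosen to keep each stochastic check's Monte-Carlo error well inside
its acceptance band while the whole suite remains convenient to run on
a laptop.

## Known limitations

* The generator's anatomy is geometric; regional masks are convex and
  smooth, so label-boundary pathologies of real parcellations (holes,
  one-voxel bridges) are only exercised by the small constructed test
  fixtures, not at cohort scale.
* The intersection counting rule double-counts straddling components by
  design (documented above); cross-region count sums are therefore not
  conserved quantities.
* Distances are centroid-to-boundary-voxel-center; for lesions one or
  two voxels thick the boundary shell equals the lesion and the
  "interior" is empty, which is correct but makes `within` vs `B5`
  assignment sensitive to centroid rounding at exactly half-voxel
  offsets (ties round to even via R's `round`).
* Tubule stamping shifts component centroids off their sampled centers
  by up to half the tubule length, so the placement intensity is
  recovered only approximately by centroid-based histograms; tests of
  placement uniformity use coarse near/far shares rather than exact
  multinomial comparisons for this reason.
* No geodesic (within-tissue) distances and no per-lesion attribution
  of each EPVS to a specific lesion cluster; distances are to the
  nearest boundary voxel of any lesion.
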