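---
title: "Methods: 3D geometric morphometrics of molar crown form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D geometric morphometrics of molar crown form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molarmorph)
```

This vignette documents the statistical model behind `molarmorph`, the
meaning and defaults of every tunable parameter, how realistic the
synthetic-study generator is (and is not), and the numerical conventions
that make results reproducible to the last bit.

## 1. The statistical model

### Size and shape

A specimen is a configuration of k = 18 named crown landmarks in 3D
(mm). Its *centroid size* is

$$\mathrm{CS} = \sqrt{\textstyle\sum_{i=1}^{k} \lVert x_i - \bar{x}\rVert^2},$$

the only size measure used anywhere in the package. *Shape* is the
geometry left after removing position, orientation and scale.
`gpa()` implements generalized Procrustes analysis: every configuration
is centered, scaled to unit centroid size and rotated to the running
consensus; the consensus is re-estimated until its root-mean-square
change falls below `tol` (default 1e-10). Rotations come from the
singular value decomposition of the cross-covariance, with the
determinant forced positive so that no specimen is ever reflected —
left/right chirality is anatomically meaningful for teeth.

Superimposition removes 3 translations, 3 rotations and 1 scale, so the
shape space of 18 3D landmarks has 3k − 7 = 47 dimensions. The aligned
shapes are projected into the linear tangent space at the consensus
(`tangent_coordinates()`): each vectorized configuration has its
component along the unit consensus vector removed, then columns are
centered. For variation of the magnitude seen in crown shape the tangent
approximation is extremely good; see Section 4.

### Measurement error

`procrustes_anova()` decomposes variation in a balanced replicated
design (individuals × scan sessions × digitizations) into three nested
strata. The shape version pools squared Procrustes-coordinate deviations
over all landmarks and dimensions (an isotropic-error model) and
multiplies each ordinary degree of freedom by 47; each stratum's mean
square is tested against the stratum below it. The headline number is
`total_measurement_error()`: the percent of total variation contributed
by the scan and digitization strata together. The study design is only
usable when every individual has the same number of scans (≥ 2) and
digitizations (≥ 2); anything else is rejected as a design error rather
than silently re-weighted.

### Dimensionality of the analysis space

Test statistics with ~150 specimens cannot use all 47 dimensions plus
nuisance parameters freely; the package follows the
distance-correlation rule (`select_dimensionality()`): retain the
smallest m such that Euclidean inter-specimen distances computed from
the first m principal components correlate with the full Procrustes
distances at r ≥ 0.98 (threshold configurable). A plateau diagnostic —
the first m after which r gains less than 0.005 over the next five
components — is reported alongside, because a threshold alone can hide
a profile that is still climbing.

### Hypothesis tests

All multivariate tests are Wilks' Λ tests of linear hypotheses on a
group × sex (MANOVA) or group + size (MANCOVA) design, with Type III
sums of squares via sum-to-zero contrasts, converted to F by Rao's
approximation:

$$t = \sqrt{\frac{p^2q^2 - 4}{p^2 + q^2 - 5}}, \quad
  w = \nu - \frac{p - q + 1}{2}, \quad
  \mathrm{df}_1 = pq, \quad \mathrm{df}_2 = wt - \frac{pq}{2} + 1,$$

$$F = \frac{1 - \Lambda^{1/t}}{\Lambda^{1/t}}
      \cdot \frac{\mathrm{df}_2}{\mathrm{df}_1},$$

with ν the residual df, p the number of responses and q the hypothesis
df (t = 1 when pq ≤ 3 or the denominator under the root is
non-positive; the transformation is then exact). The multivariate effect
size is η² = 1 − Λ^{1/s} with s = min(p, q); the two conventions
η² = 1 − Λ and η² = 1 − Λ^{1/s} coincide only when s = 1, and the
package deliberately uses the latter because it is the one consistent
with the Λ/η² pairs the design dfs were validated against.

Pairwise group comparisons use permutation tests
(`pairwise_permutation_tests()`): the observed statistic (Procrustes
distance between group mean shapes, Euclidean distance between mean
tangent vectors, or absolute mean difference of a scalar) is compared to
its distribution under random relabeling of the two groups' specimens,
with p = (b + 1)/(n_perm + 1) — never an unattainable zero. Families of
pairs are Holm-corrected. Percent explained is the between-group share
of the total sum of squares on the pair's subsample.

### Allometry and size correction

`allometry_regression()` regresses tangent coordinates on centroid size
and reports the percent of shape variance predicted by size with a
permutation p-value. `size_correct()` removes the *pooled within-group*
slope, evaluated about the grand mean size, so that group mean
differences beyond their allometric component are retained — correcting
with a total (between + within) slope would subtract part of the group
effect itself.

### Mean shapes and deformation grids

Group mean shapes are arithmetic means of aligned coordinates.
`tps_warp()` computes a 3D thin-plate spline from the control mean to a
group mean using the kernel U(r) = r — the biharmonic fundamental
solution in 3D (the familiar r² log r kernel is the 2D solution and is
dimensionally wrong here). The warp interpolates every landmark exactly,
decomposes into an affine part plus kernel weights, and reports the
bending energy (zero iff the target is an affine image of the
reference). Grids are three axis-aligned planes through the reference
centroid, 20 × 20 cells, extended 10% beyond the bounding box.

## 2. Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `gpa(tol)` | 1e-10 | shape units | consensus RMS change; converges in ~4 iterations on realistic data |
| `select_dimensionality(threshold)` | 0.98 | correlation | retains distance geometry while cutting noise dimensions |
| plateau window / gain | 5 comps / 0.005 | — | flags profiles that have stopped climbing |
| `pairwise_permutation_tests(n_perm)` | 10000 | — | p-value resolution 1e-4; pipeline default 999 for speed |
| `alpha` | 0.05 | — | flag threshold after Holm adjustment |
| `shape_rank(tol)` | 1e-7 | relative | see Section 4 |
| TPS grid | 20 × 20, +10% margin | cells | visual convention |

Generator (`generator_spec()`) defaults emulate the clinical design:

| Parameter | Default | Units |
|---|---|---|
| cell sizes | F: 20/20/20/19, M: 20/20/19/15 (N = 153) | specimens |
| female group mean CS | 18.58 / 17.88 / 17.84 / 17.51 | mm |
| `sex_size_effect` | +0.45 | mm |
| `size_sd` | 1.05 | mm |
| `landmark_noise_sd` | 0.15 | mm, isotropic |
| `offset_norms` | 0 / 0.030 / 0.042 / 0.052 | Procrustes units |
| `allometry_share` | 0.07 | fraction of shape variance |
| error design | 20 × 2 × 2, shares 82.8 / 6.2 / 11.0 | % |

## 3. The generator: construction and realism

`template_molar()` is a constructed (not measured) 18-landmark
configuration that respects the schema's topology — cusp tips occlusal
to pits, pits occlusal to the gingival margin, contacts at opposite
mesiodistal ends — scaled to CS = 18.6 mm. Each simulated specimen is

1. the unit-size template plus its group's tangent-space offset plus an
   allometric vector times the specimen's size deviation,
2. rescaled to a centroid size drawn from the group × sex normal
   distribution,
3. perturbed by isotropic landmark noise in mm,
4. randomly rotated (uniform quaternion) and translated.

Two construction details matter:

- **Offsets live in the tangent space.** Group offsets and the
  allometric vector are projected orthogonal to *all seven* nuisance
  directions at the template — 3 translations, the scale direction, and
  3 infinitesimal rotations (antisymmetric generators). Skipping the
  rotational directions lets GPA absorb part of each offset and biases
  recovered effect sizes downward by several percent.
- **Designed shares are solved, not tuned.** `error_sds_for_shares()`
  inverts the expected nested sums of squares of the balanced design to
  get scan/digitization noise sds from target percent shares;
  `allometry_norm_for_share()` sizes the allometric vector so that
  regression of shape on size is expected to explain the requested
  share. Both inversions are validated by recovery tests.

Realism limits, stated plainly: landmark noise is isotropic and
homoscedastic (real digitization error is landmark- and
direction-specific); group offsets are a fixed severity axis plus small
lateral components (real group differences are higher-dimensional);
sizes are normal with a common sd; there is no covariance between size
and which landmarks are noisy; and the template is a plausible cartoon,
not an average of real teeth. The generator is therefore suitable for
validating *machinery* (recovery, calibration, dfs) but not for making
biological claims.

## 4. Numerical conventions

- **Canonical orientation.** After convergence, the fit is rotated to
  the principal axes of the consensus. Signs are fixed on the *rotated
  consensus coordinates* (largest-magnitude coordinate along each axis
  made positive), which is invariant to the input orientation of the
  data; fixing signs on the eigenvector matrix itself is not, because
  eigenvectors co-rotate with the input frame. The basis determinant is
  forced to +1 so canonicalization never reflects shapes.
- **Rank tolerance.** `shape_rank()` counts covariance eigenvalues
  above 1e-7 × the largest. On generated data the 47th eigenvalue sits
  around 1e-5 relative to the first while the 48th is at numerical zero
  (~1e-15 and below) — a gap of many orders of magnitude, so the
  tolerance placement is uncritical.
- **Distance-correlation limit.** With all components retained, the
  correlation between score distances and full Procrustes distances is
  not exactly 1: tangent (chordal) and Procrustes distances differ by
  shape-space curvature. Empirically 1 − r ≈ 2e-7 at the simulated
  variation scale, so the package tests r(full) against 1 − 1e-6 rather
  than machine precision.
- **TPS solving.** The interpolation system is solved densely with one
  step of iterative refinement; landmark interpolation residuals are
  ~1e-15 (the naive expanded-form distance evaluation loses 7 digits to
  cancellation and is avoided).
- **Permutation p-values** use the add-one convention; **Wilks' Λ** is
  clamped into (0, 1] and a singular error matrix is an error ("use
  fewer PCs"), never a silent pseudo-inverse.
- **Serialization.** Landmark files are written with `%.17g`, so
  write/read round-trips are bit-identical in all three dialects; the
  pipeline is byte-identical across reruns with the same seed.

## 5. Problem sizes and runtime

The design-scale problem (153 specimens × 18 landmarks) superimposes in
well under a second and the full pipeline (error ANOVA, GPA, PCA,
MANOVA/MANCOVA, three families of permutation tests at n_perm = 999,
discriminant analyses, mean shapes, TPS grids, figures) runs in a few
seconds. Recovery tests in the test suite run GPA on up to 800
specimens without strain.

## 6. Limitations

Beyond the generator's realism limits: the isotropic Procrustes ANOVA
understates error that concentrates on a few landmarks; Rao's F is an
approximation except when min(p, q) ≤ 2; Type III tests assume the
sum-to-zero parameterization is the comparison of interest; the
distance-correlation rule targets distance geometry, not test power, so
the retained m is a convention rather than an optimum; and LOO accuracy
from `lda_crossval()` is an honest but high-variance estimate at ~20
specimens per group.
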