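---
title: "Geometric morphometrics of rodent sperm heads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric morphometrics of rodent sperm heads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(spermshape)
library(dplyr)
```

## The problem

Rodent spermatozoa carry falciform (hooked) heads whose shape differs
markedly between even closely related species. Traditional sperm morphometry
summarizes a head by linear dimensions — head length (HL), head width (HW),
area (A), perimeter (P) — and by ratios derived from them. Those numbers are
essentially size descriptors: two heads can share every linear dimension and
still differ in the curvature of the hook, the protrusion of the base, or the
position of the flagellum insertion. Landmark-based geometric morphometrics
separates size from shape explicitly and localizes where shape differences
occur. This package implements that toolkit end to end for a 22-point sperm
head scheme, together with a three-step protocol that quantifies how much
structure the traditional descriptors miss.

## The landmark scheme

Each head is digitized as 12 fixed landmarks and 10 semilandmarks
(`sperm_roles()`): landmarks 3 and 8 span the main axis (HL), 6 and 12 the
maximum width (HW), 1 and 2 the flagellum insertion, 4 and 10 the basal
dorsal and ventral curvatures, 5 and 11 the acrosomal boundary, 7 and 9 the
hook insertions. Semilandmark 13 is the hook tip, and 14–22 are constructed
at half-distances along the hook chain; their along-curve positions are not
homologous and are relaxed ("slid") during superimposition. The slider
topology (`sperm_sliders()`) records, for every sliding point, its two chain
neighbors, which also define its tangent direction.

## Superimposition model

Shape is what remains of a landmark configuration after translation,
rotation and scale are removed. The package uses generalized least-squares
Procrustes superimposition (`gpa()`):

* every configuration is centered and scaled to unit centroid size
  (CS, the square root of summed squared landmark-to-centroid distances;
  `centroid_size()` keeps the raw value in micrometres for separate size
  analyses);
* each configuration is rotated to fit the current mean shape in the
  least-squares sense (closed 2D form, determinant +1 — reflections are
  disallowed because chirality is biologically meaningful and has been
  canonicalized upstream);
* the mean is recomputed, re-scaled to unit centroid size, and the loop
  repeats until the mean moves less than `tol = 1e-10` in partial Procrustes
  distance (`max_iter = 100`). These values are conservative: on realistic
  data the fit converges in 3–6 iterations.

The initial reference is the coordinate-wise mean of the normalized inputs
(falling back to the first specimen if rotations cancel that mean out). This
makes the fit invariant to specimen order and makes re-running `gpa()` on
aligned data converge in a single iteration.

Orientation is canonicalized before superimposition
(`canonicalize_orientation()`): a head is mirrored (`x` negated) exactly when
the signed area of the triangle through the basal pole (3), apical pole (8)
and hook tip (13) is negative. Any non-collinear triple defining chirality
would do; this one spans base, apex and hook and is robust to digitization
noise. The test is rotation-invariant, hence idempotent and compatible with
arbitrarily oriented input.

Distances between shapes (`procrustes_distance()`) are partial Procrustes
chord distances by default — the square root of summed squared differences
after centering, unit scaling, and optimal rotation — with full (scale-
optimized) distance available via `mode = "full"`. No tangent-space
projection is applied to distances; an orthogonal tangent projection is
available as an option in the regression functions (`tangent = TRUE`) but
defaults off, since the analyses operate on Procrustes coordinates directly.
At sperm-head scales the curvature of shape space is negligible (distances
of order 0.1 on a unit-radius manifold), so the choice is immaterial in
practice.

## Thin-plate splines and sliding semilandmarks

`fit_tps()` fits the standard 2D interpolating thin-plate spline with kernel
$U(r) = r^2 \log r^2$ (with $U(0) = 0$ to avoid the log singularity). Its
bending energy — the integral of squared second derivatives — is the
quadratic form of the source's bending-energy matrix evaluated at the
target, zero exactly for affine deformations. `deformation_grid()` exposes
the classical visualization: a regular grid over the reference shape warped
into the target.

Semilandmarks are relaxed by bending-energy minimization
(`slide_semilandmarks()`), the criterion that penalizes locally sharp,
biologically implausible deformations (the alternative criterion, Procrustes
distance minimization, is deliberately out of scope). Each round:

1. every specimen's sliders are displaced *jointly* along their tangent
   lines by the exact minimizer of the bending energy of the spline from the
   current mean to that specimen (a small linear solve in the tangent
   directions); fixed landmarks never move;
2. all specimens are re-superimposed and the mean is updated.

Tangents are chords between the two chain neighbors of each slider — in a
landmark-only pipeline there is no underlying pixel outline to re-project
onto, so linearized sliding is the appropriate model. Because each
within-round solve is an exact quadratic minimization, the summed bending
energy to the mean is non-increasing across rounds; the loop records this
history, stops when the improvement falls below `tol = 1e-8` (relative) or
after `max_rounds = 10`, and refuses to take a step if the mean update would
raise the criterion. In practice 3–5 rounds suffice. Sliding iterates
against the updating grand mean (not a frozen one), which is the standard
relaxation scheme.

## Traditional morphometry

`traditional_measures()` computes, per specimen: HL (distance 3–8), HW
(distance 6–12), A and P (shoelace area and perimeter of the simple polygon
through the outline landmarks, `sperm_outline()`), CS, and the four
dimensions-derived parameters

* ellipticity $= HL/HW$,
* elongation $= (HL - HW)/(HL + HW)$,
* regularity $= \pi \, HL \, HW / (4A)$,
* roughness $= 4\pi A / P^2$ (with its historical inverse `P2A` also
  reported).

On micrographs A and P would be measured from the pixel outline; with only
landmarks available, the outline polygon is a documented proxy. Ellipticity
and elongation are exact monotone transforms of one another
(elongation $= (E-1)/(E+1)$), so they carry identical information — a fact
the test suite asserts. Roughness obeys the isoperimetric bound
$4\pi A/P^2 \le 1$ for every simple closed outline, approached exactly by a
circle. Reported roughness values above 1 in parts of the sperm-morphometry
literature are therefore inconsistent with this formula as printed (they are
plausibly percentages or perimeter-to-area values); the package implements
the formula literally and leaves the bound intact.

## The statistical layer

**Shape-on-covariate regression** (`shape_regression()`) fits, coordinate by
coordinate, $Y = mX + b + r$ across all 2K = 44 Procrustes coordinates. The
summary statistic is the percentage of total shape variance predicted
(predicted sum of squares over total, in the Procrustes metric). Its
significance comes from permuting covariate values among specimens; the
p-value uses the add-one convention $(\#\{perm \ge obs\} + 1)/(B + 1)$ and
is never zero. The permuted statistic is percent-predicted itself (a
monotone alternative would be Goodall's F; with a single covariate the two
orderings agree on the permutation distribution's tail behaviour, and
percent-predicted matches the quantity reported).

**Standardization** (`standardize_shapes()`) replaces each specimen by mean
shape plus regression residual. The output contains *no* variation predicted
by the standardizing variable: re-regression yields exactly 0% (a tested
contract), per-coordinate means are preserved, and the operation is
idempotent. Multi-covariate standardization is supported by the same model
but the default protocol standardizes one variable at a time.

**Group distances** (`group_mean_distances()`) computes partial Procrustes
distances between group mean shapes — typically species means of
standardized residuals — with a per-pair permutation test that reshuffles
the two groups' labels. Matrices are tidied to long form with `tidy()`, and
the conventional flag at P < 0.0001 is reported alongside the raw p-value.

**Procrustes ANOVA** (`procrustes_anova()`) quantifies digitization error:
replicated digitizations are superimposed jointly and the Procrustes sums of
squares decompose into among-individual and residual components, with
degrees of freedom scaled by the shape-space dimension $2K - 4$ and a
Goodall-style F ratio. Replicate digitization is typically done without
semilandmarks, so `landmarks = "fixed"` restricts the decomposition to the
12 fixed points.

**Univariate ANOVA** (`univariate_anova()`) wraps the standard one-way
ANOVA with Bonferroni-adjusted pairwise t tests (family level 0.05) for the
traditional variables.

## The three-step protocol

`run_protocol()` chains the stages: canonicalize → superimpose + slide →
traditional measures → (1) ANOVAs of HL/HW/A/P/CS and the four derived
parameters across species; (2) for each standardizer, shape regression with
permutations, then standardization; (3) permutation-tested Procrustes
distances between standardized species means. If step 3 finds differences
where step 1 found none, residual shape carries structure the traditional
variable cannot express — the package's central, synthetically testable
claim. All randomness flows from one root seed through named substreams, so
a report is reproducible end to end and equals a manual stage-by-stage run
with the same substream seeds.

```{r protocol}
report <- run_protocol(
  list(n_individuals = 2, cells_per_individual = 10),
  standardizers = c("HL", "A"),
  regression_permutations = 199, distance_permutations = 199, seed = 42
)
report$step2
tidy(report$step3$HL)
```

## The synthetic generator

No specimen photographs ship with the package, so `simulate_sperm()`
generates datasets with the statistical structure the analysis assumes. The
template (`sperm_template()`) is a stylized vole-like head — an oval body
with an apical hook, head length fixed at 8 µm — whose three parameters
deform exactly the regions where species differ most: hook curvature, basal
protrusion (landmarks 4/10), and flagellum-insertion position (landmarks
1/2). Only the topological arrangement of the scheme is guaranteed, not any
species' actual outline. Semilandmarks obey their half-distance construction
rules exactly, and the outline stays a simple polygon over the whole
parameter range (a tested invariant).

The sampling design defaults to the comparative-study layout: 4 species × 5
individuals × 25 cells per individual. Per cell:

* isotropic Gaussian shape noise, scaled so `shape_noise_sd` (default 0.01)
  is the RMS Procrustes distance of a cell from its template — an
  interpretable digitization/biological noise magnitude on the shape scale;
* an optional allometric shift proportional to $\log CS - \overline{\log CS}$
  along a fixed elongation-like deformation direction (default slope 0);
* a log-normal centroid size (`size_cv` 0.06, a realistic few-percent size
  scatter; the mean defaults to each template's natural size);
* a random rotation, translation, and a reflection with probability 0.5, so
  orientation canonicalization is exercised on every run.

Cells are independent draws around their species template; the individual
label is carried in the covariates but no individual-level random effect is
added by default, which matches an analysis that treats cells as the
sampling unit. Ground truth (templates, sizes, reflection flags) is attached
for recovery tests, and `calibrate_hook_curvature()` solves for the hook
parameter placing two templates at a prescribed Procrustes distance with
identical head lengths — the construction used to demonstrate the protocol's
resolution property.

What the generator does *not* emulate: staining and imaging noise, outline
pixelation, digitizer-specific bias, individual-level shape heterogeneity,
and real species' absolute shapes. Passing tests therefore demonstrate the
*methods* — recovery of known differences under known noise — not any claim
about particular rodent taxa.

## Numerical choices and edge cases

* Degenerate configurations (all landmarks coincident) give centroid size 0
  with a warning; every downstream operation rejects them.
* Coincident thin-plate-spline source points make the system singular; the
  error names the offending pair. Coincident slider neighbors (zero tangent)
  name the specimen and slider.
* The polygon self-intersection test treats exactly-collinear adjacent
  edges (which the half-distance construction produces) as valid and flags
  only genuine crossings or collinear overlaps.
* Permutation p-values never return 0 (add-one convention); distance-matrix
  permutations reshuffle only the two groups under comparison.
* Internally all landmark indices are 1-based (R convention); slider files
  are 1-based on disk as well.
* Problem sizes in the tests and the acceptance script — hundreds of cells,
  hundreds to thousands of permutations — were chosen as the smallest sizes
  at which the Monte-Carlo checks are stable; all analyses scale linearly in
  cells and permutations.

## Known limitations

2D landmarks only; no Bookstein baseline or resistant-fit superimposition;
no relative-warp/PCA or discriminant layer; no image digitization. The
outline-polygon proxy for A and P underestimates the area of a smoothly
curved head relative to its pixel outline by a small, shape-dependent
amount, which is why the derived parameters should be compared within a
pipeline, not across digitization modalities.
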