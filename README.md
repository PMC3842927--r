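# spermshape

Landmark-based geometric morphometrics for falciform rodent sperm heads.

Rodent spermatozoa have hooked, sickle-shaped heads whose form varies
strikingly between species, strains, and treatment groups. Classical sperm
morphometry reduces a head to linear dimensions — head length (HL), head
width (HW), area (A), perimeter (P) — and ratios derived from them
(ellipticity HL/HW, elongation (HL−HW)/(HL+HW), regularity πHL·HW/4A,
roughness 4πA/P²). Those are size descriptors: heads with identical
dimensions can still differ in hook curvature, basal protrusion, or the
position of the flagellum insertion. This package is for reproductive
biologists and morphometricians who want to quantify those *shape*
differences explicitly, with the standard geometric-morphometrics machinery:

* **TPS-dialect landmark I/O** (`read_tps()`, `write_tps()`,
  `read_sliders()`, `read_covariates()`) and chirality canonicalization
  (`canonicalize_orientation()`) for a 22-point scheme (12 fixed landmarks +
  10 semilandmarks along the hook).
* **Generalized Procrustes analysis** (`gpa()`): iterative removal of
  translation, rotation and scale; centroid size
  CS = √Σᵢ‖pᵢ − p̄‖² retained per specimen as the separate size variable;
  partial Procrustes distances (`procrustes_distance()`), mean shapes.
* **Thin-plate splines** (`fit_tps()`, kernel U(r) = r² log r²): bending
  energy, **semilandmark sliding** by bending-energy minimization
  (`slide_semilandmarks()`), and deformation grids
  (`deformation_grid()` + `autoplot()`).
* **Traditional morphometry** (`traditional_measures()`) computing HL, HW,
  A, P, CS and the four dimensions-derived parameters from the landmark
  outline.
* **The statistical layer**: multivariate regression of the 44 Procrustes
  shape coordinates on any covariate with permutation tests
  (`shape_regression()`), residual standardization
  (`standardize_shapes()`), permutation-tested Procrustes distances between
  group mean shapes (`group_mean_distances()`), Procrustes ANOVA for
  digitization error (`procrustes_anova()`), and one-way ANOVAs with
  Bonferroni post-hoc tests (`univariate_anova()`).
* **A three-step comparison protocol** (`run_protocol()`): (1) traditional
  ANOVAs; (2) standardize shape on a traditional variable via
  Y = mX + b + r so no variation of that variable remains; (3) test whether
  species still differ in the residual shapes. Residual differences that
  survive step 3 are structure the traditional variable cannot see.
* **A synthetic sperm-head generator** (`simulate_sperm()`,
  `sperm_template()`, `simulate_replicates()`) emulating the comparative
  design (4 species × individuals × 25 cells, size scatter, optional
  allometry, random reflections), with ground truth attached for
  parameter-recovery checks.

Results are tibbles throughout, fitted objects have `tidy()`/`glance()`
methods, and every result type has an `autoplot()`.

## Worked example

```r
library(spermshape)

# a synthetic 4-species dataset: 2 individuals x 10 cells per species
ds  <- simulate_sperm(n_individuals = 2, cells_per_individual = 10, seed = 7)
ds  <- canonicalize_orientation(ds)
fit <- slide_semilandmarks(ds)
fit
#> <gpa_fit> 80 specimens, 22 landmarks; 4 iteration(s), converged

traditional_measures(ds)[1:3, c("specimen_id","HL","HW","A","P","roughness")]
#> # A tibble: 3 × 6
#>   specimen_id    HL    HW     A     P roughness
#>   <chr>       <dbl> <dbl> <dbl> <dbl>     <dbl>
#> 1 AS_i01_c001  9.15  4.64  26.8  22.1     0.686
#> 2 AS_i01_c002  8.03  4.09  20.7  19.4     0.694
#> 3 AS_i01_c003  8.51  4.34  23.3  20.5     0.700

rep <- run_protocol(ds, standardizers = c("HL", "A"),
                    regression_permutations = 499,
                    distance_permutations = 999, seed = 1)
rep$step2
#> # A tibble: 2 × 4
#>   variable percent_predicted     p n_permutations
#> 1 HL                    1.02 0.396            499
#> 2 A                     1.63 0.264            499

tidy(rep$step3$A)
#> # A tibble: 6 × 5
#>   group1 group2 distance p_value significant_1e4
#> 1 AS     AT       0.0314   0.001 FALSE
#> 2 AS     CG       0.0832   0.001 FALSE
#> 3 AT     CG       0.0524   0.001 FALSE
#> 4 AS     MA       0.0550   0.001 FALSE
#> 5 AT     MA       0.0302   0.001 FALSE
#> 6 CG     MA       0.0433   0.001 FALSE
```

Reading: head dimensions predict only ~1–2 % of shape variance here (the
generator's default panel has no allometry), yet after standardizing to a
common head area every species pair remains separated by a Procrustes
distance of 0.03–0.08 at the smallest attainable permutation p (0.001 at 999
permutations) — species differ in residual shape even where the traditional
variable carries no signal. Deformation-grid views of any pair:

```r
y   <- spermshape:::shapes_matrix(fit$coords)
sp  <- fit$covariates$species
m1  <- colMeans(y[sp == "AS", ]); m2 <- colMeans(y[sp == "CG", ])
autoplot(deformation_grid(matrix(m1, ncol = 2, byrow = TRUE),
                          matrix(m2, ncol = 2, byrow = TRUE)))
```

A thin CLI over the same functions lives in
`inst/scripts/sperm-protocol.R` (subcommands `simulate` and `protocol`,
flags `--config`, `--seed`, `--out-dir`).

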