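test_that("templates satisfy the scheme's structural contract", {
  tpl <- sperm_template()
  expect_equal(dim(tpl), c(22L, 2L))
  expect_equal(sum(sperm_roles() == "fixed"), 12L)
  expect_equal(sum(sperm_roles() == "semilandmark"), 10L)
  # outline is a simple polygon across the parameter space
  for (h in c(0, 0.5, 1)) {
    for (bp in c(-1, 0, 1)) {
      for (ins in c(-1, 0, 1)) {
        poly <- sperm_template(h, bp, ins)[sperm_outline(), ]
        expect_false(spermshape:::polygon_self_intersects(poly))
      }
    }
  }
  expect_error(sperm_template(hook_curvature = 1.2), "hook_curvature")
  expect_error(sperm_template(base_protrusion = -2), "base_protrusion")
})

test_that("semilandmarks sit exactly at their half-distance constructions", {
  tpl <- sperm_template(0.37, -0.2, 0.4)
  expect_equal(tpl[14, ], (tpl[7, ] + tpl[8, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[15, ], (tpl[7, ] + tpl[14, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[16, ], (tpl[14, ] + tpl[8, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[17, ], (tpl[8, ] + tpl[13, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[18, ], (tpl[17, ] + tpl[13, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[19, ], (tpl[8, ] + tpl[17, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[20, ], (tpl[9, ] + tpl[13, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[21, ], (tpl[9, ] + tpl[20, ]) / 2, tolerance = 1e-12)
  expect_equal(tpl[22, ], (tpl[13, ] + tpl[20, ]) / 2, tolerance = 1e-12)
})

test_that("hook curvature separates templates monotonically in shape space", {
  expect_gt(procrustes_distance(sperm_template(0), sperm_template(1)), 0.05)
  ref <- sperm_template(0)
  d <- vapply(seq(0.1, 1, by = 0.1),
              function(h) procrustes_distance(ref, sperm_template(h)),
              numeric(1))
  expect_true(all(diff(d) > 0))
  # head length is untouched by the hook parameter
  hl <- vapply(seq(0, 1, by = 0.25),
               function(h) linear_dimensions(sperm_template(h))$HL,
               numeric(1))
  expect_true(all(hl == 8))
})

test_that("calibrate_hook_curvature hits a requested separation", {
  h2 <- calibrate_hook_curvature(0.08, reference_curvature = 0.2)
  expect_equal(
    procrustes_distance(sperm_template(0.2), sperm_template(h2)), 0.08,
    tolerance = 1e-8)
  expect_error(calibrate_hook_curvature(10), "reach")
})

test_that("simulate_sperm is deterministic and honors the sampling design", {
  ds1 <- simulate_sperm(n_individuals = 5, cells_per_individual = 25,
                        seed = 123)
  expect_equal(dim(ds1), c(22L, 2L, 500L))
  expect_equal(nrow(ds1$covariates), 500L)
  expect_equal(unname(table(ds1$covariates$species)), rep(125L, 4),
               ignore_attr = TRUE)
  expect_equal(length(unique(ds1$covariates$individual)), 20L)
  ds2 <- simulate_sperm(n_individuals = 5, cells_per_individual = 25,
                        seed = 123)
  expect_identical(ds1$coords, ds2$coords)
  expect_identical(ds1$covariates, ds2$covariates)
})

test_that("the noise-free limit reproduces each template exactly", {
  ds <- simulate_sperm(n_individuals = 1, cells_per_individual = 5,
                       shape_noise_sd = 0, size_cv = 0, reflect_prob = 0,
                       seed = 5)
  truth <- attr(ds, "truth")
  for (sp in names(truth$templates)) {
    sel <- which(ds$covariates$species == sp)
    for (i in sel) {
      expect_lt(procrustes_distance(ds$coords[, , i], truth$templates[[sp]]),
                1e-8)
    }
  }
  # gpa on the noise-free single-species subset recovers the template
  sub <- ds[which(ds$covariates$species == "AS")]
  fit <- gpa(sub)
  expect_lt(procrustes_distance(fit$mean, truth$templates[["AS"]]), 1e-8)
})

test_that("species mean shapes are recoverable from noisy data", {
  ds <- simulate_sperm(n_individuals = 4, cells_per_individual = 25,
                       shape_noise_sd = 0.01, seed = 9)
  ds <- canonicalize_orientation(ds)
  truth <- attr(ds, "truth")
  fit <- gpa(ds)
  y <- spermshape:::shapes_matrix(fit$coords)
  for (sp in names(truth$templates)) {
    m <- colMeans(y[fit$covariates$species == sp, ])
    d <- procrustes_distance(spermshape:::vector_shape(m),
                             truth$templates[[sp]])
    expect_lt(d, 0.01)
  }
})

test_that("reflections are injected and canonicalization undoes them", {
  ds <- simulate_sperm(n_individuals = 2, cells_per_individual = 10,
                       seed = 21)
  refl <- ds$covariates$reflected
  expect_gt(sum(refl), 0)
  expect_gt(sum(!refl), 0)
  canon <- canonicalize_orientation(ds)
  truth <- attr(ds, "truth")
  # every canonicalized cell is close to its template irrespective of the flag
  for (i in seq_len(20)) {
    sp <- ds$covariates$species[i]
    expect_lt(procrustes_distance(canon$coords[, , i], truth$templates[[sp]]),
              0.05)
  }
})

test_that("allometry induces a detectable size-shape regression", {
  ds0 <- simulate_sperm(n_individuals = 2, cells_per_individual = 20,
                        allometry_slope = 0, size_cv = 0.15, seed = 30)
  ds1 <- simulate_sperm(n_individuals = 2, cells_per_individual = 20,
                        allometry_slope = 0.3, size_cv = 0.15, seed = 30)
  f0 <- gpa(canonicalize_orientation(ds0))
  f1 <- gpa(canonicalize_orientation(ds1))
  r0 <- shape_regression(f0, log(unname(f0$centroid_sizes)),
                         n_permutations = 0)
  r1 <- shape_regression(f1, log(unname(f1$centroid_sizes)),
                         n_permutations = 0)
  expect_gt(r1$percent_predicted, 3 * r0$percent_predicted)
})

test_that("simulated centroid sizes follow the requested distribution", {
  ds <- simulate_sperm(n_individuals = 5, cells_per_individual = 20,
                       size_mean = 12, size_cv = 0.05, shape_noise_sd = 0,
                       seed = 44)
  cs <- unname(centroid_size(ds))
  expect_equal(mean(cs), 12, tolerance = 0.15)
  expect_equal(sd(cs) / mean(cs), 0.05, tolerance = 0.02)
  expect_equal(cs, unname(ds$covariates$true_size), tolerance = 1e-8)
})

test_that("simulate_replicates duplicates specimens with labeled noise", {
  base <- make_tiny_dataset(n = 3, seed = 2)
  reps0 <- simulate_replicates(base, replicate_error_sd = 0, seed = 1)
  expect_equal(dim(reps0)[3], 15L)
  expect_equal(unname(table(reps0$covariates$specimen)), rep(5L, 3),
               ignore_attr = TRUE)
  # zero noise: replicates identical to their originals
  for (i in seq_len(15)) {
    orig <- reps0$covariates$specimen[i]
    expect_equal(reps0$coords[, , i], base$coords[, , orig],
                 ignore_attr = TRUE)
  }
  reps <- simulate_replicates(base, replicate_error_sd = 0.05, seed = 1)
  expect_gt(max(abs(reps$coords[, , 1] - base$coords[, , 1])), 0)
  expect_error(simulate_replicates(base, -1), ">= 0")
  expect_error(simulate_replicates(base, 0.1, n_replicates = 1),
               "at least 2")
})

test_that("synthetic datasets round-trip through the on-disk layout", {
  ds <- simulate_sperm(n_individuals = 1, cells_per_individual = 3, seed = 3)
  dir <- withr::local_tempdir()
  write_synthetic(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("data.tps", "sliders.txt", "covariates.csv", "truth.json")))))
  back <- read_tps(file.path(dir, "data.tps"),
                   sliders = read_sliders(file.path(dir, "sliders.txt")))
  expect_lt(max(abs(back$coords - ds$coords)), 1e-6)
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_equal(cov$specimen_id, ds$covariates$specimen_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(names(truth$templates)), sort(c("AS", "AT", "CG", "MA")))
})
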