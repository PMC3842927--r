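make_fit_with_covariate <- function(n = 12, slope_scale = 0.02, seed = 55,
                                    noise = 0) {
  # shapes constructed as an exact (or noisy) linear function of a covariate
  withr::with_seed(seed, {
    tpl <- normalize_template()
    direction <- matrix(rnorm(44), 22, 2)
    direction <- direction / sqrt(sum(direction^2))
    xv <- seq(-1, 1, length.out = n)
    configs <- lapply(seq_len(n), function(i) {
      tpl + slope_scale * xv[i] * direction +
        matrix(rnorm(44, 0, noise), 22, 2)
    })
    names(configs) <- paste0("s", seq_len(n))
    list(configs = configs, covariate = xv)
  })
}

normalize_template <- function() {
  tpl <- sperm_template()
  ctr <- sweep(tpl, 2, colMeans(tpl))
  ctr / sqrt(sum(ctr^2))
}

test_that("shape_regression recovers a perfect linear trend", {
  made <- make_fit_with_covariate(n = 10)
  y <- t(vapply(made$configs, function(m) as.vector(t(m)), numeric(44)))
  reg <- shape_regression(y, made$covariate, n_permutations = 99, seed = 1)
  expect_equal(reg$percent_predicted, 100, tolerance = 1e-6)
  expect_equal(reg$permutation_p, 1 / 100)
})

test_that("slopes and intercepts match per-coordinate least squares from lm", {
  # 3 specimens, hand-checkable covariate {0, 1, 2}
  y <- rbind(c(1, 2, 0.5, -1), c(1.4, 1.9, 0.8, -0.7), c(2.1, 2.2, 0.9, -0.6))
  xv <- c(0, 1, 2)
  reg <- shape_regression(y, xv, n_permutations = 0)
  for (j in 1:4) {
    co <- stats::coef(stats::lm(y[, j] ~ xv))
    expect_equal(reg$intercept[j], unname(co[1]), tolerance = 1e-12)
    expect_equal(reg$slope[j], unname(co[2]), tolerance = 1e-12)
  }
})

test_that("regression satisfies the Pythagorean decomposition", {
  ds <- simulate_sperm(n_individuals = 2, cells_per_individual = 5, seed = 77)
  fit <- gpa(canonicalize_orientation(ds))
  reg <- shape_regression(fit, "true_size", n_permutations = 0)
  y <- spermshape:::shapes_matrix(fit$coords)
  yc <- sweep(y, 2, colMeans(y))
  ss_tot <- sum(yc^2)
  ss_res <- sum(reg$residuals^2)
  ss_pred <- ss_tot * reg$percent_predicted / 100
  expect_equal(ss_pred + ss_res, ss_tot, tolerance = 1e-9 * ss_tot)
  # residuals are uncorrelated with the covariate, coordinate by coordinate
  xc <- reg$covariate - mean(reg$covariate)
  expect_lt(max(abs(crossprod(xc, reg$residuals))), 1e-9)
})

test_that("shape_regression validates its inputs", {
  y <- matrix(rnorm(20), 5, 4)
  expect_error(shape_regression(y, rep(1, 5)), "constant")
  expect_error(shape_regression(y[1:2, ], 1:2), "at least 3")
  expect_error(shape_regression(y, c(1, 2, NA, 4, 5)), "missing")
  expect_error(shape_regression(y, 1:3), "one value per specimen")
})

test_that("standardization removes all covariate-predicted variation", {
  made <- make_fit_with_covariate(n = 15, noise = 0.003, seed = 8)
  y <- t(vapply(made$configs, function(m) as.vector(t(m)), numeric(44)))
  std <- standardize_shapes(y, made$covariate, covariate_name = "HL")
  reg_after <- shape_regression(std, made$covariate, n_permutations = 0)
  expect_lt(reg_after$percent_predicted, 1e-9)
  # idempotence: standardizing already-standardized data changes nothing
  std2 <- standardize_shapes(std, made$covariate)
  expect_equal(std2$shapes, std$shapes, tolerance = 1e-12)
  # per-coordinate means preserved
  expect_equal(colMeans(std$shapes), colMeans(y), tolerance = 1e-12)
})

test_that("permutation p-values are calibrated under the null", {
  # type-I error of the seeded permutation test across null replicates
  n <- 12
  runs <- 100
  hits <- 0
  tpl <- normalize_template()
  for (s in seq_len(runs)) {
    withr::with_seed(1000 + s, {
      y <- t(vapply(seq_len(n), function(i) {
        as.vector(t(tpl + matrix(rnorm(44, 0, 0.01), 22, 2)))
      }, numeric(44)))
      xv <- rnorm(n)
    })
    reg <- shape_regression(y, xv, n_permutations = 99, seed = s)
    if (reg$permutation_p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.01)
  expect_lte(hits / runs, 0.10)
})

test_that("group distances recover a known species separation", {
  h2 <- calibrate_hook_curvature(0.1, reference_curvature = 0.1)
  sp <- tibble::tibble(species = c("S1", "S2"),
                       hook_curvature = c(0.1, h2),
                       base_protrusion = 0, insertion_shift = 0)
  ds <- simulate_sperm(sp, n_individuals = 1, cells_per_individual = 25,
                       shape_noise_sd = 0.01, seed = 12)
  fit <- gpa(canonicalize_orientation(ds))
  gd <- group_mean_distances(fit, "species", n_permutations = 499, seed = 3)
  expect_gt(gd$distances[1, 2], 0.08)
  expect_lt(gd$distances[1, 2], 0.12)
  expect_lte(gd$p_values[1, 2], 0.01)
})

test_that("group distances are near zero for groups from one template", {
  ds <- simulate_sperm(
    tibble::tibble(species = c("A", "B"), hook_curvature = 0.5,
                   base_protrusion = 0, insertion_shift = 0),
    n_individuals = 1, cells_per_individual = 10, shape_noise_sd = 0.01,
    seed = 31)
  fit <- gpa(canonicalize_orientation(ds))
  gd <- group_mean_distances(fit, "species", n_permutations = 199, seed = 4)
  expect_lt(gd$distances[1, 2], 0.02)
  expect_gt(gd$p_values[1, 2], 0.05)
  # invariance to label and specimen order
  perm <- sample(seq_len(20))
  y <- spermshape:::shapes_matrix(fit$coords)
  gd2 <- group_mean_distances(y[perm, ], fit$covariates$species[perm],
                              n_permutations = 0)
  expect_equal(gd2$distances, gd$distances, tolerance = 1e-12)
})

test_that("group distance contracts: identical groups and degenerate input", {
  y <- matrix(rnorm(80), 8, 10)
  g <- rep(c("a", "b"), each = 4)
  # duplicated labels -> the same specimens in both groups -> distance 0
  gd <- group_mean_distances(rbind(y[1:4, ], y[1:4, ]),
                             rep(c("a", "b"), each = 4), n_permutations = 0)
  expect_equal(gd$distances[1, 2], 0, tolerance = 1e-9)
  expect_error(group_mean_distances(y, rep("a", 8)), "at least 2 groups")
  expect_error(group_mean_distances(y, c("a", rep("b", 7))), "fewer than 2")
})

test_that("procrustes ANOVA partitions sums of squares like a hand computation", {
  # two individuals x two replicates of pre-aligned unit-size shapes
  tpl <- normalize_template()
  d1 <- matrix(0.01, 22, 2)
  d2 <- matrix(c(0.005, -0.01), 22, 2, byrow = TRUE)
  configs <- list(a1 = tpl + d1, a2 = tpl + d1 + 0.001,
                  b1 = tpl - d2, b2 = tpl - d2 - 0.001)
  cov <- tibble::tibble(specimen_id = names(configs),
                        specimen = c("a", "a", "b", "b"))
  ds <- gm_dataset(configs, sperm_roles(), covariates = cov)
  res <- procrustes_anova(ds)
  # independent decomposition on the aligned coordinates
  fit <- gpa(ds)
  y <- spermshape:::shapes_matrix(fit$coords)
  grand <- colMeans(y)
  ma <- colMeans(y[1:2, ])
  mb <- colMeans(y[3:4, ])
  ss_ind <- 2 * sum((ma - grand)^2) + 2 * sum((mb - grand)^2)
  ss_err <- sum(sweep(y[1:2, ], 2, ma)^2) + sum(sweep(y[3:4, ], 2, mb)^2)
  expect_equal(res$effect_SS, ss_ind, tolerance = 1e-10)
  expect_equal(res$error_SS, ss_err, tolerance = 1e-10)
  expect_equal(res$effect_df, 1 * (2 * 22 - 4))
  expect_equal(res$error_df, 2 * (2 * 22 - 4))
  expect_equal(res$F, (ss_ind / res$effect_df) / (ss_err / res$error_df))
})

test_that("procrustes ANOVA flags zero digitization error", {
  tpl <- sperm_template()
  configs <- list(a1 = tpl, a2 = tpl, b1 = 2 * tpl + 0.3, b2 = 2 * tpl + 0.3)
  cov <- tibble::tibble(specimen_id = names(configs),
                        specimen = c("a", "a", "b", "b"))
  ds <- gm_dataset(configs, sperm_roles(), covariates = cov)
  expect_warning(res <- procrustes_anova(ds), "infinite")
  expect_equal(res$error_SS, 0)
  expect_identical(res$F, Inf)
})

test_that("procrustes ANOVA recovers the variance-component ordering", {
  # digitization error an order of magnitude below individual variation
  tpl <- sperm_template()
  ok <- 0
  ratios <- numeric(10)
  for (s in 1:10) {
    withr::with_seed(200 + s, {
      inds <- lapply(1:10, function(i) tpl + matrix(rnorm(44, 0, 0.27), 22, 2))
      names(inds) <- paste0("i", 1:10)
    })
    base <- gm_dataset(inds, sperm_roles())
    reps <- simulate_replicates(base, replicate_error_sd = 0.027,
                                n_replicates = 5, seed = 300 + s)
    res <- procrustes_anova(reps, landmarks = "fixed")
    ratios[s] <- res$effect_MS / res$error_MS
    if (res$error_MS < res$effect_MS) ok <- ok + 1
  }
  expect_equal(ok, 10L)
  expect_true(all(ratios > 5))
})

test_that("procrustes ANOVA rejects single replicates", {
  tpl <- sperm_template()
  configs <- list(a1 = tpl + 0.01, a2 = tpl - 0.01, b1 = 2 * tpl)
  cov <- tibble::tibble(specimen_id = names(configs),
                        specimen = c("a", "a", "b"))
  ds <- gm_dataset(configs, sperm_roles(), covariates = cov)
  expect_error(procrustes_anova(ds), "single replicate")
})

test_that("univariate ANOVA matches a hand-computed F on a textbook layout", {
  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 13, 8, 17, 13, 14, 12)
  grp <- rep(c("g1", "g2", "g3"), c(6, 6, 4))
  res <- univariate_anova(vals, grp)
  # direct one-way decomposition
  grand <- mean(vals)
  ss_b <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  f_hand <- (ss_b / 2) / (ss_w / 13)
  expect_equal(res$anova$F, f_hand, tolerance = 1e-10)
  expect_equal(res$anova$df_between, 2)
  expect_equal(res$anova$df_within, 13)
  expect_equal(nrow(res$pairwise), 3L)
})

test_that("univariate ANOVA handles null identity and validates input", {
  res <- univariate_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p, 1)
  expect_error(univariate_anova(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
  expect_error(univariate_anova(1:4, c("a", "a", "a", "b")),
               "at least 2 members")
})

test_that("four groups yield six Bonferroni pairs at alpha/6", {
  withr::with_seed(2, vals <- rnorm(20))
  grp <- rep(c("a", "b", "c", "d"), each = 5)
  res <- univariate_anova(vals, grp)
  expect_equal(nrow(res$pairwise), 6L)
  expect_equal(unique(res$pairwise$alpha_per_pair), 0.05 / 6)
})

test_that("higher resolution of residual-shape analysis over a shared trait", {
  # two species share the HL distribution but differ in hook shape: the
  # traditional ANOVA on HL sees nothing while standardized residual shapes
  # separate clearly
  h2 <- calibrate_hook_curvature(0.1, reference_curvature = 0.1)
  sp <- tibble::tibble(species = c("S1", "S2"),
                       hook_curvature = c(0.1, h2),
                       base_protrusion = 0, insertion_shift = 0)
  ds <- simulate_sperm(sp, n_individuals = 5, cells_per_individual = 5,
                       shape_noise_sd = 0.01, seed = 1)
  ds <- canonicalize_orientation(ds)
  meas <- traditional_measures(ds)
  grp <- ds$covariates$species
  an <- univariate_anova(dplyr::mutate(meas, g = grp), "HL", "g")
  expect_gt(an$anova$p, 0.05)
  fit <- gpa(ds)
  std <- standardize_shapes(fit, meas$HL, covariate_name = "HL")
  std$covariates <- ds$covariates
  gd <- group_mean_distances(std, grp, n_permutations = 999, seed = 2)
  expect_lte(gd$p_values[1, 2], 0.01)
  expect_gt(gd$distances[1, 2], 0.05)
})
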