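#' Run the three-step traditional-vs-geometric comparison protocol
#'
#' Step 1 (traditional analysis): one-way ANOVAs with Bonferroni post-hoc
#' tests of the linear dimensions (HL, HW, A, P), centroid size, and the four
#' dimensions-derived parameters across groups. Step 2 (standardization): for
#' each requested standardizing variable, multivariate regression of the
#' Procrustes shape coordinates on that variable with a permutation test, then
#' replacement of each specimen by mean shape plus residual so no variation of
#' the variable remains. Step 3 (residual geometric morphometrics): Procrustes
#' distances between group mean shapes of the standardized data with per-pair
#' permutation tests. If shape differences persist in step 3 where step 1 saw
#' none, geometric morphometrics resolves structure the traditional variables
#' cannot.
#'
#' @param x a [gm_dataset()] with a group column in its covariates, or a named
#'   list of [simulate_sperm()] arguments.
#' @param standardizers subset of `HL`, `HW`, `A`, `P`, `CS`, `ellipticity`,
#'   `elongation`, `regularity`, `roughness` (default the four size
#'   variables).
#' @param group name of the group covariate column (default `"species"`).
#' @param regression_permutations permutations for step-2 regressions
#'   (default 1000).
#' @param distance_permutations permutations per step-3 pair (default 10000).
#' @param slide slide semilandmarks before analysis when a slider topology is
#'   present (default `TRUE`).
#' @param seed root seed; all permutation and simulation streams are derived
#'   from it, so a seed reproduces the full report.
#' @return A `protocol_report`: `step1` (ANOVA tibble per variable),
#'   `step1_pairwise`, `step2` (regression table: Variable, % predicted, P),
#'   `regressions`, `step3` (named list of [group_mean_distances()] results),
#'   `measures`, `fit`, `provenance`.
#' @export
run_protocol <- function(x, standardizers = c("HL", "HW", "A", "CS"),
                         group = "species", regression_permutations = 1000L,
                         distance_permutations = 10000L, slide = TRUE,
                         seed = NULL) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  if (!inherits(x, "gm_dataset")) {
    if (!is.list(x)) rlang::abort("x must be a gm_dataset or a simulation spec")
    x$seed <- x$seed %||% substream_seed(seed, "simulation")
    x <- do.call(simulate_sperm, x)
  }
  valid <- c("HL", "HW", "A", "P", "CS", "ellipticity", "elongation",
             "regularity", "roughness")
  bad <- setdiff(standardizers, valid)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown standardizer(s) %s; valid names: %s",
                         paste(bad, collapse = ", "),
                         paste(valid, collapse = ", ")))
  }
  if (is.null(x$covariates) || !group %in% names(x$covariates)) {
    rlang::abort(sprintf("covariates must contain a '%s' column", group))
  }
  ds <- canonicalize_orientation(x)
  fit <- if (slide && !is.null(ds$sliders)) slide_semilandmarks(ds) else gpa(ds)
  measures <- traditional_measures(ds)
  groups <- as.character(ds$covariates[[group]])

  step1_fits <- purrr::map(valid, function(v) {
    univariate_anova(dplyr::mutate(measures, .group = groups), v, ".group")
  })
  names(step1_fits) <- valid
  step1 <- dplyr::bind_rows(purrr::map(step1_fits, "anova"))
  step1_pairwise <- purrr::map(step1_fits, "pairwise")

  regressions <- list()
  step3 <- list()
  for (v in standardizers) {
    covariate <- measures[[v]]
    regressions[[v]] <- shape_regression(
      fit, covariate, n_permutations = regression_permutations,
      seed = substream_seed(seed, paste0("regression:", v)),
      covariate_name = v)
    std <- standardize_shapes(fit, covariate, covariate_name = v)
    std$covariates <- ds$covariates
    step3[[v]] <- group_mean_distances(
      std, groups, n_permutations = distance_permutations,
      seed = substream_seed(seed, paste0("distances:", v)))
  }
  step2 <- tibble::tibble(
    variable = standardizers,
    percent_predicted = unname(purrr::map_dbl(regressions,
                                              "percent_predicted")),
    p = unname(purrr::map_dbl(regressions, "permutation_p")),
    n_permutations = regression_permutations
  )
  structure(
    list(
      step1 = step1, step1_pairwise = step1_pairwise,
      step2 = step2, regressions = regressions, step3 = step3,
      measures = measures, fit = fit, group = group,
      provenance = list(
        seed = seed,
        standardizers = standardizers,
        config_hash = rlang::hash(list(standardizers, group,
                                       regression_permutations,
                                       distance_permutations, slide)),
        package_version = as.character(utils::packageVersion("spermshape"))
      )
    ),
    class = "protocol_report"
  )
}

# deterministic per-purpose seed below 2^31, derived from the root seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("<protocol_report>\n\nStep 1: traditional ANOVAs\n")
  print(as.data.frame(x$step1), digits = 4)
  cat("\nStep 2: shape-on-variable regressions\n")
  print(as.data.frame(x$step2), digits = 4)
  cat("\nStep 3: Procrustes distances between standardized group means\n")
  for (v in names(x$step3)) {
    cat(sprintf("  common %s:\n", v))
    m <- x$step3[[v]]$distances
    print(round(m, 4))
  }
  invisible(x)
}

#' Write a protocol report to disk
#'
#' Emits `step1_anova.csv`, `step2_regressions.csv`, one
#' `step3_distances_<variable>.csv` per standardizer (with matching p-value
#' columns), the traditional measures table, and a JSON report with
#' provenance.
#'
#' @param report a [run_protocol()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol_report <- function(report, dir) {
  stopifnot(inherits(report, "protocol_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$step1, file.path(dir, "step1_anova.csv"))
  readr::write_csv(report$step2, file.path(dir, "step2_regressions.csv"))
  readr::write_csv(report$measures, file.path(dir, "measures.csv"))
  for (v in names(report$step3)) {
    readr::write_csv(
      generics::tidy(report$step3[[v]]),
      file.path(dir, sprintf("step3_distances_%s.csv", v))
    )
  }
  jsonlite::write_json(
    list(
      step1 = report$step1,
      step2 = report$step2,
      step3 = purrr::map(report$step3, generics::tidy),
      provenance = report$provenance
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
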