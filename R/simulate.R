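#' Default synthetic species panel
#'
#' Four stylized vole-like species whose templates differ where rodent sperm
#' heads differ most: hook curvature, protrusion of the base of the head, and
#' the position of the flagellum insertion.
#'
#' @return A tibble with columns `species`, `hook_curvature`,
#'   `base_protrusion`, `insertion_shift`.
#' @export
default_species <- function() {
  tibble::tibble(
    species = c("AS", "AT", "CG", "MA"),
    hook_curvature = c(0.15, 0.35, 0.75, 0.55),
    base_protrusion = c(0.3, 0.1, -0.4, 0.5),
    insertion_shift = c(0.2, -0.1, -0.3, 0.4)
  )
}

#' Simulate a multi-species sperm head landmark dataset
#'
#' Emulates the sampling design of a comparative sperm morphometry study:
#' several species, several individuals per species, 25 digitized cells per
#' individual. Each cell starts from its species template (unit centroid
#' size), receives isotropic Gaussian shape noise scaled so that
#' `shape_noise_sd` is the root-mean-square Procrustes offset of a cell from
#' its template (per-coordinate sd `shape_noise_sd / sqrt(2K)`), an optional
#' allometric shape shift proportional to
#' `log(CS) - mean log(CS)` along a fixed elongation-like deformation
#' direction, is scaled to a log-normally distributed centroid size, and is
#' then randomly rotated, translated, and reflected with probability 1/2 —
#' the reflection exercising [canonicalize_orientation()] on every run.
#'
#' @param species a tibble like [default_species()] (optionally with a
#'   per-species `size_mean` column), or `NULL` for the default panel.
#' @param n_individuals individuals per species (default 5).
#' @param cells_per_individual digitized cells per individual (default 25).
#' @param shape_noise_sd digitization/cell-shape noise magnitude on the
#'   Procrustes distance scale (default 0.01).
#' @param size_mean mean centroid size in micrometres; `NULL` (default) keeps
#'   each template's natural size (head length 8 um).
#' @param size_cv coefficient of variation of centroid size (default 0.06).
#' @param allometry_slope shape displacement per unit log-size (default 0).
#' @param reflect_prob probability a cell is digitized mirrored (default 0.5).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A [gm_dataset()] with sperm roles and sliders, covariates
#'   (`specimen_id`, `species`, `individual`, `true_size`, `reflected`), and a
#'   `truth` attribute recording the unit-size species templates, the template
#'   parameters, and per-cell sizes.
#' @export
simulate_sperm <- function(species = NULL, n_individuals = 5L,
                           cells_per_individual = 25L,
                           shape_noise_sd = 0.01, size_mean = NULL,
                           size_cv = 0.06, allometry_slope = 0,
                           reflect_prob = 0.5, seed = NULL) {
  species <- species %||% default_species()
  species <- tibble::as_tibble(species)
  if (anyDuplicated(species$species)) rlang::abort("species names must be unique")
  if (cells_per_individual < 1) rlang::abort("cells_per_individual must be >= 1")
  if (shape_noise_sd < 0 || size_cv < 0) rlang::abort("sigmas must be >= 0")
  templates <- purrr::pmap(
    species[c("hook_curvature", "base_protrusion", "insertion_shift")],
    function(hook_curvature, base_protrusion, insertion_shift) {
      sperm_template(hook_curvature, base_protrusion, insertion_shift)
    })
  names(templates) <- species$species
  shapes0 <- purrr::map(templates, normalize_config)
  dir <- allometry_direction()
  sdlog <- sqrt(log(1 + size_cv^2))
  withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    configs <- list()
    rows <- list()
    truth_sizes <- numeric(0)
    for (s in seq_len(nrow(species))) {
      sp <- species$species[s]
      mu_cs <- if (!is.null(species[["size_mean"]])) species$size_mean[s]
               else size_mean %||% centroid_size(templates[[s]])
      meanlog <- log(mu_cs) - sdlog^2 / 2
      for (ind in seq_len(n_individuals)) {
        for (cell in seq_len(cells_per_individual)) {
          id <- sprintf("%s_i%02d_c%03d", sp, ind, cell)
          cs_i <- stats::rlnorm(1, meanlog, sdlog)
          shp <- shapes0[[s]] +
            matrix(stats::rnorm(44, 0, shape_noise_sd / sqrt(44)), 22, 2)
          if (allometry_slope != 0) {
            shp <- shp + allometry_slope * (log(cs_i) - meanlog) * dir
          }
          shp <- center_config(shp)
          cfg <- shp / sqrt(sum(shp^2)) * cs_i
          refl <- stats::runif(1) < reflect_prob
          if (refl) cfg[, 1] <- -cfg[, 1]
          th <- stats::runif(1, 0, 2 * pi)
          rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
          cfg <- cfg %*% rot
          cfg <- sweep(cfg, 2, stats::rnorm(2, 0, 10), `+`)
          colnames(cfg) <- c("x", "y")
          configs[[id]] <- cfg
          rows[[id]] <- tibble::tibble(
            specimen_id = id, species = sp,
            individual = sprintf("%s_i%02d", sp, ind),
            true_size = cs_i, reflected = refl
          )
          truth_sizes[id] <- cs_i
        }
      }
    }
    out <- gm_dataset(configs, roles = sperm_roles(),
                      sliders = sperm_sliders(),
                      covariates = dplyr::bind_rows(rows))
    attr(out, "truth") <- list(
      species = species, templates = shapes0, sizes = truth_sizes,
      shape_noise_sd = shape_noise_sd, allometry_slope = allometry_slope
    )
    out
  })
}

# fixed elongation-like unit deformation of the default template shape:
# compress x, stretch y, centered and orthogonalized against pure scaling
allometry_direction <- function() {
  s0 <- normalize_config(sperm_template())
  d <- cbind(-s0[, 1], s0[, 2])
  d <- center_config(d)
  d <- d - sum(d * s0) * s0
  d / sqrt(sum(d^2))
}

#' Simulate replicated digitizations of each specimen
#'
#' Duplicates every specimen `n_replicates` times with independent Gaussian
#' digitization noise added to each coordinate, emulating one observer
#' re-measuring the same cells on several occasions, for use with
#' [procrustes_anova()].
#'
#' @param x a [gm_dataset()].
#' @param replicate_error_sd digitization noise sd, in the coordinate units of
#'   `x` (micrometres); must be `>= 0`.
#' @param n_replicates digitizations per specimen (default 5, `>= 2`).
#' @param seed integer seed.
#' @return A [gm_dataset()] whose covariates carry `specimen` (the original
#'   identity) and `replicate`.
#' @export
simulate_replicates <- function(x, replicate_error_sd, n_replicates = 5L,
                                seed = NULL) {
  stopifnot(inherits(x, "gm_dataset"))
  if (replicate_error_sd < 0) rlang::abort("replicate_error_sd must be >= 0")
  if (n_replicates < 2) rlang::abort("need at least 2 replicates")
  k <- n_landmarks(x)
  withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    configs <- list()
    rows <- list()
    for (i in seq_len(n_specimens(x))) {
      base_id <- specimen_ids(x)[i]
      for (r in seq_len(n_replicates)) {
        id <- sprintf("%s_r%d", base_id, r)
        configs[[id]] <- x$coords[, , i] +
          matrix(stats::rnorm(2 * k, 0, replicate_error_sd), k, 2)
        rows[[id]] <- tibble::tibble(specimen_id = id, specimen = base_id,
                                     replicate = r)
      }
    }
    gm_dataset(configs, roles = x$roles, sliders = x$sliders,
               covariates = dplyr::bind_rows(rows))
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `data.tps`, `sliders.txt`, `covariates.csv`, and (when present) the
#' ground-truth record `truth.json`.
#'
#' @param x a [gm_dataset()], typically from [simulate_sperm()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(x, file.path(dir, "data.tps"))
  if (!is.null(x$sliders)) {
    write_sliders(x$sliders, file.path(dir, "sliders.txt"))
  }
  if (!is.null(x$covariates)) {
    readr::write_csv(x$covariates, file.path(dir, "covariates.csv"))
  }
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(
        species = truth$species,
        templates = purrr::map(truth$templates, ~ unname(as.matrix(.x))),
        sizes = as.list(truth$sizes),
        shape_noise_sd = truth$shape_noise_sd,
        allometry_slope = truth$allometry_slope
      ),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
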