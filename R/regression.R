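#' Multivariate regression of shape on a covariate with a permutation test
#'
#' Fits, coordinate by coordinate, the linear model
#' `(Y1, ..., Y2K) = (m1, ..., m2K) X + (b1, ..., b2K) + (r1, ..., r2K)`
#' of the Procrustes shape coordinates on a mean-centered covariate. The
#' summary statistic is the percentage of total shape variance predicted,
#' `100 * SS_predicted / SS_total` summed over all coordinates in the
#' Procrustes metric; its significance is assessed by permuting covariate
#' values among specimens. The permutation p-value uses the add-one
#' convention `(count >= observed + 1) / (n_permutations + 1)` and so is never
#' zero.
#'
#' @param x a [gpa()]/[slide_semilandmarks()] fit, or an `n x 2K` matrix of
#'   shape coordinates.
#' @param covariate a numeric vector (one value per specimen, in specimen
#'   order) or the name of a numeric column of the fit's covariate table.
#' @param n_permutations number of permutations (default 1000).
#' @param seed optional integer seed for the permutations.
#' @param tangent if `TRUE`, shapes are orthogonally projected onto the
#'   tangent space at the mean shape before regression; default `FALSE`
#'   (Procrustes coordinates are used directly).
#' @param covariate_name label used in reports.
#' @return A `shape_regression` object with `slope`, `intercept` (length-2K
#'   vectors), `residuals` (`n x 2K`), `fitted`, `percent_predicted`,
#'   `permutation_p`, `n_permutations`, `covariate`, `covariate_name`. The
#'   Pythagorean decomposition `SS_total = SS_predicted + SS_residual` holds to
#'   numerical precision, and residuals are uncorrelated with the covariate.
#' @export
shape_regression <- function(x, covariate, n_permutations = 1000L,
                             seed = NULL, tangent = FALSE,
                             covariate_name = NULL) {
  prep <- resolve_shapes_covariate(x, covariate, covariate_name)
  y <- prep$y
  xv <- prep$covariate
  n <- nrow(y)
  if (n < 3) rlang::abort("shape regression needs at least 3 specimens")
  if (anyNA(xv)) {
    rlang::abort(sprintf("missing covariate values for specimens: %s",
                         paste(rownames(y)[is.na(xv)], collapse = ", ")))
  }
  if (stats::var(xv) == 0) {
    rlang::abort("constant covariate: cannot regress shape on it")
  }
  if (tangent) y <- tangent_project(y)
  ybar <- colMeans(y)
  yc <- sweep(y, 2, ybar)
  xc <- xv - mean(xv)
  sxx <- sum(xc^2)
  slope <- as.vector(crossprod(xc, yc)) / sxx
  fitted_c <- outer(xc, slope)
  resid <- yc - fitted_c
  ss_total <- sum(yc^2)
  ss_pred <- sum(fitted_c^2)
  pct <- 100 * ss_pred / ss_total
  perm_pct <- numeric(0)
  p <- NA_real_
  if (n_permutations > 0) {
    perm_pct <- withr::with_seed(
      seed %||% sample.int(.Machine$integer.max, 1), {
        vapply(seq_len(n_permutations), function(b) {
          xp <- xc[sample.int(n)]
          100 * sum(as.vector(crossprod(xp, yc))^2 / sum(xp^2)) / ss_total
        }, numeric(1))
      })
    p <- (sum(perm_pct >= pct) + 1) / (n_permutations + 1)
  }
  structure(
    list(
      slope = slope,
      intercept = ybar - slope * mean(xv),
      mean = ybar,
      residuals = resid,
      fitted = sweep(fitted_c, 2, ybar, `+`),
      percent_predicted = pct,
      permutation_p = p,
      n_permutations = n_permutations,
      covariate = xv,
      covariate_name = prep$covariate_name,
      specimen_ids = rownames(y),
      tangent = tangent
    ),
    class = "shape_regression"
  )
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf(
    "<shape_regression> shape ~ %s: %.2f%% of variance predicted, permutation P = %s (%d permutations)\n",
    x$covariate_name, x$percent_predicted,
    format.pval(x$permutation_p, digits = 3), x$n_permutations))
  invisible(x)
}

#' Standardize shape coordinates to a common covariate value
#'
#' Removes all shape variation predicted by a traditional variable: each
#' specimen is replaced by the mean shape plus its regression residual, so the
#' output carries only residual variation and re-regressing it on the same
#' covariate predicts exactly 0% of variance. Per-coordinate means are
#' preserved, and the operation is idempotent.
#'
#' @inheritParams shape_regression
#' @return A `standardized_shapes` object: `shapes` (`n x 2K` matrix),
#'   `covariate_name`, and the covariate table carried over from the fit.
#' @export
standardize_shapes <- function(x, covariate, covariate_name = NULL,
                               tangent = FALSE) {
  reg <- shape_regression(x, covariate, n_permutations = 0L,
                          covariate_name = covariate_name, tangent = tangent)
  shapes <- sweep(reg$residuals, 2, reg$mean, `+`)
  rownames(shapes) <- reg$specimen_ids
  structure(
    list(shapes = shapes, covariate_name = reg$covariate_name,
         covariates = if (inherits(x, "gpa_fit")) x$covariates else NULL),
    class = "standardized_shapes"
  )
}

#' @export
print.standardized_shapes <- function(x, ...) {
  cat(sprintf("<standardized_shapes> %d specimens standardized to common %s\n",
              nrow(x$shapes), x$covariate_name))
  invisible(x)
}

# common input plumbing: shapes matrix + covariate vector + name
resolve_shapes_covariate <- function(x, covariate, covariate_name = NULL) {
  if (inherits(x, "gpa_fit")) {
    y <- shapes_matrix(x$coords)
  } else if (inherits(x, "standardized_shapes")) {
    y <- x$shapes
  } else {
    y <- as.matrix(x)
  }
  if (is.character(covariate) && length(covariate) == 1) {
    nm <- covariate
    if (identical(nm, "CS") && inherits(x, "gpa_fit")) {
      covariate <- unname(x$centroid_sizes)
    } else {
      cov_tab <- if (inherits(x, "gpa_fit")) x$covariates else NULL
      if (is.null(cov_tab) || !nm %in% names(cov_tab)) {
        rlang::abort(sprintf("no covariate column named '%s'", nm))
      }
      covariate <- cov_tab[[nm]]
    }
    covariate_name <- covariate_name %||% nm
  }
  if (length(covariate) != nrow(y)) {
    rlang::abort("covariate must have one value per specimen")
  }
  list(y = y, covariate = as.numeric(covariate),
       covariate_name = covariate_name %||% "covariate")
}

# orthogonal projection of unit-size shape rows onto the tangent plane at the
# (unit-vector) mean shape
tangent_project <- function(y) {
  m <- colMeans(y)
  m <- m / sqrt(sum(m^2))
  proj <- y - outer(as.vector(y %*% m), m)
  sweep(proj, 2, m, `+`)
}
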