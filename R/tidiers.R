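#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape regression
#'
#' @param x a [shape_regression()] result.
#' @param ... unused.
#' @return A tibble with one row per shape coordinate: `coordinate`, `slope`,
#'   `intercept`.
#' @method tidy shape_regression
#' @export
tidy.shape_regression <- function(x, ...) {
  tibble::tibble(
    coordinate = names(x$slope) %||%
      paste0(rep(c("x", "y"), length(x$slope) / 2),
             rep(seq_len(length(x$slope) / 2), each = 2)),
    slope = unname(x$slope),
    intercept = unname(x$intercept)
  )
}

#' @rdname tidy.shape_regression
#' @method glance shape_regression
#' @export
glance.shape_regression <- function(x, ...) {
  tibble::tibble(
    covariate = x$covariate_name,
    percent_predicted = x$percent_predicted,
    p_value = x$permutation_p,
    n_permutations = x$n_permutations,
    n = length(x$covariate)
  )
}

#' Tidy a group distance matrix
#'
#' @param x a [group_mean_distances()] result.
#' @param ... unused.
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `distance`, `p_value`, and a flag at the conventional P < 0.0001 level.
#' @method tidy group_distances
#' @export
tidy.group_distances <- function(x, ...) {
  idx <- which(upper.tri(x$distances), arr.ind = TRUE)
  tibble::tibble(
    group1 = x$labels[idx[, 1]],
    group2 = x$labels[idx[, 2]],
    distance = x$distances[idx],
    p_value = x$p_values[idx],
    significant_1e4 = x$p_values[idx] < 1e-4
  )
}

#' Tidy a Procrustes ANOVA
#'
#' @param x a [procrustes_anova()] result.
#' @param ... unused.
#' @return A tibble with rows `individual` and `error`.
#' @method tidy procrustes_anova
#' @export
tidy.procrustes_anova <- function(x, ...) {
  tibble::tibble(
    term = c("individual", "error"),
    SS = c(x$effect_SS, x$error_SS),
    df = c(x$effect_df, x$error_df),
    MS = c(x$effect_MS, x$error_MS),
    F = c(x$F, NA),
    p = c(x$p, NA)
  )
}

#' @rdname tidy.procrustes_anova
#' @method glance procrustes_anova
#' @export
glance.procrustes_anova <- function(x, ...) {
  tibble::tibble(F = x$F, p = x$p, n_individuals = x$n_individuals,
                 n_observations = x$n_observations)
}

#' Tidy a univariate ANOVA with post-hoc tests
#'
#' @param x a [univariate_anova()] result.
#' @param ... unused.
#' @return `tidy()` returns the Bonferroni pairwise comparisons; `glance()`
#'   the one-row ANOVA summary.
#' @method tidy trad_anova
#' @export
tidy.trad_anova <- function(x, ...) x$pairwise

#' @rdname tidy.trad_anova
#' @method glance trad_anova
#' @export
glance.trad_anova <- function(x, ...) x$anova
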