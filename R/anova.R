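#' Procrustes ANOVA for digitization measurement error
#'
#' Superimposes all replicated digitizations jointly, then decomposes the
#' Procrustes sums of squares of the aligned coordinates into an
#' among-individual component and a residual (digitization error) component.
#' Degrees of freedom are scaled by the shape-space dimension `2K - 4`
#' (Goodall-style), and `F = MS_individual / MS_error` is referred to an F
#' distribution. Intra-observer error is negligible when the error mean square
#' is well below the individual mean square.
#'
#' @param x a [gm_dataset()] whose covariate table identifies, for every
#'   record, which individual it is a digitization of.
#' @param specimen name of the covariate column giving the individual identity
#'   (default `"specimen"`). Every individual needs at least 2 replicates.
#' @param landmarks `"all"` or `"fixed"`; `"fixed"` drops semilandmarks first,
#'   matching replicate digitization done without semilandmarks.
#' @return A `procrustes_anova` object with `effect_SS`, `error_SS`,
#'   `effect_df`, `error_df`, `effect_MS`, `error_MS`, `F`, `p`, and the table
#'   as a tibble via [generics::tidy()]. Zero error SS yields `F = Inf` with a
#'   warning.
#' @export
procrustes_anova <- function(x, specimen = "specimen",
                             landmarks = c("all", "fixed")) {
  landmarks <- match.arg(landmarks)
  stopifnot(inherits(x, "gm_dataset"))
  if (is.null(x$covariates) || !specimen %in% names(x$covariates)) {
    rlang::abort(sprintf("covariates must contain a '%s' column", specimen))
  }
  ind <- as.character(x$covariates[[specimen]])
  counts <- table(ind)
  if (length(counts) < 2) rlang::abort("need at least 2 individuals")
  if (any(counts < 2)) {
    rlang::abort(sprintf("individuals with a single replicate: %s",
                         paste(names(counts)[counts < 2], collapse = ", ")))
  }
  ds <- x
  if (landmarks == "fixed") {
    keep <- which(x$roles == "fixed")
    ds <- gm_dataset(x$coords[keep, , , drop = FALSE],
                     roles = x$roles[keep], covariates = x$covariates)
  }
  fit <- gpa(ds)
  y <- shapes_matrix(fit$coords)
  k <- dim(fit$coords)[1]
  dim_shape <- 2L * k - 4L
  grand <- colMeans(y)
  means <- rowsum(y, ind) / as.vector(counts[sort(unique(ind))])
  # align row order of means with counts
  counts <- counts[rownames(means)]
  ss_ind <- sum(as.vector(counts) * rowSums(sweep(means, 2, grand)^2))
  ss_err <- sum((y - means[ind, , drop = FALSE])^2)
  a <- nrow(means)
  n <- nrow(y)
  df_ind <- (a - 1L) * dim_shape
  df_err <- (n - a) * dim_shape
  ms_ind <- ss_ind / df_ind
  ms_err <- ss_err / df_err
  if (ss_err == 0) {
    rlang::warn("zero digitization error sum of squares; F is infinite")
    f <- Inf
    p <- 0
  } else {
    f <- ms_ind / ms_err
    p <- stats::pf(f, df_ind, df_err, lower.tail = FALSE)
  }
  structure(
    list(effect_SS = ss_ind, error_SS = ss_err,
         effect_df = df_ind, error_df = df_err,
         effect_MS = ms_ind, error_MS = ms_err,
         F = f, p = p, landmarks = landmarks, n_individuals = a,
         n_observations = n),
    class = "procrustes_anova"
  )
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("<procrustes_anova> individual vs digitization error\n")
  tab <- data.frame(
    SS = c(x$effect_SS, x$error_SS),
    df = c(x$effect_df, x$error_df),
    MS = c(x$effect_MS, x$error_MS),
    F = c(x$F, NA),
    p = c(x$p, NA),
    row.names = c("individual", "error")
  )
  print(tab)
  invisible(x)
}

#' One-way ANOVA with Bonferroni post-hoc tests
#'
#' Tests whether group means of a univariate measure differ, and which pairs
#' differ, with pairwise t tests Bonferroni-adjusted at family level 0.05.
#'
#' @param data a data frame, or a numeric vector of values (in which case
#'   `value` is taken as the group labels).
#' @param value name of the numeric column (or, for the vector interface, the
#'   group label vector).
#' @param group name of the group label column. Every group needs at least 2
#'   members; at least one group must have nonzero within-group variance.
#' @return A `trad_anova` object: `anova` (one-row tibble: `df_between`,
#'   `df_within`, `F`, `p`) and `pairwise` (tibble of group pairs with
#'   Bonferroni-adjusted p-values and the adjusted per-pair alpha).
#' @export
univariate_anova <- function(data, value, group = NULL) {
  if (is.data.frame(data)) {
    values <- data[[value]]
    groups <- data[[group]]
    label <- value
  } else {
    values <- data
    groups <- value
    label <- "value"
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) rlang::abort("need at least 2 groups")
  if (any(table(groups) < 2)) {
    rlang::abort("every group needs at least 2 members")
  }
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    rlang::abort("zero within-group variance in every group")
  }
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  if (an$`Sum Sq`[1] == 0) {
    f <- 0
    p <- 1
  }
  pw <- stats::pairwise.t.test(values, groups,
                               p.adjust.method = "bonferroni")$p.value
  pairs <- which(!is.na(pw), arr.ind = TRUE)
  n_pairs <- choose(nlevels(groups), 2)
  pairwise <- tibble::tibble(
    group1 = rownames(pw)[pairs[, 1]],
    group2 = colnames(pw)[pairs[, 2]],
    p_adjusted = pw[pairs],
    alpha_per_pair = 0.05 / n_pairs,
    significant = pw[pairs] < 0.05
  )
  structure(
    list(
      variable = label,
      anova = tibble::tibble(
        variable = label,
        df_between = an$Df[1], df_within = an$Df[2],
        F = f, p = p
      ),
      pairwise = pairwise
    ),
    class = "trad_anova"
  )
}

#' @export
print.trad_anova <- function(x, ...) {
  cat(sprintf("<trad_anova> %s: F(%d, %d) = %.4g, p = %s\n",
              x$variable, x$anova$df_between, x$anova$df_within, x$anova$F,
              format.pval(x$anova$p, digits = 3)))
  invisible(x)
}
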