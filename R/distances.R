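#' Procrustes distances between group mean shapes with permutation tests
#'
#' Computes the partial (or full) Procrustes distance between every pair of
#' group mean shapes — typically species means of standardized regression
#' residuals — and a per-pair permutation p-value obtained by reshuffling the
#' two groups' labels and recomputing the mean-shape distance. P-values use
#' the add-one convention and are never zero.
#'
#' @param x a [gpa()] fit, a [standardize_shapes()] result, or an `n x 2K`
#'   matrix of shape coordinates.
#' @param groups a label per specimen, or the name of a column of the carried
#'   covariate table. Every group needs at least 2 members.
#' @param n_permutations permutations per pair (default 10000).
#' @param seed optional integer seed.
#' @param mode Procrustes distance mode, `"partial"` (default) or `"full"`.
#' @return A `group_distances` object: `labels`, symmetric `distances` and
#'   `p_values` matrices, `n_permutations`. Tidy with [generics::tidy()].
#' @export
group_mean_distances <- function(x, groups, n_permutations = 10000L,
                                 seed = NULL, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  y <- if (inherits(x, "gpa_fit")) shapes_matrix(x$coords)
       else if (inherits(x, "standardized_shapes")) x$shapes
       else as.matrix(x)
  if (is.character(groups) && length(groups) == 1) {
    cov_tab <- if (inherits(x, "gpa_fit") ||
                   inherits(x, "standardized_shapes")) x$covariates else NULL
    if (is.null(cov_tab) || !groups %in% names(cov_tab)) {
      rlang::abort(sprintf("no covariate column named '%s'", groups))
    }
    groups <- cov_tab[[groups]]
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(y)) {
    rlang::abort("groups must have one label per specimen")
  }
  labels <- sort(unique(groups))
  if (length(labels) < 2) rlang::abort("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    rlang::abort(sprintf("groups with fewer than 2 members: %s",
                         paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  g <- length(labels)
  d <- matrix(0, g, g, dimnames = list(labels, labels))
  p <- matrix(NA_real_, g, g, dimnames = list(labels, labels))
  diag(p) <- 1
  pair_distance <- function(ymat, idx1) {
    m1 <- colMeans(ymat[idx1, , drop = FALSE])
    m2 <- colMeans(ymat[-idx1, , drop = FALSE])
    procrustes_distance(vector_shape(m1), vector_shape(m2), mode = mode)
  }
  withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    for (i in seq_len(g - 1)) {
      for (j in (i + 1):g) {
        sel <- groups %in% c(labels[i], labels[j])
        yp <- y[sel, , drop = FALSE]
        idx1 <- which(groups[sel] == labels[i])
        obs <- pair_distance(yp, idx1)
        d[i, j] <- d[j, i] <- obs
        if (n_permutations > 0) {
          np <- nrow(yp)
          n1 <- length(idx1)
          hits <- sum(vapply(seq_len(n_permutations), function(b) {
            pair_distance(yp, sample.int(np, n1)) >= obs
          }, logical(1)))
          p[i, j] <- p[j, i] <- (hits + 1) / (n_permutations + 1)
        }
      }
    }
  })
  structure(
    list(labels = labels, distances = d, p_values = p,
         n_permutations = n_permutations, mode = mode),
    class = "group_distances"
  )
}

#' @export
print.group_distances <- function(x, ...) {
  cat(sprintf(
    "<group_distances> %s Procrustes distances between %d group means (%d permutations)\n",
    x$mode, length(x$labels), x$n_permutations))
  print(round(x$distances, 4))
  invisible(x)
}
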