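#' Slide semilandmarks by bending-energy minimization
#'
#' Runs generalized Procrustes analysis and then iteratively relaxes the
#' semilandmarks: in each round, every specimen's sliding points are displaced
#' along their tangent direction (the chord between the two chain neighbors of
#' each slider) by the joint displacement that minimizes the bending energy of
#' the thin-plate spline from the current Procrustes mean shape to that
#' specimen, after which all specimens are re-superimposed and the mean is
#' recomputed. Fixed landmarks never move. Because each within-round solve is
#' an exact quadratic minimization, the summed bending energy to the mean is
#' non-increasing across rounds; the loop stops when it stabilizes (or would
#' increase through the mean update), or after `max_rounds`.
#'
#' @param x a [gm_dataset()] carrying a slider topology (or pass `sliders`).
#' @param sliders optional `m x 3` matrix (before, slider, after; 1-based)
#'   overriding `x$sliders`.
#' @param max_rounds maximum sliding rounds (default 10).
#' @param tol stop when the relative change in total bending energy falls
#'   below `tol` (default 1e-8).
#' @param gpa_tol,gpa_max_iter superimposition controls passed to the
#'   Procrustes loop.
#' @return A `gpa_fit` (see [gpa()]) with extra fields `slid = TRUE`, `rounds`,
#'   and `bending_energy_history` (total bending energy to the mean after the
#'   initial superimposition and after each round).
#' @export
slide_semilandmarks <- function(x, sliders = NULL, max_rounds = 10L,
                                tol = 1e-8, gpa_tol = 1e-10,
                                gpa_max_iter = 100L) {
  if (!inherits(x, "gm_dataset")) {
    rlang::abort("slide_semilandmarks expects a gm_dataset")
  }
  sliders <- if (is.null(sliders)) x$sliders else
    validate_sliders(sliders, x$roles)
  if (is.null(sliders)) {
    rlang::abort("no slider topology available")
  }
  fit <- gpa(x, tol = gpa_tol, max_iter = gpa_max_iter)
  n <- dim(fit$coords)[3]
  total_be <- function(coords, be_mat) {
    sum(vapply(seq_len(dim(coords)[3]), function(i) {
      y <- coords[, , i]
      sum(y[, 1] * (be_mat %*% y[, 1])) + sum(y[, 2] * (be_mat %*% y[, 2]))
    }, numeric(1)))
  }
  be_mat <- bending_energy_matrix(fit$mean)
  history <- total_be(fit$coords, be_mat)
  rounds <- 0L
  coords <- fit$coords
  m <- fit$mean
  for (r in seq_len(max_rounds)) {
    new_coords <- coords
    for (i in seq_len(n)) {
      new_coords[, , i] <- slide_one(coords[, , i], be_mat, sliders,
                                     dimnames(coords)[[3]][i])
    }
    # re-superimpose the slid configurations
    for (i in seq_len(n)) new_coords[, , i] <- normalize_config(new_coords[, , i])
    it <- 0L
    repeat {
      it <- it + 1L
      for (i in seq_len(n)) {
        new_coords[, , i] <- new_coords[, , i] %*%
          optimal_rotation(new_coords[, , i], m)
      }
      m_new <- mean_shape(new_coords)
      delta <- procrustes_distance(m, m_new)
      m <- m_new
      if (delta < gpa_tol || it >= gpa_max_iter) break
    }
    be_mat_new <- bending_energy_matrix(m)
    be_new <- total_be(new_coords, be_mat_new)
    be_old <- history[length(history)]
    if (be_new > be_old + 1e-12) {
      # the mean update would raise the criterion; keep the previous state
      break
    }
    coords <- new_coords
    be_mat <- be_mat_new
    rounds <- r
    history <- c(history, be_new)
    if (be_old - be_new < tol * max(be_old, 1e-300)) break
  }
  fit$coords <- coords
  fit$mean <- mean_shape(coords)
  fit$sliders <- sliders
  fit$slid <- TRUE
  fit$rounds <- rounds
  fit$bending_energy_history <- history
  fit
}

# one specimen: joint tangent-direction displacement of all sliders minimizing
# tr(Y' B Y); tangents from the specimen's own chain neighbors
slide_one <- function(y, be_mat, sliders, specimen_id) {
  s <- sliders[, "slider"]
  u <- y[sliders[, "after"], , drop = FALSE] -
    y[sliders[, "before"], , drop = FALSE]
  len <- sqrt(rowSums(u^2))
  if (any(len < 1e-12)) {
    bad <- which(len < 1e-12)[1]
    rlang::abort(sprintf(
      "specimen %s: slider %d has coincident neighbors (zero tangent)",
      specimen_id, s[bad]))
  }
  u <- u / len
  g <- be_mat[s, , drop = FALSE] %*% y          # m x 2
  bvec <- rowSums(g * u)
  a <- be_mat[s, s, drop = FALSE] * tcrossprod(u)
  t_hat <- tryCatch(
    solve(a, -bvec),
    error = function(e) {
      solve(a + diag(1e-10 * mean(diag(a)), nrow(a)), -bvec)
    }
  )
  y[s, ] <- y[s, ] + t_hat * u
  y
}
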