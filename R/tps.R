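#' Thin-plate spline interpolation between two landmark configurations
#'
#' Fits the standard 2D interpolating thin-plate spline with kernel
#' `U(r) = r^2 log(r^2)` (with `U(0) = 0`) mapping each source landmark exactly
#' onto its target landmark. The deformation decomposes into an affine part and
#' a non-affine warp whose bending energy — the integral of squared second
#' derivatives — is the quadratic form of the source's bending-energy matrix
#' evaluated at the target; it is zero exactly when the target is an affine
#' image of the source.
#'
#' @param source,target `K x 2` coordinate matrices, `K >= 3`, source points
#'   not all collinear and pairwise distinct.
#' @return A `tps_transform`: `source`, `target`, `affine` (3 x 2 coefficients
#'   of `1, x, y`), `warp` (K x 2 kernel weights), `bending_energy`, and the
#'   `bending_energy_matrix` of the source.
#' @seealso [apply_tps()], [deformation_grid()], [slide_semilandmarks()]
#' @export
fit_tps <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (!identical(dim(source), dim(target))) {
    rlang::abort("source and target must have the same number of landmarks")
  }
  k <- nrow(source)
  if (k < 3) rlang::abort("a thin-plate spline needs at least 3 landmarks")
  dup <- duplicated_pair(source)
  if (!is.null(dup)) {
    rlang::abort(sprintf("coincident source landmarks %d and %d", dup[1],
                         dup[2]))
  }
  be_mat <- bending_energy_matrix(source)
  km <- tps_kernel_matrix(source, source)
  p <- cbind(1, source)
  l <- rbind(cbind(km, p), cbind(t(p), matrix(0, 3, 3)))
  sol <- solve(l, rbind(target, matrix(0, 3, 2)))
  warp <- sol[seq_len(k), , drop = FALSE]
  affine <- sol[k + 1:3, , drop = FALSE]
  be <- sum(target[, 1] * (be_mat %*% target[, 1])) +
    sum(target[, 2] * (be_mat %*% target[, 2]))
  structure(
    list(source = source, target = target, affine = affine, warp = warp,
         bending_energy = max(0, be), bending_energy_matrix = be_mat),
    class = "tps_transform"
  )
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d landmarks, bending energy %.6g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

duplicated_pair <- function(x) {
  d <- as.matrix(stats::dist(x))
  d[upper.tri(d, diag = TRUE)] <- Inf
  hit <- which(d < 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0) NULL else c(hit[1, 2], hit[1, 1])
}

# U(r) = r^2 log r^2 kernel between two point sets (rows)
tps_kernel_matrix <- function(a, b) {
  r2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  r2[r2 < 1e-300] <- 1 # U(0) = 0 via log(1)
  r2 * log(r2)
}

#' Bending-energy matrix of a landmark configuration
#'
#' The `K x K` matrix `B` such that the bending energy of a thin-plate spline
#' from this configuration to any target `Y` is `tr(Y' B Y)`. `B` is symmetric,
#' positive semi-definite, and annihilates affine targets.
#'
#' @param source a `K x 2` coordinate matrix (`K >= 3`, not all collinear).
#' @return A `K x K` matrix.
#' @export
bending_energy_matrix <- function(source) {
  source <- as.matrix(source)
  k <- nrow(source)
  km <- tps_kernel_matrix(source, source)
  p <- cbind(1, source)
  l <- rbind(cbind(km, p), cbind(t(p), matrix(0, 3, 3)))
  li <- tryCatch(solve(l), error = function(e) {
    rlang::abort("singular thin-plate spline system (collinear or coincident landmarks)")
  })
  b <- li[seq_len(k), seq_len(k), drop = FALSE]
  (b + t(b)) / 2
}

#' Evaluate a thin-plate spline at query points
#'
#' @param transform a fitted [fit_tps()] transform.
#' @param query a `m x 2` matrix of points to map.
#' @return The warped `m x 2` coordinates; exact at the source landmarks.
#' @export
apply_tps <- function(transform, query) {
  stopifnot(inherits(transform, "tps_transform"))
  query <- rbind(as.matrix(query))
  if (!all(is.finite(query))) rlang::abort("non-finite query points")
  u <- tps_kernel_matrix(query, transform$source)
  cbind(1, query) %*% transform$affine + u %*% transform$warp
}

#' Thin-plate spline deformation grid between two shapes
#'
#' Lays a regular grid over the reference shape's bounding box (expanded by a
#' margin fraction) and maps every node through the thin-plate spline deforming
#' the reference into the target — the classical visualization of mean-shape
#' differences between species.
#'
#' @param reference,target `K x 2` coordinate matrices of equal `K`.
#' @param rows,cols grid dimensions, both at least 2 (default 20 x 20).
#' @param margin bounding-box expansion as a fraction of the box size
#'   (default 0.1).
#' @return A `deformation_grid` tibble with columns `row`, `col`, `x0`, `y0`
#'   (undeformed node) and `x`, `y` (warped node); the reference and target
#'   shapes are attached as attributes. Plot with [ggplot2::autoplot()].
#' @export
deformation_grid <- function(reference, target, rows = 20L, cols = 20L,
                             margin = 0.1) {
  if (rows < 2 || cols < 2) {
    rlang::abort("a deformation grid needs at least 2 rows and 2 columns")
  }
  reference <- as.matrix(reference)
  target <- as.matrix(target)
  rng_x <- range(reference[, 1])
  rng_y <- range(reference[, 2])
  pad_x <- margin * diff(rng_x)
  pad_y <- margin * diff(rng_y)
  xs <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = cols)
  ys <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = rows)
  nodes <- as.matrix(expand.grid(x0 = xs, y0 = ys))
  tr <- fit_tps(reference, target)
  warped <- apply_tps(tr, nodes)
  out <- tibble::tibble(
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    x0 = nodes[, 1], y0 = nodes[, 2],
    x = warped[, 1], y = warped[, 2]
  )
  attr(out, "reference") <- reference
  attr(out, "target") <- target
  attr(out, "bending_energy") <- tr$bending_energy
  class(out) <- c("deformation_grid", class(out))
  out
}
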