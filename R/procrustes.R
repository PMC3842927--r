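#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between every landmark and
#' the configuration centroid — the geometric-morphometric size measure that is
#' uncorrelated with shape in the absence of allometry.
#'
#' @param x a `K x 2` coordinate matrix, or a [gm_dataset()] (one value per
#'   specimen).
#' @return Centroid size in micrometres (a named vector for datasets). A
#'   configuration whose points all coincide returns 0 with a warning.
#' @export
centroid_size <- function(x) {
  if (inherits(x, "gm_dataset")) {
    return(vapply(seq_len(n_specimens(x)),
                  function(i) centroid_size(x$coords[, , i]),
                  numeric(1), USE.NAMES = FALSE) |>
             stats::setNames(specimen_ids(x)))
  }
  x <- as.matrix(x)
  cs <- sqrt(sum(sweep(x, 2, colMeans(x))^2))
  if (cs == 0) {
    rlang::warn("degenerate configuration: all landmarks coincide")
  }
  cs
}

center_config <- function(x) sweep(x, 2, colMeans(x))

# center + unit centroid size; errors on degenerate input
normalize_config <- function(x) {
  xc <- center_config(x)
  cs <- sqrt(sum(xc^2))
  if (cs == 0) rlang::abort("degenerate configuration (centroid size 0)")
  xc / cs
}

# optimal rotation matrix R (det +1) minimizing ||X R - M||^2, rows = points.
# Closed 2D form: maximize tr(R'A) with A = X'M.
optimal_rotation <- function(x, m) {
  a <- crossprod(x, m)
  theta <- atan2(a[2, 1] - a[1, 2], a[1, 1] + a[2, 2])
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the similarity transform (rotation, scale, translation) minimizing the
#' summed squared distances between the transformed target and the reference.
#'
#' @param target,reference `K x 2` coordinate matrices with equal `K`.
#' @param allow_reflection if `TRUE` the fit may include a reflection;
#'   default `FALSE` (determinant +1), preserving the biological left/right
#'   convention set by [canonicalize_orientation()].
#' @return A list with `rotation` (2 x 2), `angle` (radians), `scale`,
#'   `translation` (length 2), `aligned` (transformed target), `rss` (residual
#'   sum of squares) and `reflected`.
#' @export
opa_align <- function(target, reference, allow_reflection = FALSE) {
  target <- as.matrix(target)
  reference <- as.matrix(reference)
  if (!identical(dim(target), dim(reference))) {
    rlang::abort("target and reference must have the same number of landmarks")
  }
  tc <- colMeans(target)
  rc <- colMeans(reference)
  x <- sweep(target, 2, tc)
  m <- sweep(reference, 2, rc)
  if (sum(x^2) == 0 || sum(m^2) == 0) {
    rlang::abort("degenerate configuration (centroid size 0)")
  }
  rot <- optimal_rotation(x, m)
  reflected <- FALSE
  if (allow_reflection) {
    # candidate with reflection: flip x of target, re-solve rotation
    xr <- x %*% diag(c(-1, 1))
    rot_r <- optimal_rotation(xr, m)
    gain <- sum(diag(crossprod(x %*% rot, m)))
    gain_r <- sum(diag(crossprod(xr %*% rot_r, m)))
    if (gain_r > gain) {
      x <- xr
      rot <- rot_r
      reflected <- TRUE
    }
  }
  s <- sum(diag(crossprod(x %*% rot, m))) / sum(x^2)
  aligned <- sweep(s * (x %*% rot), 2, rc, `+`)
  list(
    rotation = rot,
    angle = atan2(rot[2, 1], rot[1, 1]),
    scale = s,
    translation = rc - s * as.vector(tc %*% rot),
    aligned = aligned,
    rss = sum((aligned - reference)^2),
    reflected = reflected
  )
}

#' Procrustes distance between two shapes
#'
#' Both configurations are centered and scaled to unit centroid size, the
#' optimal rotation is removed, and the square root of the summed squared
#' inter-landmark distances is returned. `"partial"` optimizes rotation only;
#' `"full"` additionally optimizes scale.
#'
#' @param a,b `K x 2` coordinate matrices with equal `K`.
#' @param mode `"partial"` (default) or `"full"`.
#' @return A dimensionless distance; 0 for identical shapes.
#' @export
procrustes_distance <- function(a, b, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) {
    rlang::abort("configurations must have the same number of landmarks")
  }
  x <- normalize_config(a)
  y <- normalize_config(b)
  rot <- optimal_rotation(y, x)
  yr <- y %*% rot
  if (mode == "full") {
    s <- sum(yr * x) # optimal scale for unit-norm shapes = cos(rho)
    sqrt(max(0, sum((x - s * yr)^2)))
  } else {
    sqrt(max(0, sum((x - yr)^2)))
  }
}

#' Mean shape of aligned configurations
#'
#' Coordinate-wise arithmetic mean, re-centered and re-scaled to unit centroid
#' size.
#'
#' @param shapes a `K x 2 x n` array of aligned configurations, or a list of
#'   `K x 2` matrices.
#' @return A `K x 2` matrix with unit centroid size.
#' @export
mean_shape <- function(shapes) {
  if (is.list(shapes)) {
    shapes <- array(unlist(shapes), dim = c(dim(shapes[[1]]), length(shapes)))
  }
  if (length(dim(shapes)) == 2L) shapes <- array(shapes, c(dim(shapes), 1L))
  if (dim(shapes)[3] < 1) rlang::abort("mean_shape needs at least one shape")
  m <- apply(shapes, c(1, 2), mean)
  colnames(m) <- c("x", "y")
  normalize_config(m)
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition: every configuration is centered and
#' scaled to unit centroid size, aligned by rotation to the running mean shape,
#' and the mean is recomputed until it changes by less than `tol` in partial
#' Procrustes distance. Raw centroid sizes are retained per specimen so size
#' can be analyzed separately from shape.
#'
#' @param x a [gm_dataset()] or `K x 2 x n` array with at least 2 specimens.
#' @param tol convergence tolerance on the mean-shape change (default 1e-10).
#' @param max_iter maximum iterations (default 100).
#' @return A `gpa_fit`: `coords` (`K x 2 x n` aligned, unit centroid size),
#'   `mean` (`K x 2`), `centroid_sizes` (micrometres, named), `roles`,
#'   `sliders`, `covariates`, `iterations`, `converged`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  ds <- if (inherits(x, "gm_dataset")) x else
    gm_dataset(x, roles = rep("fixed", dim(x)[1]))
  n <- n_specimens(ds)
  if (n < 2) rlang::abort("gpa needs at least 2 configurations")
  cs <- centroid_size(ds)
  coords <- ds$coords
  for (i in seq_len(n)) coords[, , i] <- normalize_config(coords[, , i])
  # initial reference: naive coordinate-wise mean (order-invariant, and a
  # no-op on already-aligned data); fall back to the first configuration if
  # the inputs' rotations cancel it out
  m <- tryCatch(mean_shape(coords), error = function(e) coords[, , 1])
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      coords[, , i] <- coords[, , i] %*% optimal_rotation(coords[, , i], m)
    }
    m_new <- mean_shape(coords)
    delta <- procrustes_distance(m, m_new)
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
  }
  structure(
    list(coords = coords, mean = m, centroid_sizes = cs, roles = ds$roles,
         sliders = ds$sliders, covariates = ds$covariates,
         iterations = iterations, converged = converged),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf(
    "<gpa_fit> %d specimens, %d landmarks; %d iteration(s), %s\n",
    dim(x$coords)[3], dim(x$coords)[1], x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Aligned shapes as a wide tibble
#'
#' @param x a `gpa_fit`.
#' @param ... unused.
#' @return A tibble with `specimen_id`, `centroid_size`, and shape coordinate
#'   columns `x1, y1, ..., xK, yK` (2K columns; 44 for the sperm scheme).
#' @method as_tibble gpa_fit
#' @export
as_tibble.gpa_fit <- function(x, ...) {
  mat <- shapes_matrix(x$coords)
  out <- tibble::tibble(
    specimen_id = dimnames(x$coords)[[3]],
    centroid_size = unname(x$centroid_sizes)
  )
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

# K x 2 x n array -> n x 2K matrix with columns x1, y1, ..., xK, yK
shapes_matrix <- function(coords) {
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  out <- matrix(aperm(coords, c(2, 1, 3)), nrow = n, ncol = 2L * k,
                byrow = TRUE)
  colnames(out) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  rownames(out) <- dimnames(coords)[[3]]
  out
}

# n x 2K matrix -> K x 2 x n array
matrix_shapes <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat) / 2L
  aperm(array(t(mat), dim = c(2L, k, n),
              dimnames = list(c("x", "y"), NULL, rownames(mat))),
        c(2, 1, 3))
}

# row vector (2K) -> K x 2 matrix
vector_shape <- function(v) {
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}
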