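#' Linear head dimensions from a landmark configuration
#'
#' Head length (HL) is the distance between the basal and apical points of
#' maximum length (landmarks 3 and 8); head width (HW) the distance between
#' the dorsal and ventral maximum-width landmarks (6 and 12). Head area (A)
#' and perimeter (P) are computed on the simple polygon through the outline
#' landmarks — a proxy for the pixel outline measured on micrographs, using the
#' only geometry a landmark dataset carries. The polygon is normalized
#' counter-clockwise and the shoelace area reported as an absolute value.
#'
#' @param config a `K x 2` coordinate matrix in micrometres containing the
#'   22-point sperm scheme (or compatible indices).
#' @param outline_order landmark indices tracing the head outline; default
#'   [sperm_outline()].
#' @return A one-row tibble with `HL`, `HW` and `P` in micrometres and `A` in
#'   square micrometres.
#' @export
linear_dimensions <- function(config, outline_order = sperm_outline()) {
  config <- as.matrix(config)
  need <- max(12L, max(outline_order))
  if (nrow(config) < need) {
    rlang::abort(sprintf("configuration has %d landmarks; %d required",
                         nrow(config), need))
  }
  poly <- config[outline_order, , drop = FALSE]
  if (polygon_self_intersects(poly)) {
    rlang::abort("outline polygon is self-intersecting")
  }
  a2 <- shoelace_signed(poly)
  if (a2 < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  tibble::tibble(
    HL = sqrt(sum((config[3, ] - config[8, ])^2)),
    HW = sqrt(sum((config[6, ] - config[12, ])^2)),
    A = abs(shoelace_signed(poly)),
    P = polygon_perimeter(poly)
  )
}

shoelace_signed <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

# strict test: any two non-adjacent edges properly crossing, or collinear
# non-adjacent edges overlapping over positive length
polygon_self_intersects <- function(poly, eps = 1e-12) {
  n <- nrow(poly)
  seg <- function(i) list(a = poly[i, ], b = poly[i %% n + 1, ])
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (sharing a vertex), incl. the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      s1 <- seg(i)
      s2 <- seg(j)
      d1 <- cross2(s1$a, s1$b, s2$a)
      d2 <- cross2(s1$a, s1$b, s2$b)
      d3 <- cross2(s2$a, s2$b, s1$a)
      d4 <- cross2(s2$a, s2$b, s1$b)
      if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
          ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
        return(TRUE)
      }
      if (abs(d1) <= eps && abs(d2) <= eps) {
        # collinear: check 1D overlap along the dominant axis
        ax <- if (abs(s1$b[1] - s1$a[1]) >= abs(s1$b[2] - s1$a[2])) 1 else 2
        r1 <- sort(c(s1$a[ax], s1$b[ax]))
        r2 <- sort(c(s2$a[ax], s2$b[ax]))
        if (min(r1[2], r2[2]) - max(r1[1], r2[1]) > eps) return(TRUE)
      }
    }
  }
  FALSE
}

#' Dimensions-derived shape parameters
#'
#' The four classical descriptors computed from linear head dimensions:
#' ellipticity `HL/HW`, elongation `(HL - HW)/(HL + HW)`, regularity
#' `pi * HL * HW / (4 A)` (departure from the ellipse with the same axes), and
#' roughness `4 pi A / P^2` (isoperimetric resemblance to a circle, at most 1
#' for simple outlines). The historical inverse of roughness, perimeter-to-area
#' `P2A = P^2 / (4 pi A)`, is also reported. Ellipticity and elongation are
#' exact monotone transforms of one another: elongation equals
#' `(ellipticity - 1) / (ellipticity + 1)`.
#'
#' @param HL,HW head length and width (micrometres), positive.
#' @param A head area (square micrometres), positive.
#' @param P head perimeter (micrometres), positive.
#' @return A tibble with columns `ellipticity`, `elongation`, `regularity`,
#'   `roughness`, `P2A`. All are invariant to uniform scaling.
#' @export
derived_parameters <- function(HL, HW, A, P) {
  if (any(c(HL, HW, A, P) <= 0) || anyNA(c(HL, HW, A, P))) {
    rlang::abort("HL, HW, A and P must all be positive")
  }
  tibble::tibble(
    ellipticity = HL / HW,
    elongation = (HL - HW) / (HL + HW),
    regularity = pi * HL * HW / (4 * A),
    roughness = 4 * pi * A / P^2,
    P2A = P^2 / (4 * pi * A)
  )
}

#' Traditional morphometry table for a landmark dataset
#'
#' Computes linear dimensions, the dimensions-derived parameters and centroid
#' size for every specimen.
#'
#' @param x a [gm_dataset()] with the 22-point sperm scheme.
#' @param outline_order outline landmark indices; default [sperm_outline()].
#' @return A tibble with one row per specimen: `specimen_id`, `HL`, `HW`, `A`,
#'   `P`, `CS`, `ellipticity`, `elongation`, `regularity`, `roughness`, `P2A`.
#' @export
traditional_measures <- function(x, outline_order = sperm_outline()) {
  stopifnot(inherits(x, "gm_dataset"))
  rows <- purrr::map(seq_len(n_specimens(x)), function(i) {
    dims <- linear_dimensions(x$coords[, , i], outline_order)
    dplyr::bind_cols(
      dims,
      tibble::tibble(CS = centroid_size(x$coords[, , i])),
      derived_parameters(dims$HL, dims$HW, dims$A, dims$P)
    )
  })
  dplyr::bind_cols(
    tibble::tibble(specimen_id = specimen_ids(x)),
    dplyr::bind_rows(rows)
  )
}
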