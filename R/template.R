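#' The 22-point sperm head landmark scheme
#'
#' The package works on a falciform (hooked) rodent sperm head digitized with
#' 12 fixed landmarks and 10 semilandmarks. Landmarks 3 and 8 span the head
#' main axis (basal and apical points of maximum length), 6 and 12 the maximum
#' head width, 1 and 2 the flagellum insertion at the posterior ring, 4 and 10
#' the dorsal and ventral curvature inflexions, 5 and 11 the limits of the
#' equatorial region of the acrosomal cap, and 7 and 9 the dorsal and ventral
#' insertions of the apical hook. Semilandmark 13 is the hook tip; 14-22 are
#' placed at half-distances along the hook chain (14 between 7 and 8, 15
#' between 7 and 14, 16 between 14 and 8, 17 between 8 and 13, 18 between 17
#' and 13, 19 between 8 and 17, 20 between 9 and 13, 21 between 9 and 20, 22
#' between 13 and 20).
#'
#' @return `sperm_roles()` returns the 22-element role vector;
#'   `sperm_sliders()` the 10 x 3 slider topology (before, slider, after;
#'   1-based); `sperm_outline()` the landmark order tracing the head outline as
#'   a simple polygon.
#' @name sperm_scheme
NULL

#' @rdname sperm_scheme
#' @export
sperm_roles <- function() {
  c(rep("fixed", 12L), rep("semilandmark", 10L))
}

#' @rdname sperm_scheme
#' @export
sperm_sliders <- function() {
  m <- rbind(
    c(7L, 15L, 14L),
    c(15L, 14L, 16L),
    c(14L, 16L, 8L),
    c(8L, 19L, 17L),
    c(19L, 17L, 18L),
    c(17L, 18L, 13L),
    c(18L, 13L, 22L),
    c(13L, 22L, 20L),
    c(22L, 20L, 21L),
    c(20L, 21L, 9L)
  )
  colnames(m) <- c("before", "slider", "after")
  m
}

#' @rdname sperm_scheme
#' @export
sperm_outline <- function() {
  c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 15L, 14L, 16L, 8L,
    19L, 17L, 18L, 13L, 22L, 20L, 21L, 9L, 10L, 11L, 12L)
}

#' Build a stylized falciform sperm head template
#'
#' Constructs one 22-point landmark configuration (micrometres, y pointing
#' apically) following the package's landmark scheme. Three parameters deform
#' the template in the regions where rodent species differ most: the curvature
#' of the apical hook, the protrusion of the base of the head (dorsal and
#' ventral inflexions, landmarks 4 and 10), and the position of the flagellum
#' insertion (landmarks 1 and 2). Head length (landmarks 3 to 8) is 8 um for
#' every parameter value, so hook-only deformations leave the main axis
#' untouched. Semilandmarks obey the half-distance construction rules of the
#' scheme exactly, and the outline order of [sperm_outline()] traces a simple
#' polygon for all in-range parameters.
#'
#' @param hook_curvature in `[0, 1]`: 0 a straight, raised hook; 1 a strongly
#'   folded hook curling toward the head base.
#' @param base_protrusion in `[-1, 1]`: protrusion (+) or retraction (-) of the
#'   basal head curvatures at landmarks 4 and 10.
#' @param insertion_shift in `[-1, 1]`: shift of the flagellum insertion point
#'   along the ventro-basal outline.
#' @return A `22 x 2` coordinate matrix with columns `x`, `y`.
#' @examples
#' tpl <- sperm_template()
#' centroid_size(tpl)
#' @export
sperm_template <- function(hook_curvature = 0.5, base_protrusion = 0,
                           insertion_shift = 0) {
  h <- hook_curvature
  bp <- base_protrusion
  ins <- insertion_shift
  if (!is.finite(h) || h < 0 || h > 1) {
    rlang::abort("hook_curvature must lie in [0, 1]")
  }
  if (!is.finite(bp) || abs(bp) > 1) {
    rlang::abort("base_protrusion must lie in [-1, 1]")
  }
  if (!is.finite(ins) || abs(ins) > 1) {
    rlang::abort("insertion_shift must lie in [-1, 1]")
  }
  p <- matrix(NA_real_, 22L, 2L, dimnames = list(NULL, c("x", "y")))
  p[1, ] <- c(-0.80 + 0.25 * ins, 0.55 + 0.15 * ins)
  p[2, ] <- c(-0.25 + 0.25 * ins, 0.18 + 0.10 * ins)
  p[3, ] <- c(0, 0)
  p[4, ] <- c(1.45 + 0.35 * bp, 1.60)
  p[5, ] <- c(1.90, 3.20)
  p[6, ] <- c(2.00, 3.40)
  p[7, ] <- c(1.20, 6.90)
  p[8, ] <- c(0, 8)
  p[9, ] <- c(-0.55, 6.80)
  p[10, ] <- c(-1.35 - 0.35 * bp, 5.00)
  p[11, ] <- c(-1.95, 3.40)
  p[12, ] <- c(-2.00, 2.60)
  p[13, ] <- c(-1.10 - 0.40 * h, 7.40 - 1.60 * h)
  # half-distance semilandmarks along the hook chain
  p[14, ] <- (p[7, ] + p[8, ]) / 2
  p[15, ] <- (p[7, ] + p[14, ]) / 2
  p[16, ] <- (p[14, ] + p[8, ]) / 2
  p[17, ] <- (p[8, ] + p[13, ]) / 2
  p[18, ] <- (p[17, ] + p[13, ]) / 2
  p[19, ] <- (p[8, ] + p[17, ]) / 2
  p[20, ] <- (p[9, ] + p[13, ]) / 2
  p[21, ] <- (p[9, ] + p[20, ]) / 2
  p[22, ] <- (p[13, ] + p[20, ]) / 2
  p
}

#' Find a hook curvature giving a prescribed template shape distance
#'
#' Solves for the `hook_curvature` whose template lies at a given partial
#' Procrustes distance from a reference template, leaving head length
#' unchanged. Used to construct species pairs that differ in residual shape by
#' a known amount.
#'
#' @param target_distance desired partial Procrustes distance (dimensionless).
#' @param reference_curvature hook curvature of the reference template.
#' @param base_protrusion,insertion_shift shared non-hook parameters.
#' @return The calibrated `hook_curvature` value.
#' @export
calibrate_hook_curvature <- function(target_distance,
                                     reference_curvature = 0.1,
                                     base_protrusion = 0,
                                     insertion_shift = 0) {
  ref <- sperm_template(reference_curvature, base_protrusion, insertion_shift)
  f <- function(h) {
    procrustes_distance(
      ref, sperm_template(h, base_protrusion, insertion_shift)
    ) - target_distance
  }
  upper <- 1
  if (f(upper) < 0) {
    rlang::abort("target_distance exceeds the template family's reach")
  }
  stats::uniroot(f, c(reference_curvature, upper), tol = 1e-10)$root
}
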