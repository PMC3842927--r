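#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

shape_outline_tbl <- function(shape, outline = sperm_outline(), label = "shape") {
  shape <- as.matrix(shape)
  if (nrow(shape) < max(outline)) outline <- seq_len(nrow(shape))
  idx <- c(outline, outline[1])
  tibble::tibble(x = shape[idx, 1], y = shape[idx, 2], shape_id = label)
}

#' Plot superimposed shapes
#'
#' Scatter of all aligned landmark positions, colored by landmark role, with
#' the mean shape outline overlaid.
#'
#' @param object a [gpa()] or [slide_semilandmarks()] fit.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gpa_fit
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- tibble::tibble(
    x = as.vector(object$coords[, 1, ]),
    y = as.vector(object$coords[, 2, ]),
    role = rep(object$roles, times = dim(object$coords)[3])
  )
  mean_tbl <- shape_outline_tbl(object$mean, label = "mean")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$role),
                        alpha = 0.3, size = 0.8) +
    ggplot2::geom_path(data = mean_tbl, color = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-superimposed configurations",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a thin-plate spline deformation grid
#'
#' The warped grid with the target shape outline overlaid, in the style of
#' classical deformation-grid figures comparing species mean shapes.
#'
#' @param object a [deformation_grid()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot deformation_grid
#' @export
autoplot.deformation_grid <- function(object, ...) {
  target <- attr(object, "target")
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$row),
                       linewidth = 0.2, color = "grey40") +
    ggplot2::geom_path(ggplot2::aes(group = .data$col),
                       linewidth = 0.2, color = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(target)) {
    g <- g + ggplot2::geom_path(
      data = shape_outline_tbl(target, label = "target"),
      color = "firebrick", linewidth = 0.6
    )
  }
  g
}

#' Plot regression-estimated shapes at covariate extremes
#'
#' Shows the model-predicted shape at the minimum and maximum observed value
#' of the standardizing variable — the "LOW vs HIGH" visualization of an
#' allometric or dimension-driven shape trend.
#'
#' @param object a [shape_regression()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot shape_regression
#' @export
autoplot.shape_regression <- function(object, ...) {
  lo <- min(object$covariate)
  hi <- max(object$covariate)
  pred <- function(v, lab) {
    shape_outline_tbl(vector_shape(object$intercept + object$slope * v),
                      label = lab)
  }
  dat <- dplyr::bind_rows(
    pred(lo, sprintf("LOW %s", object$covariate_name)),
    pred(hi, sprintf("HIGH %s", object$covariate_name))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$shape_id)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(color = NULL, x = NULL, y = NULL,
                  title = sprintf("Shape change along %s (%.1f%% predicted)",
                                  object$covariate_name,
                                  object$percent_predicted)) +
    ggplot2::theme_minimal()
}

#' Plot a group distance matrix
#'
#' @param object a [group_mean_distances()] result.
#' @param ... unused.
#' @return A ggplot tile map of pairwise Procrustes distances.
#' @method autoplot group_distances
#' @export
autoplot.group_distances <- function(object, ...) {
  dat <- generics::tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group1, y = .data$group2,
                                    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f%s", .data$distance,
                      ifelse(.data$significant_1e4, "*", ""))),
      color = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "Procrustes\ndistance") +
    ggplot2::theme_minimal()
}
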