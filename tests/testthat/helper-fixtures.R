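# small in-code fixtures shared across test files

# a tiny multi-specimen scheme-conformant dataset built from templates
make_tiny_dataset <- function(n = 4, seed = 42, noise = 0.005) {
  withr::with_seed(seed, {
    configs <- lapply(seq_len(n), function(i) {
      sperm_template(hook_curvature = runif(1)) +
        matrix(rnorm(44, 0, noise), 22, 2)
    })
    names(configs) <- paste0("s", seq_len(n))
    gm_dataset(configs, roles = sperm_roles(), sliders = sperm_sliders())
  })
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# grid-search oracle: best similarity fit of target onto reference over a
# rotation-angle grid, with closed-form scale/translation at each angle
grid_fit_rss <- function(target, reference, step_deg = 0.01) {
  xc <- sweep(target, 2, colMeans(target))
  yc <- sweep(reference, 2, colMeans(reference))
  thetas <- seq(0, 2 * pi, by = step_deg * pi / 180)
  # <Xc R(theta), Yc> = a cos(theta) + b sin(theta)
  a <- sum(xc * yc)
  b <- sum(xc[, 1] * yc[, 2] - xc[, 2] * yc[, 1])
  g <- a * cos(thetas) + b * sin(thetas)
  rss <- sum(yc^2) - pmax(g, 0)^2 / sum(xc^2)
  min(rss)
}

# grid-search oracle for the partial Procrustes distance
grid_partial_distance <- function(a, b, step_deg = 0.01) {
  x <- sweep(a, 2, colMeans(a)); x <- x / sqrt(sum(x^2))
  y <- sweep(b, 2, colMeans(b)); y <- y / sqrt(sum(y^2))
  thetas <- seq(0, 2 * pi, by = step_deg * pi / 180)
  ca <- sum(y * x)
  cb <- sum(y[, 1] * x[, 2] - y[, 2] * x[, 1])
  g <- ca * cos(thetas) + cb * sin(thetas)
  sqrt(max(0, 2 - 2 * max(g)))
}
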