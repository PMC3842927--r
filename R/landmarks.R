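#' Landmark dataset container
#'
#' A `gm_dataset` bundles a sample of 2D landmark configurations that share one
#' landmark scheme: a `K x 2 x n` coordinate array (micrometres), a per-landmark
#' role vector (`"fixed"` or `"semilandmark"`), an optional slider topology for
#' the semilandmarks, and an optional covariate table keyed by specimen id.
#'
#' @param coords numeric array `K x 2 x n` (landmarks, x/y, specimens), or a
#'   list of `K x 2` matrices. Coordinates are in micrometres.
#' @param roles character vector of length `K`, each `"fixed"` or
#'   `"semilandmark"`. At least 3 landmarks must be fixed.
#' @param sliders integer matrix with columns `before`, `slider`, `after`
#'   (1-based landmark indices), one row per sliding semilandmark, or `NULL`.
#' @param covariates data frame with a `specimen_id` column matching the
#'   specimen names of `coords` exactly once each, or `NULL`.
#' @param scale micrometres per coordinate unit already applied; retained as
#'   metadata (default 1).
#'
#' @return An object of class `gm_dataset`.
#' @seealso [read_tps()], [simulate_sperm()], [gpa()]
#' @export
gm_dataset <- function(coords, roles, sliders = NULL, covariates = NULL,
                       scale = 1) {
  if (is.list(coords) && !is.array(coords)) {
    ids <- names(coords)
    coords <- array(
      unlist(coords, use.names = FALSE),
      dim = c(nrow(coords[[1]]), 2L, length(coords)),
      dimnames = list(NULL, c("x", "y"), ids)
    )
  }
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L),
                    dimnames = c(dimnames(coords)[1:2], list(NULL)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (k < 3) rlang::abort("a landmark scheme needs at least 3 points")
  if (!all(is.finite(coords))) rlang::abort("non-finite landmark coordinates")
  roles <- match.arg(roles, c("fixed", "semilandmark"), several.ok = TRUE)
  if (length(roles) != k) {
    rlang::abort(sprintf("roles has length %d but there are %d landmarks",
                         length(roles), k))
  }
  if (sum(roles == "fixed") < 3) {
    rlang::abort("at least 3 landmarks must be fixed")
  }
  if (is.null(dimnames(coords)[[3]])) {
    dimnames(coords)[[3]] <- as.character(seq_len(n))
  }
  dimnames(coords)[[2]] <- c("x", "y")
  if (!is.null(sliders)) sliders <- validate_sliders(sliders, roles)
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!"specimen_id" %in% names(covariates)) {
      rlang::abort("covariates must contain a specimen_id column")
    }
    covariates$specimen_id <- as.character(covariates$specimen_id)
    ids <- dimnames(coords)[[3]]
    hit <- match(ids, covariates$specimen_id)
    if (anyNA(hit) || anyDuplicated(covariates$specimen_id)) {
      rlang::abort("every specimen_id must appear exactly once in covariates")
    }
    covariates <- covariates[hit, , drop = FALSE]
  }
  structure(
    list(coords = coords, roles = roles, sliders = sliders,
         covariates = covariates, scale = scale),
    class = "gm_dataset"
  )
}

validate_sliders <- function(sliders, roles) {
  sliders <- as.matrix(sliders)
  storage.mode(sliders) <- "integer"
  if (ncol(sliders) != 3L) rlang::abort("sliders must have 3 columns")
  colnames(sliders) <- c("before", "slider", "after")
  k <- length(roles)
  if (any(sliders < 1L) || any(sliders > k)) {
    rlang::abort("slider indices out of range")
  }
  if (any(roles[sliders[, "slider"]] != "semilandmark")) {
    rlang::abort("every sliding point must have role semilandmark")
  }
  if (any(sliders[, "before"] == sliders[, "slider"]) ||
      any(sliders[, "after"] == sliders[, "slider"])) {
    rlang::abort("slider neighbors must differ from the slider itself")
  }
  if (anyDuplicated(sliders[, "slider"])) {
    rlang::abort("a semilandmark appears in more than one slider row")
  }
  sliders
}

#' @export
print.gm_dataset <- function(x, ...) {
  k <- dim(x$coords)[1]
  cat(sprintf(
    "<gm_dataset> %d specimens, %d landmarks (%d fixed, %d semilandmarks)\n",
    dim(x$coords)[3], k, sum(x$roles == "fixed"),
    sum(x$roles == "semilandmark")
  ))
  if (!is.null(x$sliders)) {
    cat(sprintf("  sliders: %d triples\n", nrow(x$sliders)))
  }
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %s\n",
                paste(setdiff(names(x$covariates), "specimen_id"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.gm_dataset <- function(x) dim(x$coords)

n_specimens <- function(x) dim(x$coords)[3]
n_landmarks <- function(x) dim(x$coords)[1]

specimen_ids <- function(x) dimnames(x$coords)[[3]]

#' Coordinates of a landmark dataset as a long tibble
#'
#' @param x a `gm_dataset`.
#' @param ... unused.
#' @return A tibble with columns `specimen_id`, `landmark`, `role`, `x`, `y`.
#' @method as_tibble gm_dataset
#' @export
as_tibble.gm_dataset <- function(x, ...) {
  k <- n_landmarks(x)
  n <- n_specimens(x)
  tibble::tibble(
    specimen_id = rep(specimen_ids(x), each = k),
    landmark = rep(seq_len(k), times = n),
    role = rep(x$roles, times = n),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ])
  )
}

#' Subset specimens of a landmark dataset
#'
#' @param x a `gm_dataset`.
#' @param i specimen index or id vector.
#' @param ... unused.
#' @export
`[.gm_dataset` <- function(x, i, ...) {
  coords <- x$coords[, , i, drop = FALSE]
  cov <- x$covariates
  if (!is.null(cov)) {
    cov <- cov[match(dimnames(coords)[[3]], cov$specimen_id), , drop = FALSE]
  }
  gm_dataset(coords, x$roles, sliders = x$sliders, covariates = cov,
             scale = x$scale)
}
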