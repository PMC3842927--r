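#' Read a TPS-format landmark file
#'
#' Parses the tpsDig dialect: records start with `LM=<count>` followed by that
#' many whitespace-separated `x y` rows, with optional `ID=`, `SCALE=`,
#' `IMAGE=` lines; `CURVES=`/`POINTS=` outline blocks are skipped with a
#' warning (only the landmark block is used here).
#'
#' @param path path to a TPS file.
#' @param scale_policy `"apply"` (default) multiplies coordinates by the
#'   record's `SCALE=` factor so they are in micrometres; `"ignore"` keeps raw
#'   digitizer units.
#' @param roles per-landmark roles for the resulting dataset; defaults to the
#'   22-point sperm scheme when the file has 22 landmarks, otherwise all
#'   `"fixed"`.
#' @param sliders optional slider topology to attach.
#' @return A [gm_dataset()] (configurations only; join covariates with
#'   [read_covariates()]).
#' @export
read_tps <- function(path, scale_policy = c("apply", "ignore"), roles = NULL,
                     sliders = NULL) {
  scale_policy <- match.arg(scale_policy)
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  starts <- which(grepl("^LM\\s*=", lines_trim, ignore.case = TRUE))
  if (length(starts) == 0) {
    rlang::abort(sprintf("empty TPS dataset: no LM= record in %s", path))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  ids <- character(length(starts))
  curves_seen <- FALSE
  for (r in seq_along(starts)) {
    block <- lines_trim[starts[r]:ends[r]]
    block_lines <- starts[r]:ends[r]
    lm_count <- as.integer(sub("^LM\\s*=\\s*", "", block[1],
                               ignore.case = TRUE))
    pts <- matrix(NA_real_, lm_count, 2L)
    got <- 0L
    id <- NA_character_
    scl <- NA_real_
    skip_curve <- 0L
    for (j in seq_along(block)[-1]) {
      ln <- block[j]
      if (ln == "") next
      if (grepl("^[A-Za-z]+\\s*=", ln)) {
        key <- toupper(sub("\\s*=.*$", "", ln))
        val <- sub("^[A-Za-z]+\\s*=\\s*", "", ln)
        if (key == "ID") id <- val
        if (key == "SCALE") scl <- as.numeric(val)
        if (key %in% c("CURVES", "IMAGE")) curves_seen <- TRUE
        if (key == "POINTS") skip_curve <- as.integer(val)
        next
      }
      if (skip_curve > 0L) {
        skip_curve <- skip_curve - 1L
        next
      }
      xy <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(xy) < 2 || anyNA(xy)) {
        rlang::abort(sprintf("non-numeric coordinate row at line %d of %s",
                             block_lines[j], path))
      }
      got <- got + 1L
      if (got > lm_count) break
      pts[got, ] <- xy[1:2]
    }
    if (got != lm_count) {
      rlang::abort(sprintf(
        "record %d of %s declares LM=%d but has %d coordinate rows",
        r, path, lm_count, got))
    }
    if (scale_policy == "apply" && !is.na(scl)) pts <- pts * scl
    configs[[r]] <- pts
    ids[r] <- if (is.na(id)) as.character(r) else id
  }
  if (curves_seen) {
    rlang::warn("IMAGE=/CURVES= blocks present in TPS file; ignored")
  }
  k <- unique(vapply(configs, nrow, integer(1)))
  if (length(k) != 1) {
    rlang::abort("all records in one dataset must share the landmark count")
  }
  if (is.null(roles)) {
    roles <- if (k == 22L) sperm_roles() else rep("fixed", k)
  }
  names(configs) <- ids
  gm_dataset(configs, roles = roles, sliders = sliders)
}

#' Write a landmark dataset to a TPS file
#'
#' @param x a non-empty [gm_dataset()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_tps()] losslessly to 6
#'   significant digits with ids preserved exactly.
#' @export
write_tps <- function(x, path) {
  stopifnot(inherits(x, "gm_dataset"))
  if (n_specimens(x) == 0) rlang::abort("cannot write an empty dataset")
  k <- n_landmarks(x)
  ids <- specimen_ids(x)
  out <- unlist(lapply(seq_len(n_specimens(x)), function(i) {
    pts <- x$coords[, , i]
    c(sprintf("LM=%d", k),
      sprintf("%.9g %.9g", pts[, 1], pts[, 2]),
      sprintf("ID=%s", ids[i]))
  }))
  con <- tryCatch(file(path, "w"), error = function(e) {
    rlang::abort(sprintf("cannot open %s for writing", path))
  })
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a sliders definition file
#'
#' One whitespace-separated `before slider after` triple per line, 1-based
#' landmark indices; blank lines and `#` comments are skipped.
#'
#' @param path path to the sliders file.
#' @return An integer matrix with columns `before`, `slider`, `after`.
#' @export
read_sliders <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) rlang::abort("empty sliders file")
  vals <- lapply(lines, function(ln) {
    v <- suppressWarnings(as.integer(strsplit(ln, "\\s+")[[1]]))
    if (length(v) != 3 || anyNA(v)) {
      rlang::abort(sprintf("malformed sliders line: '%s'", ln))
    }
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- c("before", "slider", "after")
  m
}

#' Write a sliders definition file
#'
#' @param sliders `m x 3` integer matrix (before, slider, after; 1-based).
#' @param path output path.
#' @export
write_sliders <- function(sliders, path) {
  writeLines(apply(sliders, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read a specimen covariate table
#'
#' A CSV with a header row whose first column is the specimen id; remaining
#' columns are group labels or numeric measures.
#'
#' @param path path to the CSV file.
#' @return A tibble whose first column is named `specimen_id`.
#' @export
read_covariates <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  names(tab)[1] <- "specimen_id"
  tab$specimen_id <- as.character(tab$specimen_id)
  tab
}

#' Canonicalize sperm head orientation
#'
#' Digitized heads may face either way on the slide; downstream superimposition
#' disallows reflection, so all heads must share one chirality. A configuration
#' is reflected (`x` negated) exactly when the signed area of the triangle
#' through the basal pole (landmark 3), the apical pole (landmark 8) and the
#' hook tip (landmark 13) is negative, placing every hook on the same side of
#' the base-apex axis. The test triple is rotation- and translation-invariant,
#' so the operation is idempotent and commutes with rigid motions.
#'
#' @param x a [gm_dataset()] containing the designated landmarks.
#' @param axis indices of the basal and apical axis landmarks (default
#'   `c(3, 8)`).
#' @param side index of the hook-side landmark (default 13).
#' @return The dataset with all specimens in canonical orientation.
#' @export
canonicalize_orientation <- function(x, axis = c(3L, 8L), side = 13L) {
  stopifnot(inherits(x, "gm_dataset"))
  k <- n_landmarks(x)
  if (max(axis, side) > k) {
    rlang::abort(sprintf(
      "scheme has %d landmarks; orientation landmarks %s are missing",
      k, paste(c(axis, side), collapse = ", ")))
  }
  coords <- x$coords
  for (i in seq_len(dim(coords)[3])) {
    p <- coords[, , i]
    a <- p[axis[2], ] - p[axis[1], ]
    b <- p[side, ] - p[axis[1], ]
    if (a[1] * b[2] - a[2] * b[1] < 0) {
      coords[, 1, i] <- -coords[, 1, i]
    }
  }
  x$coords <- coords
  x
}
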