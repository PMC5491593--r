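#' Per-segment feature matrix
#'
#' Computes one of the four feature kinds as a sensors x bands matrix over
#' the fine grid: "totalPSD" and "relPSD" from the Welch estimate, "PLV" and
#' "PLI" by stacking per-sensor strengths of the proportionally thresholded
#' connectivity matrix of every fine band. Following the proportional
#' significance rule, PLV keeps the top 40% of links and PLI the top 50%
#' before averaging.
#'
#' @param segment a [segment_array()].
#' @param kind "totalPSD", "relPSD", "PLV" or "PLI".
#' @param grid a [band_grid()].
#' @param keep_fraction proportion of links kept; default 0.40 for PLV and
#'   0.50 for PLI.
#' @param edge_frac edge discard fraction for phase estimation.
#' @param window_sec Welch window for the PSD kinds.
#' @return A `feature_matrix` (sensors x `grid$n_bands`).
#' @export
feature_matrix <- function(segment, kind = c("relPSD", "totalPSD", "PLV", "PLI"),
                           grid = band_grid(), keep_fraction = NULL,
                           edge_frac = 0.1, window_sec = NULL) {
  kind <- match.arg(kind)
  ref <- list(subject_id = segment$subject_id, segment_index = segment$segment_index)
  if (kind %in% c("totalPSD", "relPSD")) {
    tot <- total_psd(segment, grid, window_sec = window_sec)
    tot$segment_ref <- ref
    if (kind == "totalPSD") {
      return(tot)
    }
    return(relative_psd(tot))
  }
  if (is.null(keep_fraction)) {
    keep_fraction <- if (kind == "PLV") 0.40 else 0.50
  }
  iv <- band_intervals(grid)
  out <- matrix(0, nrow(segment$data), grid$n_bands)
  for (b in seq_len(grid$n_bands)) {
    cm <- connectivity_matrix(segment, iv[b, ], kind, edge_frac = edge_frac, grid = grid)
    out[, b] <- sensor_strength(threshold_proportional(cm, keep_fraction))
  }
  new_feature_matrix(out, kind, grid, segment_ref = ref)
}

#' Restrict a feature matrix to a canonical band
#'
#' Keeps the fine-band columns whose interval lies inside the canonical
#' band: theta keeps 2 columns, alpha 3, beta1 3, beta2 4, gamma 6.
#'
#' @param fm a `feature_matrix` on the full fine grid.
#' @param band_name canonical band name.
#' @return A `feature_matrix` with the reduced column set; `band_names`
#'   records the restriction.
#' @export
restrict_to_band <- function(fm, band_name) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- band_columns(fm$grid, band_name)
  out <- fm
  out$values <- fm$values[, cols, drop = FALSE]
  out$band_names <- band_name
  out
}

#' Concatenate feature matrices into one input vector
#'
#' Row-major flattens each matrix (sensor-by-sensor) and concatenates them
#' in the given order, recording provenance `(kind, band)` per component.
#' All matrices must come from the same segment.
#'
#' @param fms list of `feature_matrix` objects.
#' @return An object of class `feature_vector`: list with `values` and
#'   `provenance` (data.frame kind, band, length).
#' @export
combine_features <- function(fms) {
  if (!length(fms)) stop("empty feature list", call. = FALSE)
  refs <- lapply(fms, function(f) f$segment_ref)
  ids <- unique(vapply(
    refs,
    function(r) {
      if (is.null(r)) NA_character_ else paste(r$subject_id, r$segment_index)
    },
    character(1)
  ))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    stop("feature matrices come from different segments", call. = FALSE)
  }
  vals <- unlist(lapply(fms, function(f) as.vector(t(f$values))))
  prov <- data.frame(
    kind = vapply(fms, function(f) f$kind, character(1)),
    band = vapply(fms, function(f) {
      if (is.null(f$band_names)) "full" else paste(f$band_names, collapse = "+")
    }, character(1)),
    length = vapply(fms, function(f) length(f$values), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(values = vals, provenance = prov), class = "feature_vector")
}

#' Extract feature arrays for a whole cohort
#'
#' Computes the requested feature kinds for every segment and stacks them
#' into arrays `[segment, sensor, band]`, together with an index mapping
#' array rows to subjects and conditions. This is the expensive step of the
#' pipeline and is done once per cohort; every classification experiment
#' then slices these arrays.
#'
#' @param cohort a [generate_cohort()] result (or a compatible list).
#' @param kinds character vector of feature kinds to compute.
#' @param grid a [band_grid()].
#' @param edge_frac,window_sec forwarded to [feature_matrix()].
#' @param verbose print one line per subject.
#' @return An object of class `feature_set`: list with `arrays` (named list
#'   of 3-d arrays), `index` (data.frame row, subject_id, condition,
#'   segment_index), `grid`.
#' @export
extract_features <- function(cohort, kinds = c("relPSD", "PLV"),
                             grid = band_grid(), edge_frac = 0.1,
                             window_sec = NULL, verbose = FALSE) {
  kinds <- match.arg(kinds, c("totalPSD", "relPSD", "PLV", "PLI"),
    several.ok = TRUE
  )
  segs <- unlist(lapply(cohort$subjects, `[[`, "segments"), recursive = FALSE)
  n_seg <- length(segs)
  n_sensors <- nrow(segs[[1]]$data)
  arrays <- lapply(kinds, function(k) array(0, c(n_seg, n_sensors, grid$n_bands)))
  names(arrays) <- kinds
  index <- data.frame(
    row = seq_len(n_seg),
    subject_id = vapply(segs, `[[`, character(1), "subject_id"),
    condition = NA_character_,
    segment_index = vapply(segs, `[[`, integer(1), "segment_index"),
    stringsAsFactors = FALSE
  )
  cond <- stats::setNames(cohort$manifest$condition, cohort$manifest$subject_id)
  index$condition <- unname(cond[index$subject_id])

  # share the totalPSD computation when both PSD kinds are requested
  for (i in seq_len(n_seg)) {
    seg <- segs[[i]]
    if (any(c("totalPSD", "relPSD") %in% kinds)) {
      tot <- total_psd(seg, grid, window_sec = window_sec)
      if ("totalPSD" %in% kinds) arrays[["totalPSD"]][i, , ] <- tot$values
      if ("relPSD" %in% kinds) arrays[["relPSD"]][i, , ] <- relative_psd(tot)$values
    }
    for (k in intersect(kinds, c("PLV", "PLI"))) {
      arrays[[k]][i, , ] <- feature_matrix(seg, k,
        grid = grid,
        edge_frac = edge_frac
      )$values
    }
    if (verbose && (i %% 50 == 0)) {
      message("  features: segment ", i, "/", n_seg)
    }
  }
  structure(
    list(arrays = arrays, index = index, grid = grid),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> %d segments x %d sensors x %d bands; kinds: %s\n",
    nrow(x$index), dim(x$arrays[[1]])[2], dim(x$arrays[[1]])[3],
    paste(names(x$arrays), collapse = ", ")
  ))
  invisible(x)
}

#' Feature specification for a classification stage
#'
#' @param ... one or more components, each `list(kind =, band =)` where
#'   `band` is a canonical band name or `NULL` for the full grid.
#' @return List of components, class `feature_spec`.
#' @examples
#' feature_spec(list(kind = "relPSD", band = "beta1"),
#'              list(kind = "PLV", band = "beta2"))
#' @export
feature_spec <- function(...) {
  comps <- list(...)
  if (!length(comps)) stop("empty feature spec", call. = FALSE)
  for (cmp in comps) {
    stopifnot(is.list(cmp), !is.null(cmp$kind))
  }
  structure(comps, class = "feature_spec")
}

#' Build the design matrix for a feature specification
#'
#' Slices the precomputed feature arrays, restricting each component to its
#' canonical band where requested, row-major flattening (sensor-major) and
#' concatenating components. Row order follows `fs$index`.
#'
#' @param fs a `feature_set`.
#' @param spec a [feature_spec()].
#' @return Numeric matrix, segments x total feature dimension.
#' @export
build_design <- function(fs, spec) {
  stopifnot(inherits(fs, "feature_set"))
  blocks <- lapply(spec, function(cmp) {
    if (!cmp$kind %in% names(fs$arrays)) {
      stop("feature kind not extracted: ", cmp$kind, call. = FALSE)
    }
    a <- fs$arrays[[cmp$kind]]
    if (!is.null(cmp$band)) {
      a <- a[, , band_columns(fs$grid, cmp$band), drop = FALSE]
    }
    # [segment, sensor, band] -> segments x (sensor-major flatten)
    matrix(aperm(a, c(3, 2, 1)), nrow = dim(a)[1], byrow = TRUE)
  })
  do.call(cbind, blocks)
}
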