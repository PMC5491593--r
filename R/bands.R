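#' Frequency band grid for feature extraction
#'
#' The analysis works on 18 fine bands of 2 Hz width spanning 4--40 Hz,
#' grouped into the five canonical rhythms used for band-restricted
#' classification: theta (4--8 Hz), alpha (8--14 Hz), beta 1 (14--20 Hz),
#' beta 2 (20--28 Hz) and low gamma (28--40 Hz). All intervals are half-open
#' `[lo, hi)`, so the canonical bands partition the fine grid exactly.
#'
#' @param lo,hi outer frequency limits in Hz.
#' @param step fine band width in Hz.
#' @return An object of class `band_grid`: a list with `edges` (ascending
#'   band edges, `length(edges) - 1` fine bands), `n_bands`, and `canonical`,
#'   a named list of `c(lo, hi)` intervals.
#' @examples
#' g <- band_grid()
#' g$n_bands              # 18
#' band_columns(g, "beta1")  # fine bands inside 14-20 Hz
#' @export
band_grid <- function(lo = 4, hi = 40, step = 2) {
  stopifnot(hi > lo, step > 0, (hi - lo) %% step == 0)
  edges <- seq(lo, hi, by = step)
  canonical <- list(
    theta = c(4, 8),
    alpha = c(8, 14),
    beta1 = c(14, 20),
    beta2 = c(20, 28),
    gamma = c(28, 40)
  )
  structure(
    list(edges = edges, n_bands = length(edges) - 1L, canonical = canonical),
    class = "band_grid"
  )
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf(
    "<band_grid> %d bands of %g Hz on [%g, %g) Hz; canonical: %s\n",
    x$n_bands, diff(x$edges[1:2]), x$edges[1], x$edges[length(x$edges)],
    paste(names(x$canonical), collapse = ", ")
  ))
  invisible(x)
}

#' Fine-band intervals of a grid
#'
#' @param grid a [band_grid()].
#' @return Two-column matrix of `[lo, hi)` fine-band limits, one row per band.
#' @export
band_intervals <- function(grid) {
  cbind(lo = grid$edges[-length(grid$edges)], hi = grid$edges[-1])
}

#' Columns of the fine grid covered by a canonical band
#'
#' @param grid a [band_grid()].
#' @param band_name one of `names(grid$canonical)`.
#' @return Integer indices of the fine bands whose interval lies inside the
#'   canonical band.
#' @export
band_columns <- function(grid, band_name) {
  if (!band_name %in% names(grid$canonical)) {
    stop("unknown canonical band: ", band_name, call. = FALSE)
  }
  b <- grid$canonical[[band_name]]
  iv <- band_intervals(grid)
  which(iv[, "lo"] >= b[1] & iv[, "hi"] <= b[2])
}

#' Resolve a band argument to a numeric interval
#'
#' Accepts either a canonical band name or a numeric `c(lo, hi)` interval.
#' @param band band name or numeric length-2 vector.
#' @param grid a [band_grid()] supplying the canonical names.
#' @return Numeric `c(lo, hi)`.
#' @keywords internal
resolve_band <- function(band, grid = band_grid()) {
  if (is.character(band)) {
    if (!band %in% names(grid$canonical)) {
      stop("unknown canonical band: ", band, call. = FALSE)
    }
    return(grid$canonical[[band]])
  }
  stopifnot(is.numeric(band), length(band) == 2, band[2] > band[1])
  unname(band)
}
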