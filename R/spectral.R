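#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: Hann-tapered windows of `window_sec`
#' seconds with 50% overlap, per-window mean removal, one-sided density
#' scaling (integral of the estimate over frequency approximates the signal
#' variance).
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param window_sec analysis window length in seconds (default 1, giving a
#'   1 Hz frequency resolution).
#' @param overlap fractional window overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate, window_sec = 1, overlap = 0.5) {
  nw <- round(window_sec * rate)
  if (length(x) < 2 * nw) {
    stop("segment too short for the PSD window (need >= 2 windows)", call. = FALSE)
  }
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / nw)
  u <- sum(w^2)
  n_keep <- floor(nw / 2) + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (rate * u)
    acc <- acc + p[seq_len(n_keep)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- 2:(n_keep - if (nw %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(n_keep) - 1L) * rate / nw, psd = psd)
}

#' Feature matrix container
#'
#' @param values sensors x bands numeric matrix.
#' @param kind one of "totalPSD", "relPSD", "PLV", "PLI".
#' @param grid the [band_grid()] the columns refer to.
#' @param band_names optional column identity (canonical-band restriction
#'   keeps track of which fine bands remain).
#' @param segment_ref optional provenance (subject/segment ids).
#' @return An object of class `feature_matrix`.
#' @export
new_feature_matrix <- function(values, kind, grid,
                               band_names = NULL, segment_ref = NULL) {
  kind <- match.arg(kind, c("totalPSD", "relPSD", "PLV", "PLI"))
  stopifnot(is.matrix(values))
  structure(
    list(
      values = values, kind = kind, grid = grid,
      band_names = band_names, segment_ref = segment_ref
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %s: %d sensors x %d bands\n",
    x$kind, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Total band power per sensor
#'
#' Welch PSD per sensor, integrated over each fine band `[f, f+2)` of the
#' grid (sum of the density estimate times the bin width).
#'
#' @param segment a [segment_array()].
#' @param grid a [band_grid()].
#' @param window_sec Welch window length in seconds; the default (`NULL`)
#'   uses half the segment duration capped at 2 s, so the frequency
#'   resolution is at most 0.5 Hz on 5-s segments and tapered leakage from
#'   mid-band tones stays inside their 2-Hz band.
#' @return A `feature_matrix` of kind "totalPSD" (sensors x bands).
#' @export
total_psd <- function(segment, grid = band_grid(), window_sec = NULL) {
  rate <- segment$sampling_rate_hz
  if (is.null(window_sec)) {
    window_sec <- min(2, floor(ncol(segment$data) / 2) / rate)
  }
  if (max(grid$edges) > rate / 2) {
    stop("band grid extends beyond the Nyquist frequency", call. = FALSE)
  }
  iv <- band_intervals(grid)
  n_sensors <- nrow(segment$data)
  out <- matrix(0, n_sensors, grid$n_bands)
  for (k in seq_len(n_sensors)) {
    p <- welch_psd(segment$data[k, ], rate, window_sec = window_sec)
    df <- p$freq[2] - p$freq[1]
    for (b in seq_len(grid$n_bands)) {
      sel <- p$freq >= iv[b, "lo"] & p$freq < iv[b, "hi"]
      out[k, b] <- sum(p$psd[sel]) * df
    }
  }
  new_feature_matrix(out, "totalPSD", grid)
}

#' Relative band power per sensor
#'
#' Each sensor's band powers divided by that sensor's summed power over the
#' whole grid (4--40 Hz), so every row sums to one. The denominator is
#' restricted to the grid rather than the full recorded bandwidth, making
#' the feature self-contained.
#'
#' @param total a `feature_matrix` of kind "totalPSD".
#' @return A `feature_matrix` of kind "relPSD" with rows summing to 1.
#' @export
relative_psd <- function(total) {
  stopifnot(inherits(total, "feature_matrix"), total$kind == "totalPSD")
  v <- total$values
  rs <- rowSums(v)
  if (any(rs <= 0)) {
    stop(
      "degenerate sensor(s) with zero total band power: ",
      paste(which(rs <= 0), collapse = ", "),
      call. = FALSE
    )
  }
  out <- v / rs
  new_feature_matrix(out, "relPSD", total$grid,
    band_names = total$band_names, segment_ref = total$segment_ref
  )
}
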