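#' Instantaneous phase of a band-limited signal
#'
#' Isolates the band with a zero-phase FFT-domain mask (raised-cosine
#' transitions of `transition_hz` outside the passband) and builds the
#' analytic signal in the same transform (negative frequencies zeroed,
#' positive doubled), so the phase is the argument of the band-limited
#' analytic signal. A fixed fraction of samples at both edges is discarded
#' before any phase statistic, guarding against wrap-around transients of
#' the circular convolution.
#'
#' Narrow 2-Hz passbands at kHz rates make forward-backward IIR filtering
#' numerically fragile; the FFT mask is exactly zero-phase at any bandwidth.
#'
#' For content entirely outside the band the analytic amplitude is near zero
#' and the returned phase is numerical noise; callers pairing sensors should
#' ensure in-band content exists (the generator always places background
#' power there).
#'
#' @param segment a [segment_array()] or a sensors x samples matrix (then
#'   `rate` is required).
#' @param band canonical band name or numeric `c(lo, hi)` in Hz.
#' @param rate sampling rate, taken from the segment when omitted.
#' @param edge_frac fraction of samples dropped at each edge (default 0.1).
#' @param transition_hz width of the raised-cosine roll-off.
#' @param grid [band_grid()] used to resolve band names.
#' @return sensors x retained-samples matrix of phases in `(-pi, pi]`, with
#'   attribute `retained` giving the kept sample indices.
#' @export
band_phases <- function(segment, band, rate = NULL, edge_frac = 0.1,
                        transition_hz = 0.5, grid = band_grid()) {
  if (inherits(segment, "segment_array")) {
    x <- segment$data
    rate <- segment$sampling_rate_hz
  } else {
    x <- segment
    if (is.null(rate)) stop("rate required for a bare matrix", call. = FALSE)
  }
  b <- resolve_band(band, grid)
  if (b[1] <= 0 || b[2] >= rate / 2) {
    stop("band [", b[1], ", ", b[2], ") outside (0, rate/2)", call. = FALSE)
  }
  n <- ncol(x)
  df <- rate / n
  if ((b[2] - b[1]) < 2 * df) {
    stop(
      "band narrower than 2 frequency bins at this length/rate; ",
      "phase reconstruction unreliable",
      call. = FALSE
    )
  }
  f <- (0:(n - 1)) * df
  f_pos <- ifelse(f <= rate / 2, f, rate - f) # mirrored frequency axis

  mask <- numeric(n)
  inside <- f_pos >= b[1] & f_pos < b[2]
  mask[inside] <- 1
  if (transition_hz > 0) {
    lo_t <- f_pos >= b[1] - transition_hz & f_pos < b[1]
    hi_t <- f_pos >= b[2] & f_pos < b[2] + transition_hz
    mask[lo_t] <- 0.5 + 0.5 * cos(pi * (b[1] - f_pos[lo_t]) / transition_hz)
    mask[hi_t] <- 0.5 + 0.5 * cos(pi * (f_pos[hi_t] - b[2]) / transition_hz)
  }
  # analytic-signal weights: zero negative frequencies, double positive
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  wgt <- mask * h

  keep <- seq_len(n)
  drop_n <- floor(edge_frac * n)
  if (drop_n > 0) keep <- keep[(drop_n + 1):(n - drop_n)]

  phases <- matrix(0, nrow(x), length(keep))
  for (k in seq_len(nrow(x))) {
    a <- stats::fft(stats::fft(x[k, ]) * wgt, inverse = TRUE) / n
    phases[k, ] <- Arg(a[keep])
  }
  attr(phases, "retained") <- keep
  phases
}

#' Phase-locking value of two phase series
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(1i * (p1 - p2)))|`. Equals 1 iff the phase difference is
#' constant; for independent uniform phases over T samples the expected
#' value is approximately `sqrt(pi) / (2 * sqrt(T))`.
#'
#' @param p1,p2 numeric phase vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
plv_pair <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("phase vectors differ in length", call. = FALSE)
  if (length(p1) < 2) stop("need at least 2 samples", call. = FALSE)
  min(1, Mod(mean(exp(1i * (p1 - p2)))))
}

#' Phase-lag index of two phase series
#'
#' Absolute mean sign of the sine of the phase difference:
#' `|mean(sign(sin(p1 - p2)))|`. Measures the asymmetry of the
#' phase-difference distribution around zero; insensitive to zero-lag
#' coupling (a phase difference identically 0 gives 0).
#'
#' @param p1,p2 numeric phase vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
pli_pair <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("phase vectors differ in length", call. = FALSE)
  if (length(p1) < 2) stop("need at least 2 samples", call. = FALSE)
  abs(mean(sign(sin(p1 - p2))))
}

#' Pairwise phase-synchronization matrix for one band
#'
#' PLV or PLI over all unordered sensor pairs of the band-limited phases of
#' one segment. Symmetric with a zero diagonal.
#'
#' @param segment a [segment_array()].
#' @param band canonical band name or `c(lo, hi)` Hz.
#' @param kind "PLV" or "PLI".
#' @param edge_frac edge discard fraction passed to [band_phases()].
#' @param grid [band_grid()].
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (sensors x sensors), `kind`, `band`.
#' @export
connectivity_matrix <- function(segment, band, kind = c("PLV", "PLI"),
                                edge_frac = 0.1, grid = band_grid()) {
  kind <- match.arg(kind)
  if (nrow(segment$data) < 2) stop("need at least 2 sensors", call. = FALSE)
  ph <- band_phases(segment, band, edge_frac = edge_frac, grid = grid)
  m <- phase_connectivity(ph, kind)
  structure(
    list(values = m, kind = kind, band = resolve_band(band, grid)),
    class = "connectivity_matrix"
  )
}

# Pairwise PLV/PLI from a sensors x samples phase matrix.
phase_connectivity <- function(ph, kind) {
  n <- nrow(ph)
  tn <- ncol(ph)
  if (kind == "PLV") {
    e <- exp(1i * ph)
    m <- Mod(e %*% Conj(t(e))) / tn
    m[m > 1] <- 1
  } else {
    s <- sin(ph)
    c <- cos(ph)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # sign(sin(pi - pj)) = sign(sin(pi) cos(pj) - cos(pi) sin(pj))
        v <- abs(mean(sign(s[i, ] * c[j, ] - c[i, ] * s[j, ])))
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  diag(m) <- 0
  m
}

#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `ceiling(keep_fraction * n_pairs)` largest off-diagonal values
#' (one per unordered pair) and zeroes the rest, preserving symmetry. Ties
#' at the cutoff are resolved deterministically by pair index (row-major
#' over the upper triangle).
#'
#' @param conn a `connectivity_matrix` or a plain symmetric matrix.
#' @param keep_fraction fraction of pairs to keep, in `(0, 1]`.
#' @return Same type as the input, thresholded.
#' @export
threshold_proportional <- function(conn, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  m <- if (inherits(conn, "connectivity_matrix")) conn$values else conn
  n <- nrow(m)
  ut <- which(upper.tri(m))
  vals <- m[ut]
  n_keep <- ceiling(keep_fraction * length(ut))
  ord <- order(-vals, seq_along(vals))
  drop_idx <- ut[ord[-seq_len(n_keep)]]
  out <- m
  out[drop_idx] <- 0
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  if (inherits(conn, "connectivity_matrix")) {
    conn$values <- out
    conn
  } else {
    out
  }
}

#' Per-sensor connectivity strength
#'
#' Average coupling of each sensor to all others: row sum over the n-1
#' off-diagonal entries divided by n-1. Links zeroed by thresholding stay in
#' the denominator, matching an average over all j != i.
#'
#' @param conn a `connectivity_matrix` or plain symmetric matrix.
#' @return Numeric vector of length n_sensors.
#' @export
sensor_strength <- function(conn) {
  m <- if (inherits(conn, "connectivity_matrix")) conn$values else conn
  rowSums(m) / (nrow(m) - 1)
}
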