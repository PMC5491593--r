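#' KPSS level-stationarity statistic
#'
#' Test statistic of Kwiatkowski, Phillips, Schmidt and Shin for the null of
#' level stationarity: partial sums of the mean-centered series, normalized
#' by a Newey--West long-run variance estimate with Bartlett weights and the
#' short truncation lag `floor(4 * (T/100)^(1/4))`. Large values indicate a
#' non-stationary (e.g. trending or random-walk) series; the 5% critical
#' value for the level-stationarity null is 0.463.
#'
#' @param x numeric vector, length >= 10, not constant.
#' @param lags Newey--West truncation lag; default the short rule above.
#' @return Non-negative scalar statistic.
#' @examples
#' set.seed(1)
#' kpss_statistic(rnorm(500))        # small: stationary
#' kpss_statistic(cumsum(rnorm(500)))  # large: random walk
#' @export
kpss_statistic <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("series too short for KPSS (need length >= 10)", call. = FALSE)
  e <- x - mean(x)
  if (all(abs(e) < .Machine$double.eps * max(1, abs(mean(x))) * 10)) {
    stop("constant series: KPSS statistic undefined (zero variance)", call. = FALSE)
  }
  if (is.null(lags)) lags <- floor(4 * (n / 100)^0.25)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  if (s2 <= 0) stop("non-positive long-run variance estimate", call. = FALSE)
  S <- cumsum(e)
  sum(S^2) / (n^2 * s2)
}

#' Select the most stationary windows of a multichannel recording
#'
#' Tiles the recording into non-overlapping, contiguous windows of
#' `window_seconds`, scores each window by the mean KPSS statistic across
#' sensors (lower = more stationary), and returns the `n_select` lowest-score
#' windows in temporal order. Ties at the cutoff are broken by earlier start
#' time.
#'
#' @param recording numeric matrix, sensors x samples.
#' @param rate sampling rate in Hz.
#' @param window_seconds window length in seconds.
#' @param n_select number of windows to keep.
#' @param aggregate function pooling per-sensor KPSS values into one window
#'   score (default `mean`).
#' @return An object of class `segment_selection`: list with
#'   `candidate_windows` (two-column matrix of half-open `[start, end)`
#'   sample intervals, 1-based starts), `scores`, and `selected` (indices
#'   into the candidate list, ascending).
#' @export
select_stationary_segments <- function(recording, rate, window_seconds,
                                       n_select, aggregate = mean) {
  stopifnot(is.matrix(recording), n_select >= 1, window_seconds > 0)
  win <- round(window_seconds * rate)
  n_win <- floor(ncol(recording) / win)
  if (n_win < n_select) {
    stop(
      "insufficient data: ", n_win, " candidate windows < n_select = ",
      n_select,
      call. = FALSE
    )
  }
  starts <- (seq_len(n_win) - 1L) * win + 1L
  scores <- vapply(starts, function(s) {
    vals <- apply(recording[, s:(s + win - 1L), drop = FALSE], 1, kpss_statistic)
    aggregate(vals)
  }, numeric(1))
  ord <- order(scores, seq_len(n_win))  # ties: earlier start first
  selected <- sort(ord[seq_len(n_select)])
  structure(
    list(
      candidate_windows = cbind(start = starts, end = starts + win),
      scores = scores,
      selected = selected,
      window_samples = win
    ),
    class = "segment_selection"
  )
}

#' @export
print.segment_selection <- function(x, ...) {
  cat(sprintf(
    "<segment_selection> %d of %d windows selected (%d samples each)\n",
    length(x$selected), length(x$scores), x$window_samples
  ))
  invisible(x)
}

#' Extract the selected windows as segment arrays
#'
#' @param recording sensors x samples matrix the selection was computed on.
#' @param selection a `segment_selection`.
#' @param rate sampling rate in Hz.
#' @param subject_id identifier stamped on the segments.
#' @return List of [segment_array()] in temporal order.
#' @export
extract_selected_segments <- function(recording, selection, rate,
                                      subject_id = NA_character_) {
  lapply(seq_along(selection$selected), function(i) {
    w <- selection$candidate_windows[selection$selected[i], ]
    segment_array(
      recording[, w["start"]:(w["end"] - 1L), drop = FALSE],
      rate,
      subject_id = subject_id, segment_index = i
    )
  })
}
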