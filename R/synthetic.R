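#' Class specification for the synthetic cohort generator
#'
#' Describes one diagnostic condition by (a) multiplicative power boosts on
#' canonical frequency bands and (b) inter-sensor phase coupling within
#' chosen bands. Both are the statistical signals the downstream features are
#' designed to pick up: band-power boosts move the relative PSD profile,
#' coupling moves PLV/PLI.
#'
#' The coupling model mixes, within the coupled band, a shared narrowband
#' Gaussian source with independent per-sensor narrowband noise:
#' sensor k receives `sqrt(s) * shared * exp(-1i*(k-1)*lag) + sqrt(1-s) * noise_k`
#' in the frequency domain, where `s` is `strength`. At `s = 0` sensors are
#' conditionally independent in the band; at `s = 1` every pair has a constant
#' phase difference (a multiple of `lag`), so PLV = 1 there.
#'
#' @param label condition name (e.g. "healthy", "generalized", "focal").
#' @param band_power_boost named numeric vector of multiplicative power
#'   factors (> 0), names being canonical band names of [band_grid()].
#' @param coupling a data.frame with columns `band` (canonical name),
#'   `strength` (in `[0,1]`) and `lag` (radians), or `NULL` for none.
#' @param subject_variability between-subject standard deviation (log scale)
#'   of a lognormal multiplier applied to each subject's band boosts.
#' @param coupling_gain amplitude factor of the coupled-band component
#'   relative to the background level in that band (power factor is its
#'   square).
#' @return An object of class `class_spec`.
#' @examples
#' class_spec("generalized",
#'   band_power_boost = c(beta1 = 1.6),
#'   coupling = data.frame(band = "beta2", strength = 0.45, lag = pi / 4)
#' )
#' @export
class_spec <- function(label,
                       band_power_boost = numeric(0),
                       coupling = NULL,
                       subject_variability = 0.1,
                       coupling_gain = 1.5) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  if (length(band_power_boost)) {
    stopifnot(!is.null(names(band_power_boost)), all(band_power_boost > 0))
  }
  if (!is.null(coupling)) {
    stopifnot(
      is.data.frame(coupling),
      all(c("band", "strength", "lag") %in% names(coupling)),
      all(coupling$strength >= 0), all(coupling$strength <= 1)
    )
  }
  stopifnot(subject_variability >= 0, coupling_gain > 0)
  structure(
    list(
      label = label,
      band_power_boost = band_power_boost,
      coupling = coupling,
      subject_variability = subject_variability,
      coupling_gain = coupling_gain
    ),
    class = "class_spec"
  )
}

#' Cohort generator configuration
#'
#' Defaults mirror the clinical study design the pipeline emulates: three
#' conditions with 14 subjects each, 40 segments of 5 s per subject, 102
#' sensors sampled at 1 kHz. [desk_cohort_config()] gives a reduced profile
#' for routine computation.
#'
#' @param class_specs list of [class_spec()] objects with distinct labels.
#' @param n_subjects_per_class subjects per condition.
#' @param n_segments segments per subject.
#' @param n_sensors number of sensors.
#' @param segment_seconds segment duration in seconds.
#' @param sampling_rate_hz sampling rate; must exceed twice the highest
#'   generated frequency.
#' @param background_exponent spectral exponent alpha of the 1/f^alpha
#'   Gaussian background.
#' @param seed integer seed making the cohort reproducible.
#' @param grid [band_grid()] used to resolve canonical band names.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(class_specs = default_class_specs(),
                          n_subjects_per_class = 14,
                          n_segments = 40,
                          n_sensors = 102,
                          segment_seconds = 5,
                          sampling_rate_hz = 1000,
                          background_exponent = 1,
                          seed = 1L,
                          grid = band_grid()) {
  stopifnot(
    n_subjects_per_class >= 1, n_segments >= 1, n_sensors >= 1,
    segment_seconds > 0, sampling_rate_hz > 0
  )
  labels <- vapply(class_specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate class labels in class_specs", call. = FALSE)
  }
  f_max <- max(grid$edges)
  for (s in class_specs) {
    if (!is.null(s$coupling)) {
      for (i in seq_len(nrow(s$coupling))) {
        f_max <- max(f_max, resolve_band(s$coupling$band[i], grid)[2])
      }
    }
  }
  if (sampling_rate_hz <= 2 * f_max) {
    stop(
      "sampling_rate_hz must exceed twice the highest generated frequency (",
      f_max, " Hz)",
      call. = FALSE
    )
  }
  structure(
    list(
      class_specs = class_specs,
      n_subjects_per_class = as.integer(n_subjects_per_class),
      n_segments = as.integer(n_segments),
      n_sensors = as.integer(n_sensors),
      segment_seconds = segment_seconds,
      sampling_rate_hz = sampling_rate_hz,
      background_exponent = background_exponent,
      seed = as.integer(seed),
      grid = grid
    ),
    class = "cohort_config"
  )
}

#' Default planted class contrasts
#'
#' Encodes the effect directions the pipeline is built to detect: both
#' epileptic conditions carry extra beta-1 (14--20 Hz) band power relative to
#' healthy subjects, and the two epileptic conditions differ from each other
#' in beta-1 power and in beta-2 (20--28 Hz) inter-sensor phase coupling.
#' Magnitudes are generator choices (the source cohort is not public), fixed
#' once at a level a desk-scale cohort can resolve.
#'
#' @param subject_variability between-subject lognormal sd of band boosts.
#' @return List of three [class_spec()] objects.
#' @export
default_class_specs <- function(subject_variability = 0.1) {
  list(
    class_spec("healthy",
      band_power_boost = numeric(0),
      coupling = data.frame(band = "beta2", strength = 0.10, lag = pi / 4),
      subject_variability = subject_variability
    ),
    class_spec("generalized",
      band_power_boost = c(beta1 = 2.0),
      coupling = data.frame(band = "beta2", strength = 0.35, lag = pi / 4),
      subject_variability = subject_variability
    ),
    class_spec("focal",
      band_power_boost = c(beta1 = 1.3),
      coupling = data.frame(band = "beta2", strength = 0.10, lag = pi / 4),
      subject_variability = subject_variability
    )
  )
}

#' Reduced-scale cohort configuration
#'
#' Same design as [cohort_config()] but sized for routine runs: fewer
#' sensors, shorter segments and a lower rate. The statistical structure
#' (class contrasts, 1/f background, band grid) is unchanged.
#'
#' @param ... overrides passed to [cohort_config()].
#' @export
desk_cohort_config <- function(...) {
  args <- list(
    n_subjects_per_class = 14,
    n_segments = 10,
    n_sensors = 12,
    segment_seconds = 2,
    sampling_rate_hz = 160,
    seed = 1L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

#' One multichannel segment
#'
#' @param data numeric matrix, sensors x samples.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param subject_id,segment_index provenance identifiers.
#' @return An object of class `segment_array`.
#' @export
segment_array <- function(data, sampling_rate_hz, subject_id = NA_character_,
                          segment_index = NA_integer_) {
  stopifnot(is.matrix(data), !anyNA(data), is.finite(sampling_rate_hz))
  structure(
    list(
      data = data,
      sampling_rate_hz = sampling_rate_hz,
      subject_id = subject_id,
      segment_index = as.integer(segment_index)
    ),
    class = "segment_array"
  )
}

#' @export
print.segment_array <- function(x, ...) {
  cat(sprintf(
    "<segment_array> %d sensors x %d samples @ %g Hz (subject %s, segment %s)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate_hz,
    x$subject_id, x$segment_index
  ))
  invisible(x)
}

# Draw one matrix of complex Gaussian spectral coefficients (rows = positive
# frequencies, cols = sensors), unit expected power per coefficient.
crnorm <- function(n_freq, n_sensors) {
  matrix(
    complex(
      real = stats::rnorm(n_freq * n_sensors, sd = 1 / sqrt(2)),
      imaginary = stats::rnorm(n_freq * n_sensors, sd = 1 / sqrt(2))
    ),
    nrow = n_freq, ncol = n_sensors
  )
}

#' Generate one synthetic segment
#'
#' Each sensor is Gaussian 1/f^alpha background noise synthesized in the
#' frequency domain, with per-band power boosts applied as multiplicative
#' spectral factors. Within each coupled band the independent background is
#' replaced by the shared-source mixture described in [class_spec()], scaled
#' by `coupling_gain` relative to the local background level. Output is
#' deterministic given the R RNG state on entry.
#'
#' @param spec a [class_spec()].
#' @param subject_boosts named numeric vector of this subject's realized band
#'   power boosts (class boost times the subject's lognormal multiplier).
#' @param n_sensors,n_samples,rate segment geometry.
#' @param background_exponent spectral exponent alpha.
#' @param grid [band_grid()] for resolving band names.
#' @return A [segment_array()].
#' @export
generate_segment <- function(spec, subject_boosts, n_sensors, n_samples, rate,
                             background_exponent = 1, grid = band_grid()) {
  stopifnot(n_sensors >= 1, n_samples >= 8)
  n_freq <- floor(n_samples / 2)
  f <- seq_len(n_freq) * rate / n_samples

  # background amplitude profile (sqrt of power spectrum)
  amp <- f^(-background_exponent / 2)
  for (bn in names(subject_boosts)) {
    b <- resolve_band(bn, grid)
    if (b[2] >= rate / 2 || b[1] <= 0) {
      stop("band ", bn, " outside (0, rate/2)", call. = FALSE)
    }
    sel <- f >= b[1] & f < b[2]
    amp[sel] <- amp[sel] * sqrt(subject_boosts[[bn]])
  }

  coef <- crnorm(n_freq, n_sensors) * amp

  if (!is.null(spec$coupling) && nrow(spec$coupling) > 0) {
    for (i in seq_len(nrow(spec$coupling))) {
      b <- resolve_band(spec$coupling$band[i], grid)
      if (b[2] >= rate / 2 || b[1] <= 0) {
        stop("coupling band outside (0, rate/2)", call. = FALSE)
      }
      sel <- which(f >= b[1] & f < b[2])
      if (!length(sel)) {
        stop("coupling band contains no frequency bins at this length/rate",
          call. = FALSE
        )
      }
      s <- spec$coupling$strength[i]
      lag <- spec$coupling$lag[i]
      shared <- crnorm(length(sel), 1L)[, 1]
      indep <- crnorm(length(sel), n_sensors)
      rot <- exp(-1i * (seq_len(n_sensors) - 1) * lag)
      mix <- sqrt(s) * outer(shared, rot) + sqrt(1 - s) * indep
      coef[sel, ] <- spec$coupling_gain * amp[sel] * mix
    }
  }

  # hermitian assembly and inverse transform, sensor by sensor
  x <- matrix(0, nrow = n_sensors, ncol = n_samples)
  even <- n_samples %% 2 == 0
  for (k in seq_len(n_sensors)) {
    spec_full <- complex(real = numeric(n_samples))
    spec_full[2:(n_freq + 1)] <- coef[, k]
    if (even) {
      # Nyquist bin must be real for a real signal
      spec_full[n_freq + 1] <- complex(real = Re(coef[n_freq, k]) * sqrt(2))
    }
    tail_idx <- n_samples:(n_freq + 2)
    spec_full[tail_idx] <- Conj(spec_full[2:(n_freq + !even)])
    x[k, ] <- Re(stats::fft(spec_full, inverse = TRUE)) / sqrt(n_samples)
  }
  segment_array(x, rate)
}

# Realized per-subject band boosts: class boost times lognormal multiplier.
draw_subject_boosts <- function(spec) {
  boosts <- spec$band_power_boost
  if (!length(boosts)) {
    return(numeric(0))
  }
  boosts * stats::rlnorm(length(boosts), meanlog = 0, sdlog = spec$subject_variability)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_subjects_per_class` subjects for each class spec, each with
#' `n_segments` segments, reproducibly from `config$seed`. Subject-level
#' variability enters through a lognormal multiplier on the class band
#' boosts, drawn once per subject.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort`: list with `subjects` (each a list
#'   with `subject_id`, `condition`, `boosts`, `segments`), `manifest`
#'   (data.frame subject_id, condition) and `config`.
#' @examples
#' cfg <- desk_cohort_config(n_subjects_per_class = 2, n_segments = 2,
#'                           n_sensors = 4)
#' coh <- generate_cohort(cfg)
#' coh$manifest
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_samples <- round(config$segment_seconds * config$sampling_rate_hz)
  subjects <- list()
  for (spec in config$class_specs) {
    for (j in seq_len(config$n_subjects_per_class)) {
      sid <- sprintf("%s_%02d", spec$label, j)
      boosts <- draw_subject_boosts(spec)
      segs <- vector("list", config$n_segments)
      for (g in seq_len(config$n_segments)) {
        seg <- generate_segment(
          spec, boosts, config$n_sensors, n_samples,
          config$sampling_rate_hz, config$background_exponent, config$grid
        )
        seg$subject_id <- sid
        seg$segment_index <- g
        segs[[g]] <- seg
      }
      subjects[[sid]] <- list(
        subject_id = sid, condition = spec$label,
        boosts = boosts, segments = segs
      )
    }
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    condition = vapply(subjects, `[[`, character(1), "condition"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(subjects = subjects, manifest = manifest, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$condition)
  cat(sprintf(
    "<cohort> %d subjects (%s), %d segments each, %d sensors @ %g Hz\n",
    nrow(x$manifest),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    x$config$n_segments, x$config$n_sensors, x$config$sampling_rate_hz
  ))
  invisible(x)
}
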