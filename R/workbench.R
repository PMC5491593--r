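#' Derive a named sub-seed from a master seed
#'
#' One master seed fans out deterministically to the generator, the fold
#' shuffle and the ensemble members, so independent randomness sources never
#' share a stream. Results stay within the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param what component name ("cohort", "folds", "elm", "scan", ...).
#' @return Positive integer seed.
#' @export
derive_seed <- function(master, what) {
  offs <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(as.numeric(master)) * 48271 + offs * 1299709) %% 2147483399) + 1L
}

#' Write a cohort to a plain-text directory
#'
#' Layout: `manifest.csv` (subject_id, condition), `meta.json` (rates,
#' shapes, seed) and one `segments_<subject>.csv` per subject holding all of
#' that subject's segments stacked long (columns: segment_index, sample,
#' then one column per sensor). Everything round-trips through
#' [read_cohort()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- cohort$config
  meta <- list(
    sampling_rate_hz = cfg$sampling_rate_hz,
    n_sensors = cfg$n_sensors,
    n_segments = cfg$n_segments,
    segment_seconds = cfg$segment_seconds,
    seed = cfg$seed
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (sub in cohort$subjects) {
    tabs <- lapply(sub$segments, function(seg) {
      d <- as.data.frame(t(seg$data))
      names(d) <- sprintf("s%03d", seq_len(nrow(seg$data)))
      cbind(
        data.frame(segment_index = seg$segment_index, sample = seq_len(ncol(seg$data))),
        d
      )
    })
    data.table::fwrite(
      data.table::rbindlist(tabs),
      file.path(dir, sprintf("segments_%s.csv", sub$subject_id))
    )
  }
  invisible(dir)
}

#' Read a cohort from a plain-text directory
#'
#' Validates the layout written by [write_cohort()]: every manifest subject
#' must have a segment file, every segment the same sensor count and length.
#'
#' @param dir directory written by [write_cohort()].
#' @return A `cohort` object (without generator config; `config` holds the
#'   stored metadata).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("missing manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "condition") %in% names(manifest))) {
    stop("manifest.csv must have subject_id and condition columns", call. = FALSE)
  }
  if (anyNA(manifest$condition) || any(!nzchar(manifest$condition))) {
    bad <- manifest$subject_id[is.na(manifest$condition) | !nzchar(manifest$condition)]
    stop("missing condition label for subject(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rate <- meta$sampling_rate_hz
  expected_len <- NULL
  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    f <- file.path(dir, sprintf("segments_%s.csv", sid))
    if (!file.exists(f)) stop("missing segment file for subject ", sid, call. = FALSE)
    dt <- data.table::fread(f)
    sensor_cols <- grep("^s\\d+$", names(dt), value = TRUE)
    segs <- lapply(split(dt, by = "segment_index", sorted = TRUE), function(d) {
      m <- t(as.matrix(d[, sensor_cols, with = FALSE]))
      segment_array(m, rate, subject_id = sid, segment_index = d$segment_index[1])
    })
    for (seg in segs) {
      if (is.null(expected_len)) expected_len <- ncol(seg$data)
      if (ncol(seg$data) != expected_len) {
        stop("segment-length mismatch at subject ", sid, call. = FALSE)
      }
    }
    subjects[[sid]] <- list(
      subject_id = sid, condition = manifest$condition[i],
      boosts = NULL, segments = unname(segs)
    )
  }
  structure(
    list(subjects = subjects, manifest = manifest, config = meta),
    class = "cohort"
  )
}

#' Experiment configuration
#'
#' Bundles everything one end-to-end run needs: the cohort (a
#' [cohort_config()] or a directory of recordings), the per-stage feature
#' specifications, the classifier parameters and the master seed. Fully
#' serializable to YAML via [write_experiment_config()].
#'
#' @param cohort a [cohort_config()] or a path to a [write_cohort()] directory.
#' @param stage1_spec,stage2_spec [feature_spec()] per stage; defaults are
#'   the full relative PSD for stage 1 and the beta1-relPSD + beta2-PLV pair
#'   for stage 2.
#' @param params an [elm_params()].
#' @param master_seed master seed fanning out via [derive_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = desk_cohort_config(),
                              stage1_spec = feature_spec(list(kind = "relPSD", band = NULL)),
                              stage2_spec = feature_spec(
                                list(kind = "relPSD", band = "beta1"),
                                list(kind = "PLV", band = "beta2")
                              ),
                              params = elm_params(D = 100, n_ensemble = 11),
                              master_seed = 1L) {
  structure(
    list(
      cohort = cohort, stage1_spec = stage1_spec, stage2_spec = stage2_spec,
      params = params, master_seed = as.integer(master_seed)
    ),
    class = "experiment_config"
  )
}

#' Write an experiment configuration to YAML
#'
#' @param config an [experiment_config()] with a generator cohort config.
#' @param path output file.
#' @export
write_experiment_config <- function(config, path) {
  cc <- config$cohort
  cohort_yaml <- if (is.character(cc)) {
    list(path = cc)
  } else {
    list(
      n_subjects_per_class = cc$n_subjects_per_class,
      n_segments = cc$n_segments,
      n_sensors = cc$n_sensors,
      segment_seconds = cc$segment_seconds,
      sampling_rate_hz = cc$sampling_rate_hz,
      background_exponent = cc$background_exponent,
      seed = cc$seed,
      class_specs = lapply(cc$class_specs, function(s) {
        list(
          label = s$label,
          band_power_boost = as.list(s$band_power_boost),
          coupling = if (is.null(s$coupling)) NULL else as.list(s$coupling),
          subject_variability = s$subject_variability,
          coupling_gain = s$coupling_gain
        )
      })
    )
  }
  spec_yaml <- function(sp) lapply(sp, function(cmp) list(kind = cmp$kind, band = cmp$band))
  yaml::write_yaml(
    list(
      cohort = cohort_yaml,
      stage1_spec = spec_yaml(config$stage1_spec),
      stage2_spec = spec_yaml(config$stage2_spec),
      params = unclass(config$params),
      master_seed = config$master_seed
    ),
    path
  )
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file written by [write_experiment_config()].
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$path)) {
    y$cohort$path
  } else {
    cc <- y$cohort
    specs <- lapply(cc$class_specs, function(s) {
      class_spec(
        label = s$label,
        band_power_boost = unlist(s$band_power_boost),
        coupling = if (is.null(s$coupling)) NULL else as.data.frame(s$coupling),
        subject_variability = s$subject_variability,
        coupling_gain = s$coupling_gain
      )
    })
    cohort_config(
      class_specs = specs,
      n_subjects_per_class = cc$n_subjects_per_class,
      n_segments = cc$n_segments,
      n_sensors = cc$n_sensors,
      segment_seconds = cc$segment_seconds,
      sampling_rate_hz = cc$sampling_rate_hz,
      background_exponent = cc$background_exponent,
      seed = cc$seed
    )
  }
  as_spec <- function(l) do.call(feature_spec, l)
  experiment_config(
    cohort = cohort,
    stage1_spec = as_spec(y$stage1_spec),
    stage2_spec = as_spec(y$stage2_spec),
    params = do.call(elm_params, y$params),
    master_seed = y$master_seed
  )
}

write_cm_csv <- function(cm, path) {
  if (cm$type == "binary") {
    tab <- matrix(c(cm$TN, cm$FP, cm$FN, cm$TP), 2, 2,
      byrow = TRUE,
      dimnames = list(
        truth = c("negative", "positive"),
        prediction = c("negative", "positive")
      )
    )
  } else {
    tab <- cm$table
  }
  utils::write.csv(as.data.frame(tab), path)
  invisible(path)
}

write_roc_csv <- function(roc, path) {
  utils::write.csv(
    data.frame(
      threshold = roc$thresholds,
      sensitivity = roc$sensitivity,
      fpr = roc$fpr
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Run the full experiment
#'
#' Generates (or ingests) the cohort, extracts the features both stages
#' need, runs the healthy-vs-epileptic stage, the generalized-vs-focal stage
#' and the two-stage cascade, and writes all tables (confusion matrices,
#' ROC curves, metrics, run metadata) under `out_dir`. Deterministic given
#' `config$master_seed`.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param control,positive2 condition roles (see [run_cascade()]).
#' @param verbose print stage summaries.
#' @return List with `stage1`, `stage2`, `cascade`, `features`, `cohort`.
#' @export
run_experiment <- function(config, out_dir = NULL,
                           control = "healthy", positive2 = "generalized",
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- if (is.character(config$cohort)) {
    read_cohort(config$cohort)
  } else {
    cc <- config$cohort
    cc$seed <- derive_seed(config$master_seed, "cohort")
    generate_cohort(cc)
  }
  conds <- sort(unique(cohort$manifest$condition))
  patho <- setdiff(conds, control)
  if (length(patho) != 2) stop("expected two pathological conditions", call. = FALSE)
  other2 <- setdiff(patho, positive2)

  kinds <- unique(c(
    vapply(config$stage1_spec, `[[`, character(1), "kind"),
    vapply(config$stage2_spec, `[[`, character(1), "kind")
  ))
  fs <- extract_features(cohort, kinds = kinds, verbose = verbose)

  elm_seed <- derive_seed(config$master_seed, "elm")
  fold_seed <- derive_seed(config$master_seed, "folds")
  params <- config$params
  params$seed <- elm_seed

  map1 <- stats::setNames(ifelse(conds == control, -1L, 1L), conds)
  map2 <- stats::setNames(c(1L, -1L), c(positive2, other2))

  stage1 <- run_stage(fs, config$stage1_spec, map1, params, fold_seed = fold_seed)
  stage2 <- run_stage(fs, config$stage2_spec, map2, params, fold_seed = fold_seed)
  cascade <- run_cascade(fs, config$stage1_spec, config$stage2_spec,
    control = control, positive2 = positive2,
    params = params, fold_seed = fold_seed
  )
  if (verbose) {
    print(stage1)
    print(stage2)
    print(cascade)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cm_csv(stage1$cm, file.path(out_dir, "stage1_confusion.csv"))
    write_cm_csv(stage2$cm, file.path(out_dir, "stage2_confusion.csv"))
    write_cm_csv(cascade$cm, file.path(out_dir, "cascade_confusion.csv"))
    write_roc_csv(stage1$segment_roc, file.path(out_dir, "stage1_roc.csv"))
    write_roc_csv(stage2$segment_roc, file.path(out_dir, "stage2_roc.csv"))
    metrics <- list(
      stage1 = c(stage1$metrics, segment_auc = stage1$segment_auc),
      stage2 = c(stage2$metrics, segment_auc = stage2$segment_auc),
      cascade = cascade$metrics,
      seeds = list(
        master = config$master_seed, cohort = derive_seed(config$master_seed, "cohort"),
        folds = fold_seed, elm = elm_seed
      ),
      params = unclass(params)
    )
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(
    stage1 = stage1, stage2 = stage2, cascade = cascade,
    features = fs, cohort = cohort
  )
}
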