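#' Subject-wise leave-one-out fold plan
#'
#' With k subjects per condition, builds k folds such that fold i tests the
#' i-th subject of every condition (after a seeded shuffle within each
#' condition) and trains on all remaining subjects. Every subject is tested
#' exactly once; train and test subjects are disjoint within each fold, so
#' no within-subject information crosses the split.
#'
#' @param manifest data.frame with columns `subject_id`, `condition`.
#' @param seed seed for the within-condition shuffle.
#' @return An object of class `fold_plan`: list of folds, each with `train`
#'   and `test` subject-id vectors.
#' @export
make_folds <- function(manifest, seed = 1L) {
  by_cond <- split(manifest$subject_id, manifest$condition)
  sizes <- lengths(by_cond)
  if (length(unique(sizes)) != 1) {
    stop(
      "unbalanced conditions (",
      paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "),
      "); equal subjects per condition required",
      call. = FALSE
    )
  }
  k <- sizes[[1]]
  set.seed(seed)
  by_cond <- lapply(by_cond, sample)
  all_ids <- manifest$subject_id
  folds <- lapply(seq_len(k), function(i) {
    test <- vapply(by_cond, `[[`, character(1), i)
    list(train = setdiff(all_ids, test), test = unname(test))
  })
  structure(folds, class = "fold_plan")
}

#' Subject label from segment-level predictions
#'
#' Majority vote over a subject's segment labels; an exact tie resolves to
#' the positive (pathological) class. The positive-vote fraction doubles as
#' a subject-level score.
#'
#' @param segment_labels vector of +1 / -1 segment predictions.
#' @param positive value coding the positive class (default `1`).
#' @return List with `label` and `positive_fraction`.
#' @export
classify_subject <- function(segment_labels, positive = 1L) {
  if (!length(segment_labels)) stop("no segment labels", call. = FALSE)
  frac <- mean(segment_labels == positive)
  list(
    label = if (frac >= 0.5) positive else setdiff(unique(c(-1L, 1L)), positive),
    positive_fraction = frac
  )
}

#' Binary confusion matrix from labels
#'
#' @param truth,pred vectors of +1 (positive / pathological) and -1.
#' @return An object of class `confusion_matrix` with counts TN, FP, FN, TP.
#' @export
confusion_binary <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(
    list(
      TN = sum(truth == -1 & pred == -1),
      FP = sum(truth == -1 & pred == 1),
      FN = sum(truth == 1 & pred == -1),
      TP = sum(truth == 1 & pred == 1),
      n = length(truth), type = "binary"
    ),
    class = "confusion_matrix"
  )
}

#' Confusion matrix from explicit counts
#'
#' @param TN,FP,FN,TP non-negative counts.
#' @export
confusion_counts <- function(TN, FP, FN, TP) {
  stopifnot(TN >= 0, FP >= 0, FN >= 0, TP >= 0)
  structure(
    list(TN = TN, FP = FP, FN = FN, TP = TP, n = TN + FP + FN + TP, type = "binary"),
    class = "confusion_matrix"
  )
}

#' Multiclass confusion table
#'
#' @param truth,pred label vectors.
#' @param labels ordered label set (rows = truth, columns = prediction).
#' @return An object of class `confusion_matrix` with a `table` field.
#' @export
confusion_multiclass <- function(truth, pred, labels) {
  tab <- table(
    factor(truth, levels = labels),
    factor(pred, levels = labels)
  )
  structure(
    list(table = unclass(tab), labels = labels, n = length(truth), type = "multiclass"),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  if (x$type == "binary") {
    cat(sprintf(
      "<confusion_matrix> TN=%d FP=%d FN=%d TP=%d (n=%d)\n",
      x$TN, x$FP, x$FN, x$TP, x$n
    ))
  } else {
    cat("<confusion_matrix> truth (rows) x prediction (columns):\n")
    print(x$table)
  }
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Binary case: accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). Multiclass (cascade) case: accuracy =
#' trace/total, specificity = recall of the control (first) class, and
#' per-class recalls are reported; a zero denominator yields `NA` for that
#' ratio.
#'
#' @param cm a `confusion_matrix`.
#' @param control_label for the multiclass case, the label whose recall is
#'   reported as specificity (default the first label).
#' @return Named list of metrics.
#' @export
confusion_metrics <- function(cm, control_label = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$type == "binary") {
    tot <- cm$TP + cm$TN + cm$FP + cm$FN
    if (tot == 0) stop("empty confusion matrix", call. = FALSE)
    list(
      accuracy = (cm$TP + cm$TN) / tot,
      sensitivity = if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_,
      specificity = if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else NA_real_
    )
  } else {
    tab <- cm$table
    if (is.null(control_label)) control_label <- cm$labels[1]
    rs <- rowSums(tab)
    recalls <- ifelse(rs > 0, diag(tab) / rs, NA_real_)
    names(recalls) <- cm$labels
    list(
      accuracy = sum(diag(tab)) / sum(tab),
      specificity = unname(recalls[control_label]),
      per_class_recall = recalls
    )
  }
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending): at each cutoff an
#' item is called positive when its score is >= the cutoff. The curve starts
#' at (0, 0) and ends at (1, 1); the AUC is the trapezoid-rule area and
#' equals the Mann--Whitney pairwise probability with ties counted 1/2.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth vector of +1 / -1 (or logical) true labels; both classes
#'   must be present.
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `fpr` (1 - specificity) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.logical(truth)) truth <- ifelse(truth, 1L, -1L)
  stopifnot(length(scores) == length(truth))
  npos <- sum(truth == 1)
  nneg <- sum(truth == -1)
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & truth == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == -1) / nneg, numeric(1))
  sens <- c(0, sens, 1)
  fpr <- c(0, fpr, 1)
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(
    list(thresholds = c(Inf, thr, -Inf), sensitivity = sens, fpr = fpr, auc = auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc, length(x$thresholds)))
  invisible(x)
}

#' One binary classification stage under subject-wise cross-validation
#'
#' For every fold, fits a fresh ELM ensemble on the training subjects'
#' segments and predicts the held-out subjects' segments; subject labels
#' follow from the segment majority rule. Returns the pooled subject-level
#' confusion matrix, per-fold accuracies, and the segment-level ROC built
#' from the ensemble positive-vote fractions of all held-out segments (each
#' segment is held out exactly once).
#'
#' @param fs a `feature_set`.
#' @param spec a [feature_spec()].
#' @param class_map named vector mapping condition names to +1 (positive /
#'   pathological) or -1; conditions absent from the map are excluded.
#' @param params an [elm_params()]; member seeds are re-derived per fold so
#'   folds are independent realizations.
#' @param fold_seed seed of the fold plan's within-condition shuffle.
#' @return An object of class `stage_result`: subject table, confusion
#'   matrix, metrics, per-fold accuracy, segment ROC and AUC.
#' @export
run_stage <- function(fs, spec, class_map, params, fold_seed = 1L) {
  stopifnot(inherits(fs, "feature_set"))
  if (length(unique(sign(class_map))) < 2) {
    stop("class_map must contain both +1 and -1 conditions", call. = FALSE)
  }
  idx <- fs$index[fs$index$condition %in% names(class_map), ]
  X <- build_design(fs, spec)
  manifest <- unique(idx[, c("subject_id", "condition")])
  folds <- make_folds(manifest, seed = fold_seed)
  y <- unname(class_map[idx$condition])

  subj_rows <- split(idx$row, idx$subject_id)
  subj_truth <- stats::setNames(
    unname(class_map[manifest$condition]),
    manifest$subject_id
  )

  subject_tab <- list()
  seg_scores <- numeric(0)
  seg_truth <- integer(0)
  fold_acc <- numeric(length(folds))

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr_rows <- match(unlist(subj_rows[fold$train]), idx$row)
    fold_params <- params
    fold_params$seed <- (params$seed + 7919L * fi) %% .Machine$integer.max
    ens <- fit_ensemble(X[idx$row[tr_rows], , drop = FALSE], y[tr_rows], fold_params)
    correct <- logical(length(fold$test))
    for (si in seq_along(fold$test)) {
      sid <- fold$test[si]
      rows <- subj_rows[[sid]]
      pr <- predict_ensemble(ens, X[rows, , drop = FALSE])
      dec <- classify_subject(pr$label)
      subject_tab[[sid]] <- data.frame(
        subject_id = sid,
        truth = subj_truth[[sid]],
        pred = dec$label,
        positive_fraction = dec$positive_fraction,
        fold = fi,
        stringsAsFactors = FALSE
      )
      correct[si] <- dec$label == subj_truth[[sid]]
      seg_scores <- c(seg_scores, pr$vote_fraction)
      seg_truth <- c(seg_truth, rep(subj_truth[[sid]], length(rows)))
    }
    fold_acc[fi] <- mean(correct)
  }

  subject_tab <- do.call(rbind, subject_tab[manifest$subject_id])
  cm <- confusion_binary(subject_tab$truth, subject_tab$pred)
  roc <- roc_auc(seg_scores, seg_truth)
  structure(
    list(
      subjects = subject_tab, cm = cm,
      metrics = confusion_metrics(cm),
      fold_accuracy = fold_acc,
      segment_roc = roc, segment_auc = roc$auc,
      spec = spec, class_map = class_map
    ),
    class = "stage_result"
  )
}

#' @export
print.stage_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<stage_result> subject accuracy %.3f (sens %.3f, spec %.3f); segment AUC %.4f\n",
    m$accuracy, m$sensitivity, m$specificity, x$segment_auc
  ))
  invisible(x)
}

#' Two-stage cascade over three conditions
#'
#' Stage 1 separates control subjects from the pooled pathological
#' conditions; subjects called pathological are passed to stage 2, trained
#' only on the two pathological conditions, which assigns the final label.
#' Both stages share the fold partition (fold i of stage 2 holds out the
#' pathological members of fold i of stage 1), so no test subject's segments
#' ever enter a training set that predicts them. Control subjects
#' mis-labelled pathological at stage 1 are scored by the stage-2 model of
#' their own fold.
#'
#' @param fs a `feature_set` over three conditions.
#' @param stage1_spec,stage2_spec [feature_spec()] per stage.
#' @param control condition treated as negative at stage 1.
#' @param positive2 pathological condition coded +1 at stage 2.
#' @param params an [elm_params()].
#' @param fold_seed fold-plan seed.
#' @return An object of class `cascade_result`: 3x3 `confusion_matrix`
#'   (rows truth, columns prediction, control first), metrics, and the
#'   per-subject decision table.
#' @export
run_cascade <- function(fs, stage1_spec, stage2_spec,
                        control = "healthy", positive2 = "generalized",
                        params = elm_params(), fold_seed = 1L) {
  conds <- sort(unique(fs$index$condition))
  if (length(conds) != 3 || !control %in% conds) {
    stop("cascade needs exactly three conditions including the control", call. = FALSE)
  }
  patho <- setdiff(conds, control)
  if (!positive2 %in% patho) stop("positive2 must be a pathological condition", call. = FALSE)
  other2 <- setdiff(patho, positive2)

  X1 <- build_design(fs, stage1_spec)
  X2 <- build_design(fs, stage2_spec)
  idx <- fs$index
  manifest <- unique(idx[, c("subject_id", "condition")])
  folds <- make_folds(manifest, seed = fold_seed)
  subj_rows <- split(idx$row, idx$subject_id)
  cond_of <- stats::setNames(manifest$condition, manifest$subject_id)

  map1 <- stats::setNames(ifelse(conds == control, -1L, 1L), conds)
  map2 <- stats::setNames(c(1L, -1L), c(positive2, other2))

  decisions <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr1 <- fold$train
    tr2 <- fold$train[cond_of[fold$train] %in% patho]
    rows1 <- unlist(subj_rows[tr1])
    rows2 <- unlist(subj_rows[tr2])
    p1 <- params
    p1$seed <- (params$seed + 7919L * fi) %% .Machine$integer.max
    p2 <- params
    p2$seed <- (params$seed + 7919L * fi + 104729L) %% .Machine$integer.max
    ens1 <- fit_ensemble(X1[rows1, , drop = FALSE], unname(map1[idx$condition[rows1]]), p1)
    ens2 <- fit_ensemble(X2[rows2, , drop = FALSE], unname(map2[idx$condition[rows2]]), p2)
    for (sid in fold$test) {
      rows <- subj_rows[[sid]]
      d1 <- classify_subject(predict_ensemble(ens1, X1[rows, , drop = FALSE])$label)
      if (d1$label == -1L) {
        final <- control
      } else {
        d2 <- classify_subject(predict_ensemble(ens2, X2[rows, , drop = FALSE])$label)
        final <- if (d2$label == 1L) positive2 else other2
      }
      decisions[[sid]] <- data.frame(
        subject_id = sid, truth = cond_of[[sid]], pred = final, fold = fi,
        stringsAsFactors = FALSE
      )
    }
  }
  decisions <- do.call(rbind, decisions[manifest$subject_id])
  labels <- c(control, positive2, other2)
  cm <- confusion_multiclass(decisions$truth, decisions$pred, labels)
  structure(
    list(
      decisions = decisions, cm = cm,
      metrics = confusion_metrics(cm, control_label = control)
    ),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "<cascade_result> 3-class accuracy %.3f (control recall %.3f)\n",
    x$metrics$accuracy, x$metrics$specificity
  ))
  print(x$cm)
  invisible(x)
}

#' AUC surface over the (eta, phi) parameter grid
#'
#' Runs a full cross-validated stage per grid point and records the
#' segment-level AUC. The ensemble size may be reduced for the scan
#' (pass a `params` with smaller `n_ensemble`).
#'
#' @param fs a `feature_set`.
#' @param spec a [feature_spec()].
#' @param class_map condition coding as in [run_stage()].
#' @param eta_grid,phi_grid numeric grids.
#' @param params an [elm_params()] used as the template.
#' @param fold_seed fold-plan seed.
#' @return Matrix of AUCs, rows = eta values, columns = phi values.
#' @export
param_scan <- function(fs, spec, class_map, eta_grid, phi_grid,
                       params = elm_params(), fold_seed = 1L) {
  stopifnot(length(eta_grid) >= 1, length(phi_grid) >= 1)
  out <- matrix(NA_real_, length(eta_grid), length(phi_grid),
    dimnames = list(
      paste0("eta=", signif(eta_grid, 4)),
      paste0("phi=", signif(phi_grid, 4))
    )
  )
  for (i in seq_along(eta_grid)) {
    for (j in seq_along(phi_grid)) {
      p <- params
      p$eta <- eta_grid[i]
      p$phi <- phi_grid[j]
      out[i, j] <- run_stage(fs, spec, class_map, p, fold_seed = fold_seed)$segment_auc
    }
  }
  out
}

#' Band-restricted feature-pair grid search
#'
#' For every pair (PLV band, relPSD band) of canonical bands, runs the
#' pathological-vs-pathological stage on the concatenation of the
#' band-restricted relative PSD and PLV features and records the
#' segment-level AUC. Rows index the PLV band, columns the relPSD band,
#' mirroring the pair-wise combination table of the analysis.
#'
#' @param fs a `feature_set` containing `relPSD` and `PLV` over the two
#'   pathological conditions (extra conditions are ignored via `class_map`).
#' @param class_map named +1/-1 coding of the two conditions.
#' @param params an [elm_params()].
#' @param fold_seed fold-plan seed.
#' @param bands canonical band names (default all five).
#' @return List with `auc` (5x5 matrix, rows PLV band, columns relPSD band)
#'   and `argmax` = c(plv_band, rel_band) of the largest AUC.
#' @export
band_grid_search <- function(fs, class_map, params = elm_params(),
                             fold_seed = 1L,
                             bands = names(fs$grid$canonical)) {
  out <- matrix(NA_real_, length(bands), length(bands),
    dimnames = list(paste0(bands, " (PLV)"), paste0(bands, " (Rel)"))
  )
  for (i in seq_along(bands)) {
    for (j in seq_along(bands)) {
      spec <- feature_spec(
        list(kind = "relPSD", band = bands[j]),
        list(kind = "PLV", band = bands[i])
      )
      out[i, j] <- run_stage(fs, spec, class_map, params, fold_seed = fold_seed)$segment_auc
    }
  }
  am <- which(out == max(out), arr.ind = TRUE)[1, ]
  list(auc = out, argmax = c(plv_band = bands[am[1]], rel_band = bands[am[2]]))
}
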