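test_that("fold plans test every subject exactly once, one per condition", {
  manifest <- data.frame(
    subject_id = sprintf("s%02d", 1:42),
    condition = rep(c("healthy", "generalized", "focal"), each = 14)
  )
  folds <- make_folds(manifest, seed = 3)
  expect_length(folds, 14)
  for (f in folds) {
    expect_length(f$test, 3)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), manifest$subject_id)
    conds <- substr(f$test, 1, 1) # one of each condition per fold
    expect_equal(
      sort(manifest$condition[match(f$test, manifest$subject_id)]),
      c("focal", "generalized", "healthy")
    )
  }
  tested <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tested, manifest$subject_id)
  expect_equal(anyDuplicated(tested), 0)

  # two-condition plan (second stage): 14 folds of 2 test subjects
  folds2 <- make_folds(manifest[manifest$condition != "healthy", ], seed = 3)
  expect_length(folds2, 14)
  expect_true(all(vapply(folds2, function(f) length(f$test), integer(1)) == 2))

  expect_error(make_folds(manifest[-1, ]), "unbalanced")
})

test_that("subject majority rule follows segment votes with ties to positive", {
  expect_equal(classify_subject(c(rep(1L, 26), rep(-1L, 14)))$label, 1L)
  expect_equal(classify_subject(c(rep(1L, 20), rep(-1L, 20)))$label, 1L)
  all_neg <- classify_subject(rep(-1L, 10))
  expect_equal(all_neg$label, -1L)
  expect_equal(all_neg$positive_fraction, 0)
  expect_error(classify_subject(integer(0)), "no segment")
})

test_that("confusion metrics reproduce the published worked examples", {
  m1 <- confusion_metrics(confusion_counts(TN = 12, FP = 2, FN = 2, TP = 26))
  expect_equal(round(m1$accuracy, 2), 0.90)
  expect_equal(round(m1$specificity, 2), 0.86)
  expect_equal(round(m1$sensitivity, 2), 0.93)

  m2 <- confusion_metrics(confusion_counts(TN = 12, FP = 2, FN = 0, TP = 14))
  expect_equal(round(m2$accuracy, 2), 0.93)
  expect_equal(round(m2$specificity, 2), 0.86)
  expect_equal(m2$sensitivity, 1)

  perfect <- confusion_metrics(confusion_counts(TN = 10, FP = 0, FN = 0, TP = 10))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))

  # degenerate denominators are flagged, not fabricated
  m3 <- confusion_metrics(confusion_counts(TN = 5, FP = 1, FN = 0, TP = 0))
  expect_true(is.na(m3$sensitivity))
})

test_that("the three-class table gives trace accuracy and control recall", {
  truth <- rep(c("healthy", "generalized", "focal"), each = 14)
  pred <- truth
  pred[c(1, 2)] <- "focal" # 2 healthy -> focal
  pred[15] <- "healthy"
  pred[c(16, 17)] <- "focal" # generalized: 1 -> healthy, 2 -> focal
  pred[29] <- "healthy" # 1 focal -> healthy
  cm <- confusion_multiclass(truth, pred, c("healthy", "generalized", "focal"))
  expect_equal(sum(diag(cm$table)), 36)
  m <- confusion_metrics(cm, control_label = "healthy")
  expect_equal(round(m$accuracy, 2), 0.86)
  expect_equal(round(m$specificity, 2), 0.86)
  expect_equal(rowSums(cm$table), c(healthy = 14, generalized = 14, focal = 14))
})

test_that("ROC/AUC matches the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))$auc, 1)
  set.seed(71)
  for (i in 1:5) {
    n <- 50
    scores <- round(runif(n), 2) # rounding forces ties
    truth <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(roc_auc(scores, truth)$auc, auc_bruteforce(scores, truth),
      tolerance = 1e-12
    )
  }
  # random scores: AUC near 1/2
  set.seed(72)
  r <- roc_auc(runif(1000), sample(c(-1L, 1L), 1000, replace = TRUE))
  expect_lt(abs(r$auc - 0.5), 0.05)
  # curve anchored at (0,0) and (1,1)
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC/AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  scores <- runif(200)
  truth <- ifelse(scores + rnorm(200, sd = 0.4) > 0.5, 1L, -1L)
  if (length(unique(truth)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores,
      levels = c(-1, 1), direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
  }
})

test_that("a cross-validated stage recovers a planted contrast", {
  specs <- list(
    class_spec("healthy"),
    class_spec("generalized", band_power_boost = c(beta1 = 2.2)),
    class_spec("focal", band_power_boost = c(beta1 = 2.2))
  )
  cfg <- desk_cohort_config(
    class_specs = specs, n_subjects_per_class = 4,
    n_segments = 6, n_sensors = 6, seed = 81
  )
  fs <- extract_features(generate_cohort(cfg), kinds = "relPSD")
  res <- run_stage(
    fs, feature_spec(list(kind = "relPSD", band = NULL)),
    c(healthy = -1L, generalized = 1L, focal = 1L),
    elm_params(D = 40, n_ensemble = 5, seed = 82),
    fold_seed = 83
  )
  expect_gte(res$metrics$accuracy, 0.9)
  # every subject decided exactly once
  expect_equal(nrow(res$subjects), 12)
  expect_equal(anyDuplicated(res$subjects$subject_id), 0)
  # confusion counts add up to the subject total
  cm <- res$cm
  expect_equal(cm$TN + cm$FP + cm$FN + cm$TP, 12)
})

test_that("the cascade routes subjects through both stages correctly", {
  coh <- tiny_cohort(seed = 84, n_subjects = 4, n_segments = 4, n_sensors = 6)
  fs <- extract_features(coh, kinds = c("relPSD", "PLV"))
  res <- run_cascade(
    fs,
    feature_spec(list(kind = "relPSD", band = NULL)),
    feature_spec(list(kind = "relPSD", band = "beta1"), list(kind = "PLV", band = "beta2")),
    params = elm_params(D = 40, n_ensemble = 5, seed = 85),
    fold_seed = 86
  )
  expect_equal(rowSums(res$cm$table), c(healthy = 4, generalized = 4, focal = 4))
  expect_equal(sum(res$cm$table), 12)
  # any subject labelled healthy at stage 1 never gets a pathological label
  healthy_pred <- res$decisions$pred[res$decisions$pred == "healthy"]
  expect_true(all(healthy_pred == "healthy"))
})

test_that("cascade accuracy never exceeds its stage-1 collapse", {
  coh <- tiny_cohort(seed = 87, n_subjects = 4, n_segments = 4, n_sensors = 6)
  fs <- extract_features(coh, kinds = c("relPSD", "PLV"))
  res <- run_cascade(
    fs,
    feature_spec(list(kind = "relPSD", band = NULL)),
    feature_spec(list(kind = "relPSD", band = "beta1"), list(kind = "PLV", band = "beta2")),
    params = elm_params(D = 40, n_ensemble = 3, seed = 88),
    fold_seed = 89
  )
  acc3 <- res$metrics$accuracy
  # collapse the same decisions to healthy vs pathological
  truth_bin <- res$decisions$truth == "healthy"
  pred_bin <- res$decisions$pred == "healthy"
  acc_collapse <- mean(truth_bin == pred_bin)
  expect_lte(acc3, acc_collapse)
})

test_that("an injected perfect stage-1/stage-2 oracle yields a diagonal table", {
  # cascade logic check independent of any classifier: route by true labels
  truth <- rep(c("healthy", "generalized", "focal"), each = 5)
  stage1 <- ifelse(truth == "healthy", -1L, 1L)
  final <- ifelse(stage1 == -1L, "healthy",
    ifelse(truth == "generalized", "generalized", "focal")
  )
  cm <- confusion_multiclass(truth, final, c("healthy", "generalized", "focal"))
  expect_equal(cm$table, diag(5L, 3)[, ],
    ignore_attr = TRUE
  )
})

test_that("parameter scan is finite and pi-periodic in phi", {
  coh <- tiny_cohort(seed = 90, n_subjects = 3, n_segments = 4, n_sensors = 5)
  fs <- extract_features(coh, kinds = "relPSD")
  spec <- feature_spec(list(kind = "relPSD", band = NULL))
  map <- c(healthy = -1L, generalized = 1L, focal = 1L)
  p <- elm_params(D = 20, n_ensemble = 3, seed = 91)
  surf <- param_scan(fs, spec, map, eta_grid = 0.1, phi_grid = c(2.1, 2.1 + pi), p,
    fold_seed = 92
  )
  expect_true(all(is.finite(surf)))
  expect_equal(surf[1, 1], surf[1, 2])
  # 1x1 grid equals a direct stage run
  single <- param_scan(fs, spec, map, 0.1, 2.1, p, fold_seed = 92)
  direct <- run_stage(fs, spec, map, {
    q <- p
    q$eta <- 0.1
    q$phi <- 2.1
    q
  }, fold_seed = 92)
  expect_equal(unname(single[1, 1]), direct$segment_auc)
})

test_that("band grid search returns the 5x5 table with PLV rows", {
  specs <- default_class_specs()[2:3]
  cfg <- desk_cohort_config(
    class_specs = specs, n_subjects_per_class = 4,
    n_segments = 4, n_sensors = 6, seed = 93
  )
  fs <- extract_features(generate_cohort(cfg), kinds = c("relPSD", "PLV"))
  bg <- band_grid_search(fs, c(generalized = 1L, focal = -1L),
    elm_params(D = 30, n_ensemble = 3, seed = 94),
    fold_seed = 95
  )
  expect_equal(dim(bg$auc), c(5, 5))
  expect_equal(rownames(bg$auc)[4], "beta2 (PLV)")
  expect_equal(colnames(bg$auc)[3], "beta1 (Rel)")
  expect_true(all(is.finite(bg$auc)))
  expect_named(bg$argmax, c("plv_band", "rel_band"))
})
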