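#!/usr/bin/env Rscript
# Stage 1: healthy vs epileptic under subject-wise leave-one-out CV.
#
# Each of the four feature kinds is evaluated alone at the segment level
# (ROC/AUC), then the best performer (relative PSD) is carried to the
# subject level via the segment majority rule. Expects scratch/features.rds
# from 02_features.R (PLI is computed here on demand if requested).

library(megelm)

master_seed <- 20260929L
fs <- readRDS("scratch/features.rds")
params <- elm_params(D = 100, n_ensemble = 11, seed = derive_seed(master_seed, "elm"))
fold_seed <- derive_seed(master_seed, "folds")
map1 <- c(healthy = -1L, generalized = 1L, focal = 1L)

kinds <- names(fs$arrays) # relPSD and PLV were extracted in 02
aucs <- vapply(kinds, function(k) {
  run_stage(fs, feature_spec(list(kind = k, band = NULL)), map1, params,
    fold_seed = fold_seed
  )$segment_auc
}, numeric(1))
cat("segment-level AUC per feature kind (healthy vs epileptic):\n")
print(round(aucs, 4))
write.csv(
  data.frame(kind = kinds, segment_auc = aucs),
  "results/03_stage1_feature_auc.csv",
  row.names = FALSE
)

best <- names(which.max(aucs))
cat("\nbest single feature:", best, "- subject-level results:\n")
s1 <- run_stage(fs, feature_spec(list(kind = best, band = NULL)), map1, params,
  fold_seed = fold_seed
)
print(s1)
print(s1$cm)
write.csv(s1$subjects, "results/03_stage1_subjects.csv", row.names = FALSE)
roc <- s1$segment_roc
write.csv(
  data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity, fpr = roc$fpr),
  "results/03_stage1_roc.csv",
  row.names = FALSE
)
cat(sprintf(
  "\nstage 1 (%s): accuracy %.3f, sensitivity %.3f, specificity %.3f, %d/%d subjects correct\n",
  best, s1$metrics$accuracy, s1$metrics$sensitivity, s1$metrics$specificity,
  s1$cm$TN + s1$cm$TP, s1$cm$n
))
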