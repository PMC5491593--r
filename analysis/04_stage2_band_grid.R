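#!/usr/bin/env Rscript
# Stage 2: generalized vs focal epilepsy, trained on epileptic subjects only.
#
# Full-grid features barely separate the two epilepsy types, so the features
# are restricted to canonical bands and all 25 pair-wise combinations of
# band-restricted relative PSD and PLV are scanned (rows = PLV band,
# columns = relPSD band). The best pair is then evaluated at the subject
# level. Expects scratch/features.rds from 02_features.R.

library(megelm)

master_seed <- 20260929L
fs <- readRDS("scratch/features.rds")
map2 <- c(generalized = 1L, focal = -1L)
fold_seed <- derive_seed(master_seed, "folds")

# reduced ensemble for the 25-cell scan; full ensemble for the final model
scan_params <- elm_params(D = 100, n_ensemble = 5, seed = derive_seed(master_seed, "elm"))
bg <- band_grid_search(fs, map2, scan_params, fold_seed = fold_seed)
cat("segment-level AUC for band-restricted feature pairs:\n")
print(round(bg$auc, 4))
cat(sprintf(
  "\nbest pair: %s PLV + %s relPSD\n",
  bg$argmax["plv_band"], bg$argmax["rel_band"]
))
write.csv(bg$auc, "results/04_stage2_band_grid_auc.csv")

best_spec <- feature_spec(
  list(kind = "relPSD", band = unname(bg$argmax["rel_band"])),
  list(kind = "PLV", band = unname(bg$argmax["plv_band"]))
)
params <- elm_params(D = 100, n_ensemble = 11, seed = derive_seed(master_seed, "elm"))
s2 <- run_stage(fs, best_spec, map2, params, fold_seed = fold_seed)
print(s2)
print(s2$cm)
write.csv(s2$subjects, "results/04_stage2_subjects.csv", row.names = FALSE)
roc <- s2$segment_roc
write.csv(
  data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity, fpr = roc$fpr),
  "results/04_stage2_roc.csv",
  row.names = FALSE
)
cat(sprintf(
  "\nstage 2 (%s relPSD + %s PLV): accuracy %.3f, %d/%d epileptic subjects correct\n",
  bg$argmax["rel_band"], bg$argmax["plv_band"], s2$metrics$accuracy,
  s2$cm$TN + s2$cm$TP, s2$cm$n
))
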