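#!/usr/bin/env Rscript
# Full three-condition classification: the two-stage cascade.
#
# Stage 1 (full relative PSD) decides healthy vs epileptic; subjects called
# epileptic are passed to stage 2 (beta1 relPSD + beta2 PLV) which decides
# generalized vs focal. Both stages share the fold partition so no subject's
# segments ever train a model that predicts them. Expects
# scratch/features.rds from 02_features.R.

library(megelm)

master_seed <- 20260929L
fs <- readRDS("scratch/features.rds")

cascade <- run_cascade(
  fs,
  stage1_spec = feature_spec(list(kind = "relPSD", band = NULL)),
  stage2_spec = feature_spec(
    list(kind = "relPSD", band = "beta1"),
    list(kind = "PLV", band = "beta2")
  ),
  control = "healthy", positive2 = "generalized",
  params = elm_params(D = 100, n_ensemble = 11, seed = derive_seed(master_seed, "elm")),
  fold_seed = derive_seed(master_seed, "folds")
)
print(cascade)
write.csv(as.data.frame(cascade$cm$table), "results/05_cascade_confusion.csv")
write.csv(cascade$decisions, "results/05_cascade_decisions.csv", row.names = FALSE)
cat(sprintf(
  "\ncascade: %d/%d subjects correct (accuracy %.3f, healthy recall %.3f)\n",
  sum(diag(cascade$cm$table)), sum(cascade$cm$table),
  cascade$metrics$accuracy, cascade$metrics$specificity
))
cat("per-class recall:\n")
print(round(cascade$metrics$per_class_recall, 3))
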