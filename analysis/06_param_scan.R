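#!/usr/bin/env Rscript
# Scan the classifier's input scaling (eta) and activation phase (phi) on the
# healthy-vs-epileptic stage and record the segment-level AUC surface.
#
# A reduced ensemble (3 members) keeps the 20-point scan cheap; the surface
# is flat enough that this suffices to locate the good operating region
# around eta ~ 0.1, phi ~ 2.1. Expects scratch/features.rds.

library(megelm)

master_seed <- 20260929L
fs <- readRDS("scratch/features.rds")

eta_grid <- c(0.025, 0.05, 0.1, 0.2, 0.4)
phi_grid <- c(0.5, 1.3, 2.1, 2.9)
surf <- param_scan(
  fs, feature_spec(list(kind = "relPSD", band = NULL)),
  c(healthy = -1L, generalized = 1L, focal = 1L),
  eta_grid, phi_grid,
  params = elm_params(D = 100, n_ensemble = 3, seed = derive_seed(master_seed, "elm")),
  fold_seed = derive_seed(master_seed, "folds")
)
cat("segment-level AUC over the (eta, phi) grid:\n")
print(round(surf, 4))
best <- which(surf == max(surf), arr.ind = TRUE)[1, ]
cat(sprintf(
  "\nbest grid point: %s, %s (AUC %.4f)\n",
  rownames(surf)[best[1]], colnames(surf)[best[2]], max(surf)
))
write.csv(surf, "results/06_param_scan_auc.csv")
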