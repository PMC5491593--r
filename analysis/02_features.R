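#!/usr/bin/env Rscript
# Extract the per-segment feature matrices (relative PSD and PLV) from the
# stored cohort and summarize the class contrasts they carry.
#
# Expects scratch/cohort from 01_simulate.R.

library(megelm)

cohort <- read_cohort("scratch/cohort")
fs <- extract_features(cohort, kinds = c("relPSD", "PLV"), verbose = TRUE)
print(fs)

g <- fs$grid
iv <- band_intervals(g)
band_label <- sprintf("[%g,%g)", iv[, "lo"], iv[, "hi"])

# class-mean feature profiles (averaged over sensors and segments)
profiles <- do.call(rbind, lapply(names(fs$arrays), function(kind) {
  do.call(rbind, lapply(unique(fs$index$condition), function(cond) {
    rows <- fs$index$condition == cond
    data.frame(
      kind = kind, condition = cond, band = band_label,
      mean_value = apply(fs$arrays[[kind]][rows, , , drop = FALSE], 3, mean)
    )
  }))
}))
write.csv(profiles, "results/02_class_band_profiles.csv", row.names = FALSE)

# where do the planted contrasts show up?
rel <- profiles[profiles$kind == "relPSD", ]
plv <- profiles[profiles$kind == "PLV", ]
show_contrast <- function(df, what) {
  wide <- reshape(df[, c("condition", "band", "mean_value")],
    idvar = "band", timevar = "condition", direction = "wide"
  )
  names(wide) <- sub("mean_value\\.", "", names(wide))
  wide$gen_vs_foc <- wide$generalized - wide$focal
  cat("\n", what, "- five largest generalized-vs-focal contrasts:\n")
  print(head(wide[order(-abs(wide$gen_vs_foc)), ], 5), row.names = FALSE)
  wide
}
rel_w <- show_contrast(rel, "relative PSD")
plv_w <- show_contrast(plv, "PLV strength")

dir.create("scratch", showWarnings = FALSE)
saveRDS(fs, "scratch/features.rds") # binary cache for the downstream scripts
cat("\nfeature set cached in scratch/features.rds\n")
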