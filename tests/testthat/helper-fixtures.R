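# Small deterministic fixtures shared across test files.

tiny_cohort <- function(seed = 1, n_subjects = 2, n_segments = 2,
                        n_sensors = 4, specs = NULL) {
  if (is.null(specs)) specs <- default_class_specs()
  generate_cohort(desk_cohort_config(
    class_specs = specs,
    n_subjects_per_class = n_subjects,
    n_segments = n_segments,
    n_sensors = n_sensors,
    seed = seed
  ))
}

null_class_specs <- function() {
  list(class_spec("healthy"), class_spec("generalized"), class_spec("focal"))
}

# Two well-separated Gaussian blobs, a linearly separable toy task.
blob_task <- function(n, d = 6, gap = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(ceiling(n / 2) * d, -gap), ncol = d),
    matrix(rnorm(floor(n / 2) * d, gap), ncol = d)
  )
  y <- c(rep(-1L, ceiling(n / 2)), rep(1L, floor(n / 2)))
  idx <- sample(nrow(X))
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

# Brute-force pairwise-comparison AUC (Mann-Whitney with ties = 1/2).
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
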