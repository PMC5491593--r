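test_that("band grid partitions 4-40 Hz into 18 bands and 5 canonical groups", {
  g <- band_grid()
  expect_equal(g$n_bands, 18)
  expect_equal(length(g$edges), 19)
  widths <- vapply(names(g$canonical), function(b) length(band_columns(g, b)), integer(1))
  expect_equal(unname(widths), c(2L, 3L, 3L, 4L, 6L))
  # canonical bands cover every fine column exactly once
  all_cols <- unlist(lapply(names(g$canonical), band_columns, grid = g))
  expect_equal(sort(all_cols), 1:18)
  expect_error(band_columns(g, "delta"), "unknown")
})

test_that("a pure tone concentrates its band power correctly", {
  t <- (0:799) / 160
  seg <- segment_array(matrix(sin(2 * pi * 11 * t), 1), 160)
  tp <- total_psd(seg)
  expect_gte(tp$values[1, 4] / sum(tp$values), 0.95) # [10,12) band
  # zero signal -> all-zero matrix
  z <- total_psd(segment_array(matrix(0, 1, 800), 160))
  expect_true(all(z$values == 0))
  # two equal tones -> equal band powers within 5%
  seg2 <- segment_array(matrix(sin(2 * pi * 11 * t) + sin(2 * pi * 25 * t), 1), 160)
  tp2 <- total_psd(seg2)
  expect_lt(abs(tp2$values[1, 4] - tp2$values[1, 11]) / tp2$values[1, 4], 0.05)
})

test_that("band powers obey Parseval for band-limited signals", {
  # sum of tones inside 4-40 Hz: total band power ~ signal variance
  t <- (0:1599) / 200
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 19 * t) + 0.3 * sin(2 * pi * 33 * t)
  seg <- segment_array(matrix(x, 1), 200)
  tp <- total_psd(seg)
  expect_lt(abs(sum(tp$values) - var(x)) / var(x), 0.02)
  # broadband signal: band sums cannot exceed the total variance
  set.seed(21)
  spec <- class_spec("h")
  seg2 <- generate_segment(spec, numeric(0), 1, 1600, 200)
  tp2 <- total_psd(seg2)
  expect_lt(sum(tp2$values), var(seg2$data[1, ]))
})

test_that("relative PSD rows sum to one and white noise is uniform", {
  set.seed(22)
  seg <- segment_array(matrix(rnorm(3 * 3200), 3), 160)
  rp <- relative_psd(total_psd(seg))
  expect_equal(rowSums(rp$values), rep(1, 3), tolerance = 1e-9)
  expect_true(all(rp$values >= 0 & rp$values <= 1))
  # flat spectrum: each band's share ~ its bandwidth share 2/36
  expect_lt(max(abs(colMeans(rp$values) - 2 / 36)), 0.02)
  # constant rows -> every entry 1/18
  fm <- new_feature_matrix(matrix(5, 2, 18), "totalPSD", band_grid())
  expect_true(all(relative_psd(fm)$values == 1 / 18))
  # degenerate sensor flagged
  fm0 <- new_feature_matrix(rbind(rep(1, 18), rep(0, 18)), "totalPSD", band_grid())
  expect_error(relative_psd(fm0), "degenerate")
})

test_that("band-limited phases advance at the tone frequency", {
  t <- (0:799) / 160
  seg <- segment_array(matrix(sin(2 * pi * 11 * t), 1), 160)
  ph <- band_phases(seg, c(10, 12))
  d <- diff(ph[1, ])
  d <- ((d + pi) %% (2 * pi)) - pi
  f_est <- mean(d) * 160 / (2 * pi)
  expect_lt(abs(f_est - 11) / 11, 0.01)
  # identical sensors -> zero phase difference at all retained samples
  seg2 <- segment_array(rbind(seg$data[1, ], seg$data[1, ]), 160)
  ph2 <- band_phases(seg2, c(10, 12))
  expect_equal(max(abs(ph2[1, ] - ph2[2, ])), 0)
  # edge guard: 10% of samples dropped at each end
  expect_equal(ncol(ph), 800 - 2 * 80)
  expect_error(band_phases(seg, c(70, 90)), "outside")
})

test_that("PLV and PLI closed-form cases hold", {
  p <- runif(300, -pi, pi)
  expect_equal(plv_pair(p, p), 1)
  expect_equal(pli_pair(p, p), 0) # sign(sin(0)) = 0
  expect_equal(plv_pair(p + pi / 2, p), 1)
  expect_equal(pli_pair(p + pi / 2, p), 1)
  # phase differences symmetric about zero cancel in PLI
  delta <- rep(c(pi / 4, -pi / 4), 150)
  expect_equal(pli_pair(p + delta, p), 0)
  expect_error(plv_pair(p, p[-1]), "length")
  expect_error(pli_pair(p, p[-1]), "length")
})

test_that("independent uniform phases give the predicted chance PLV", {
  set.seed(23)
  T_len <- 400
  draws <- replicate(1000, plv_pair(runif(T_len, -pi, pi), runif(T_len, -pi, pi)))
  expect_lt(abs(mean(draws) - sqrt(pi) / (2 * sqrt(T_len))), 0.005)
})

test_that("connectivity matrix equals the brute-force pair loop", {
  set.seed(24)
  spec <- class_spec("c", coupling = data.frame(band = "alpha", strength = 0.5, lag = 0.3))
  seg <- generate_segment(spec, numeric(0), 6, 640, 160)
  for (kind in c("PLV", "PLI")) {
    cm <- connectivity_matrix(seg, "alpha", kind)
    ph <- band_phases(seg, "alpha")
    pair_fun <- if (kind == "PLV") plv_pair else pli_pair
    brute <- matrix(0, 6, 6)
    for (i in 1:5) {
      for (j in (i + 1):6) {
        brute[i, j] <- brute[j, i] <- pair_fun(ph[i, ], ph[j, ])
      }
    }
    expect_lt(max(abs(cm$values - brute)), 1e-9)
    expect_equal(cm$values, t(cm$values))
    expect_true(all(diag(cm$values) == 0))
    expect_true(all(cm$values >= 0 & cm$values <= 1))
  }
})

test_that("proportional thresholding keeps the largest links", {
  m <- matrix(0, 4, 4)
  vals <- c(0.9, 0.2, 0.5, 0.8, 0.1, 0.6)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  th <- threshold_proportional(m, 0.5)
  kept <- th[upper.tri(th)]
  expect_equal(sum(kept > 0), 3)
  expect_setequal(kept[kept > 0], c(0.9, 0.8, 0.6))
  expect_equal(th, t(th))
  # keep_fraction = 1 is the identity
  expect_equal(threshold_proportional(m, 1), m)
  # ties at the cutoff resolve by pair index, deterministically
  m2 <- matrix(0.5, 4, 4)
  diag(m2) <- 0
  th2a <- threshold_proportional(m2, 0.5)
  th2b <- threshold_proportional(m2, 0.5)
  expect_identical(th2a, th2b)
  expect_equal(sum(th2a[upper.tri(th2a)] > 0), 3)
})

test_that("sensor strength averages over all n-1 partners", {
  m <- matrix(0.7, 5, 5)
  diag(m) <- 0
  expect_equal(sensor_strength(m), rep(0.7, 5))
  # star graph: hub connected to all, periphery only to the hub
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(sensor_strength(star), c(1, 1 / 3, 1 / 3, 1 / 3))
  # thresholding can only lower strengths
  set.seed(25)
  mm <- matrix(0, 6, 6)
  mm[upper.tri(mm)] <- runif(15)
  mm <- mm + t(mm)
  expect_true(all(sensor_strength(threshold_proportional(mm, 0.4)) <= sensor_strength(mm)))
})

test_that("feature matrices have the right shape and tie behaviour", {
  set.seed(26)
  spec <- class_spec("h")
  seg <- generate_segment(spec, numeric(0), 5, 640, 160)
  for (kind in c("totalPSD", "relPSD", "PLV", "PLI")) {
    fm <- feature_matrix(seg, kind)
    expect_equal(dim(fm$values), c(5, 18))
  }
  # identical sensors: every pair ties at PLV 1, threshold keeps 40% of pairs,
  # strengths = kept links / (n-1); total kept = ceiling(0.4 * 10) = 4
  seg_id <- segment_array(matrix(rep(seg$data[1, ], 5), 5, byrow = TRUE), 160)
  fm_id <- feature_matrix(seg_id, "PLV")
  expect_equal(sum(fm_id$values[, 1] * 4), 2 * ceiling(0.4 * 10), tolerance = 1e-9)
})

test_that("feature operations are equivariant under sensor permutation", {
  set.seed(27)
  spec <- class_spec("c", coupling = data.frame(band = "beta2", strength = 0.6, lag = 0.5))
  seg <- generate_segment(spec, numeric(0), 5, 640, 160)
  perm <- c(3, 1, 5, 2, 4)
  seg_p <- segment_array(seg$data[perm, ], 160)
  for (kind in c("relPSD", "PLI")) {
    fm <- feature_matrix(seg, kind)
    fm_p <- feature_matrix(seg_p, kind)
    expect_equal(fm_p$values, fm$values[perm, ], tolerance = 1e-9)
  }
})

test_that("band restriction and combination give the documented dimensions", {
  g <- band_grid()
  fm <- new_feature_matrix(matrix(runif(102 * 18), 102, 18), "relPSD", g)
  r <- restrict_to_band(fm, "beta1")
  expect_equal(dim(r$values), c(102, 3))
  # full single feature flattens to 102 x 18 = 1,836
  fv <- combine_features(list(fm))
  expect_equal(length(fv$values), 1836)
  # beta1 relPSD + beta2 PLV for 102 sensors: 102*3 + 102*4 = 714
  fm2 <- new_feature_matrix(matrix(runif(102 * 18), 102, 18), "PLV", g)
  fv2 <- combine_features(list(restrict_to_band(fm, "beta1"), restrict_to_band(fm2, "beta2")))
  expect_equal(length(fv2$values), 714)
  expect_equal(fv2$provenance$band, c("beta1", "beta2"))
  expect_error(combine_features(list()), "empty")
  # mixed segments rejected
  fa <- fm
  fa$segment_ref <- list(subject_id = "a", segment_index = 1L)
  fb <- fm2
  fb$segment_ref <- list(subject_id = "b", segment_index = 1L)
  expect_error(combine_features(list(fa, fb)), "different segments")
})

test_that("build_design matches per-segment combine_features flattening", {
  coh <- tiny_cohort(seed = 31, n_subjects = 1, n_segments = 2, n_sensors = 4)
  fs <- extract_features(coh, kinds = c("relPSD", "PLV"))
  X <- build_design(fs, feature_spec(
    list(kind = "relPSD", band = "beta1"),
    list(kind = "PLV", band = "beta2")
  ))
  seg <- coh$subjects[[1]]$segments[[1]]
  fv <- combine_features(list(
    restrict_to_band(feature_matrix(seg, "relPSD"), "beta1"),
    restrict_to_band(feature_matrix(seg, "PLV"), "beta2")
  ))
  expect_equal(X[1, ], fv$values, tolerance = 1e-12)
  expect_equal(dim(X), c(nrow(fs$index), 4 * 3 + 4 * 4))
})
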