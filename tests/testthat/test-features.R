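# Feature extraction, z-scoring, PCA and species profiles.

make_drum <- function(times, amps = rep(1, length(times)), pf = 1000,
                      sp = "spA") {
  d <- structure(list(species_id = sp, strike_times = times,
                      amplitudes = amps / max(amps), peak_freq = pf),
                 class = "drum")
  d
}

test_that("constant-interval drums give degenerate jitter features", {
  d <- make_drum(seq(0, 0.9, by = 0.1))
  f <- extract_features(d)
  expect_equal(f[["n_strikes"]], 10)
  expect_equal(f[["duration"]], 0.9)
  expect_equal(f[["ipi_cv"]], 0)
  expect_equal(f[["amp_cv"]], 0)
  expect_equal(f[["pulse_rate"]], 10 / 0.9)
  expect_equal(f[["accel_slope"]], 0)
  expect_equal(f[["n_bouts"]], 1)
  expect_equal(f[["bout_size_mean"]], 10)
  expect_equal(f[["inter_bout_ipi_mean"]], 0)
  expect_error(extract_features(make_drum(0)), "2 strikes")
})

test_that("acceleration and max-IPI position features behave as defined", {
  shortening <- make_drum(cumsum(c(0, 0.3, 0.25, 0.2, 0.15, 0.1)))
  f <- extract_features(shortening)
  expect_lt(f[["accel_slope"]], 0)
  expect_equal(f[["ipi_max_first"]], 1)
  expect_equal(f[["ipi_max_last"]], 0)
  expect_equal(f[["ipi_max_pos"]], 0)

  lengthening <- make_drum(cumsum(c(0, 0.1, 0.15, 0.2, 0.25, 0.3)))
  g <- extract_features(lengthening)
  expect_gt(g[["accel_slope"]], 0)
  expect_equal(g[["ipi_max_last"]], 1)
  expect_equal(g[["ipi_max_pos"]], 1)
})

test_that("every feature of a hand-built 6-strike drum equals its oracle", {
  tt <- c(0, 0.10, 0.25, 0.33, 0.80, 0.95)
  aa <- c(0.9, 1, 0.8, 0.7, 0.6, 0.5)
  f <- extract_features(make_drum(tt, aa, pf = 1234))
  d <- c(0.10, 0.15, 0.08, 0.47, 0.15)
  # spreadsheet-style recomputation, term by term
  expect_equal(f[["n_strikes"]], 6)
  expect_equal(f[["duration"]], 0.95)
  expect_equal(f[["ipi_mean"]], sum(d) / 5)
  expect_equal(f[["ipi_sd"]], sqrt(sum((d - mean(d))^2) / 4))
  expect_equal(f[["ipi_cv"]], sqrt(sum((d - mean(d))^2) / 4) / (sum(d) / 5))
  expect_equal(f[["ipi_min"]], 0.08)
  expect_equal(f[["ipi_max"]], 0.47)
  expect_equal(f[["ipi_max_pos"]], 3 / 4)   # 4th of 5 IPIs
  expect_equal(f[["ipi_max_first"]], 0)
  expect_equal(f[["ipi_max_last"]], 0)
  expect_equal(f[["pulse_rate"]], 6 / 0.95)
  x <- 1:5
  expect_equal(f[["accel_slope"]],
               sum((x - 3) * (d - mean(d))) / sum((x - 3)^2))
  expect_equal(f[["amp_mean"]], mean(aa))
  expect_equal(f[["amp_sd"]], sd(aa))
  expect_equal(f[["amp_cv"]], sd(aa) / mean(aa))
  expect_equal(f[["amp_slope"]],
               sum((1:6 - 3.5) * (aa - mean(aa))) / sum((1:6 - 3.5)^2))
  expect_equal(f[["amp_last_first"]], 0.5 / 0.9)
  # median IPI 0.15, threshold 0.45: single gap of 0.47 -> bouts (4, 2)
  expect_equal(f[["n_bouts"]], 2)
  expect_equal(f[["bout_size_mean"]], 3)
  expect_equal(f[["bout_size_cv"]], sd(c(4, 2)) / 3)
  expect_equal(f[["inter_bout_ipi_mean"]], 0.47)
  expect_equal(f[["peak_freq"]], 1234)
})

test_that("z-scoring and PCA satisfy their invariants", {
  ds <- generate_dataset(n_species = 15, drums_per_species = c(3, 6),
                         seed = 31)
  ds <- standardize_and_pca(feature_matrix(ds))
  Z <- ds$z$matrix
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-8)
  # round trip through the stored parameters
  expect_equal(unname(apply_zscore(ds, ds$features)), unname(Z),
               tolerance = 1e-12)
  # score means zero, score variances equal eigenvalues
  expect_lt(max(abs(colMeans(ds$pca$scores))), 1e-8)
  expect_equal(unname(apply(ds$pca$scores, 2, var)),
               unname(ds$pca$eigenvalues), tolerance = 1e-8)
  expect_true(all(ds$pca$eigenvalues[ds$pca$retained] > 1))
  # sign convention: largest-magnitude loading positive
  for (j in ds$pca$retained) {
    l <- ds$pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("degenerate feature matrices are caught or flagged", {
  ds <- generate_dataset(n_species = 10, drums_per_species = c(3, 4),
                         seed = 5)
  ds <- feature_matrix(ds)
  ds$features[, "peak_freq"] <- 7   # constant column
  expect_error(standardize_and_pca(ds), "peak_freq")
  expect_message(standardize_and_pca(ds, drop_constant = TRUE),
                 "peak_freq")

  # i.i.d. noise: retained-set instability is flagged
  ds$features <- matrix(rnorm(500 * 22), 500, 22,
                        dimnames = list(NULL, feature_names()))
  set.seed(88)
  ds$features[] <- rnorm(500 * 22)
  expect_warning(standardize_and_pca(ds), "unstable")

  # two perfectly correlated features load equally (up to sign) on PC1
  set.seed(13)
  ds$features[] <- rnorm(500 * 22)
  ds$features[, 2] <- ds$features[, 1]
  dsc <- suppressWarnings(standardize_and_pca(ds))
  l1 <- dsc$pca$loadings[, 1]
  expect_equal(abs(unname(l1[1])), abs(unname(l1[2])), tolerance = 1e-8)
})

test_that("species profiles apply the minimum-drums filter", {
  ds <- generate_dataset(n_species = 10, drums_per_species = c(4, 6),
                         seed = 17)
  ds <- standardize_and_pca(feature_matrix(ds))
  # clone one species' first drum so all its drums are identical
  target <- ds$species$species_id[1]
  idx <- which(ds$drum_species == target)
  for (i in idx) ds$drums[[i]] <- ds$drums[[idx[1]]]
  ds <- standardize_and_pca(feature_matrix(ds))
  dsp <- species_profiles(ds)
  expect_equal(unname(dsp$profiles[target, ]),
               unname(dsp$z$matrix[idx[1], ]))

  # drop a species below 3 drums
  drop_sp <- ds$species$species_id[2]
  keep <- which(ds$drum_species != drop_sp)
  ds2 <- ds
  ds2$drums <- c(ds$drums[keep], ds$drums[which(ds$drum_species == drop_sp)[1:2]])
  ds2 <- standardize_and_pca(feature_matrix(ds2))
  expect_warning(ds2 <- species_profiles(ds2), drop_sp)
  expect_false(drop_sp %in% rownames(ds2$profiles))
})

test_that("the full-scale dataset yields a 92 x 22 profile matrix", {
  ds <- shared_dataset()
  expect_equal(dim(ds$profiles), c(92, 22))
  expect_gte(sum(ds$pca$var_explained[ds$pca$retained]), 0.60)
})

test_that("feature extraction is permutation-safe", {
  ds <- generate_dataset(n_species = 6, drums_per_species = c(3, 4),
                         seed = 23)
  ds <- feature_matrix(ds)
  perm <- rev(seq_along(ds$drums))
  ds2 <- ds
  ds2$drums <- ds$drums[perm]
  ds2 <- feature_matrix(ds2)
  expect_equal(ds2$features, ds$features[perm, ])
})
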