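test_that("generated datasets have the configured shape", {
  cfg <- generator_config(n_clusters = 3, subjects_per_cluster = 5,
                          n_trials = 10, n_channels = 8, fs = 32,
                          trial_length_s = 60, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$personalities), 15)
  expect_equal(length(ds$recordings), 150)
  expect_equal(dim(ds$recordings[[1]]$signal), c(8, 1920))
  expect_equal(nrow(ds$ratings), 150)
  expect_true(all(ds$ratings$valence >= -3 & ds$ratings$valence <= 3))
  expect_true(all(ds$ratings$arousal >= 0 & ds$ratings$arousal <= 6))
  expect_equal(ncol(ds$personalities) - 1L, 5L)
})

test_that("generation is deterministic in the seed", {
  cfg <- generator_config(2, 2, n_trials = 2, trial_length_s = 6, seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$personalities, d2$personalities)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(
    lapply(d1$recordings, `[[`, "signal"),
    lapply(d2$recordings, `[[`, "signal")
  )
  d3 <- generate_dataset(generator_config(2, 2, n_trials = 2,
                                          trial_length_s = 6, seed = 32))
  expect_false(identical(d1$recordings[[1]]$signal, d3$recordings[[1]]$signal))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(cluster_sep = -1), "nonnegative")
  expect_error(generator_config(trial_length_s = 1 / 64), "analysis window")
  expect_error(generator_config(n_clusters = 2,
                                informative_channels = list(`0` = 0L)),
               "keys")
  expect_error(generator_config(n_channels = 4,
                                informative_channels = list(`0` = 7L, `1` = 1L, `2` = 2L)),
               "indices")
})

test_that("well-separated personalities are recovered by k-means exactly", {
  cfg <- generator_config(3, 5, n_trials = 2, trial_length_s = 6,
                          cluster_sep = 10, seed = 5)
  ds <- generate_dataset(cfg)
  fit <- fit_kmeans(ds$personalities, 3, seed = 9)
  expect_equal(partition_agreement(unname(fit$assignment[ds$personalities$subject_id]),
                                   unname(ds$true_cluster[ds$personalities$subject_id])),
               1.0)
})

test_that("latent states are balanced per subject", {
  ds <- small_dataset()
  per <- tapply(ds$latent$z_valence, ds$latent$subject_id, mean)
  expect_true(all(per == 0.5))   # even trial count -> exact balance
  per_a <- tapply(ds$latent$z_arousal, ds$latent$subject_id, mean)
  expect_true(all(per_a == 0.5))
})

test_that("median split of ratings recovers the latent states", {
  ds <- small_dataset()
  for (ax in c("valence", "arousal")) {
    lab <- binarize_labels(ds$ratings[[ax]])$labels
    z <- ds$latent[[paste0("z_", ax)]]
    expect_equal(lab, z)
  }
})

test_that("label-state band-power contrast sits on the informative channels", {
  # direct periodogram oracle, independent of the DE pipeline
  cfg <- generator_config(2, 2, n_trials = 6, trial_length_s = 20,
                          background_jitter_sd = 0, artifact_prob = 0, seed = 77)
  ds <- generate_dataset(cfg)
  bands <- list(`0` = c(4, 8), `1` = c(8, 11))  # valence carriers per cluster
  for (cl in 0:1) {
    subs <- names(ds$true_cluster)[ds$true_cluster == cl]
    pw <- matrix(0, 2, cfg$n_channels)  # rows: state 0 / state 1
    cnt <- c(0, 0)
    for (rec in ds$recordings) {
      if (!rec$subject_id %in% subs) next
      z <- ds$latent$z_valence[ds$latent$subject_id == rec$subject_id &
                               ds$latent$trial_id == rec$trial_id]
      b <- bands[[as.character(cl)]]
      for (m in seq_len(cfg$n_channels)) {
        pw[z + 1, m] <- pw[z + 1, m] + band_power_fft(rec$signal[m, ], cfg$fs, b[1], b[2])
      }
      cnt[z + 1] <- cnt[z + 1] + 1
    }
    contrast <- abs(pw[2, ] / cnt[2] - pw[1, ] / cnt[1])
    expect_equal(which.max(contrast) - 1L,
                 ds$true_informative_channels[[as.character(cl)]])
  }
})

test_that("write/read round-trips the dataset", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  man <- write_dataset(ds, file.path(dir, "ds"))
  expect_equal(sum(grepl("^signals/", man$file)), length(ds$recordings))
  expect_true(all(file.exists(file.path(dir, "ds", man$file))))

  back <- read_dataset(file.path(dir, "ds"))
  expect_equal(length(back$recordings), length(ds$recordings))
  key <- function(r) paste(r$subject_id, r$trial_id)
  ord <- match(vapply(ds$recordings, key, character(1)),
               vapply(back$recordings, key, character(1)))
  for (i in seq_along(ds$recordings)) {
    expect_equal(back$recordings[[ord[i]]]$signal, ds$recordings[[i]]$signal,
                 tolerance = 1e-8)
  }
  expect_equal(back$personalities$O, ds$personalities$O, tolerance = 1e-12)
  expect_equal(unname(back$true_cluster[names(ds$true_cluster)]),
               unname(ds$true_cluster))
})

test_that("degenerate write targets error", {
  ds <- small_dataset()
  empty <- ds
  empty$recordings <- list()
  dir <- withr::local_tempdir()
  expect_error(write_dataset(empty, file.path(dir, "x")), "empty")
  expect_error(write_dataset(ds, file.path(dir, "no", "such", "parent")),
               "parent")
})
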