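# Shared fixtures. Everything is generated in code; heavier objects are
# memoised per test run.

tiny_model_config <- function(..., seed = 7L) {
  model_config(n_bands = 3, n_channels = 4, n_segments = 3,
               d_a = 5, d_h = 4, u = 3, K = 2, v = 4, seed = seed, ...)
}

small_eval_model_config <- function(...) {
  model_config(n_bands = 5, n_channels = 8, n_segments = 9,
               d_a = 8, d_h = 8, u = 8, K = 4, v = 16, ...)
}

# one small clustered dataset, shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(generator_config(
      n_clusters = 2, subjects_per_cluster = 3, n_trials = 4,
      trial_length_s = 18, cluster_sep = 8, seed = 402
    ))
  }
  .fixture_env$ds
}

small_features <- function() {
  if (is.null(.fixture_env$feats)) {
    .fixture_env$feats <- prepare_features(small_dataset())
  }
  .fixture_env$feats
}

# random batch for model-level tests
random_batch <- function(cfg, B = 3, seed = 99) {
  withr::with_seed(seed, {
    list(
      X = array(rnorm(cfg$F * cfg$M * cfg$N * B), c(cfg$F, cfg$M, cfg$N, B)),
      y = sample(0:1, B, replace = TRUE)
    )
  })
}

# independent band-power oracle: integrate the periodogram over a band;
# deliberately avoids bw_filter / compute_de
band_power_fft <- function(x, fs, low, high) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= low & f <= high
  2 * sum(sp[keep])
}

# exhaustive k-means oracle: minimum distortion over all assignments of the
# rows of X into P non-empty clusters (centroid = cluster mean)
brute_force_kmeans <- function(X, P) {
  n <- nrow(X)
  best <- Inf
  for (code in 0:(P^n - 1)) {
    a <- integer(n)
    cc <- code
    for (i in seq_len(n)) {
      a[i] <- cc %% P
      cc <- cc %/% P
    }
    if (length(unique(a)) < P) next
    d <- 0
    for (j in 0:(P - 1)) {
      Xi <- X[a == j, , drop = FALSE]
      mu <- colMeans(Xi)
      d <- d + sum(sweep(Xi, 2, mu)^2)
    }
    if (d < best) best <- d
  }
  best
}

# adjusted agreement of two labelings up to permutation: fraction of pairs
# on which the partitions agree (1 iff identical as partitions)
partition_agreement <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
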