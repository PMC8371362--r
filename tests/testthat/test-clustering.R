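mk_profiles <- function(X, ids = sprintf("s%02d", seq_len(nrow(X)))) {
  data.frame(subject_id = ids, O = X[, 1], C = X[, 2], E = X[, 3],
             A = X[, 4], N = X[, 5], stringsAsFactors = FALSE)
}

test_that("two well-separated groups are split perfectly", {
  withr::with_seed(1, {
    X <- rbind(matrix(rnorm(15, 0, 0.1), 3), matrix(rnorm(15, 10, 0.1), 3))
  })
  p <- mk_profiles(X)
  fit <- fit_kmeans(p, 2, seed = 4)
  a <- fit$assignment
  expect_equal(length(unique(a[1:3])), 1)
  expect_equal(length(unique(a[4:6])), 1)
  expect_false(a[1] == a[4])
  for (j in 0:1) {
    members <- X[a == j, , drop = FALSE]
    expect_lt(max(abs(fit$centroids[j + 1, ] - colMeans(members))), 1e-9)
  }
})

test_that("P = 1 collapses to the global mean and total sum of squares", {
  withr::with_seed(2, X <- matrix(rnorm(35), 7))
  fit <- fit_kmeans(mk_profiles(X), 1, seed = 1)
  expect_equal(as.vector(fit$centroids), colMeans(X), tolerance = 1e-12)
  expect_equal(fit$distortion, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-10)
})

test_that("Lloyd with restarts attains the exhaustive-enumeration optimum", {
  withr::with_seed(3, X7 <- matrix(rnorm(35), 7))
  fit <- fit_kmeans(mk_profiles(X7), 2, seed = 11, n_restarts = 20)
  expect_equal(fit$distortion, brute_force_kmeans(X7, 2), tolerance = 1e-9)

  withr::with_seed(4, X6 <- matrix(rnorm(30), 6))
  fit3 <- fit_kmeans(mk_profiles(X6), 3, seed = 11, n_restarts = 30)
  expect_equal(fit3$distortion, brute_force_kmeans(X6, 3), tolerance = 1e-9)
})

test_that("converged centroids are fixed points of the mean update", {
  ds <- small_dataset()
  fit <- fit_kmeans(ds$personalities, 2, seed = 5)
  X <- as.matrix(ds$personalities[, -1])
  rownames(X) <- ds$personalities$subject_id
  for (j in sort(unique(fit$assignment))) {
    mu <- colMeans(X[names(fit$assignment)[fit$assignment == j], , drop = FALSE])
    expect_lt(max(abs(mu - fit$centroids[j + 1, ])), 1e-12)
  }
})

test_that("the partition is invariant to subject order under the same seed", {
  ds <- small_dataset()
  p <- ds$personalities
  fit1 <- fit_kmeans(p, 2, seed = 13)
  withr::with_seed(1, p2 <- p[sample(nrow(p)), ])
  fit2 <- fit_kmeans(p2, 2, seed = 13)
  ids <- p$subject_id
  expect_equal(partition_agreement(unname(fit1$assignment[ids]),
                                   unname(fit2$assignment[ids])), 1.0)
})

test_that("invalid clustering inputs are rejected", {
  ds <- small_dataset()
  expect_error(fit_kmeans(ds$personalities, 7), "P = 7")
  dup <- rbind(ds$personalities, ds$personalities[1, ])
  expect_error(fit_kmeans(dup, 2), "duplicate")
  expect_error(fit_kmeans(ds$personalities[, 1:4], 2), "5 components")
})

test_that("the elbow curve is non-increasing and vanishes at P = n", {
  ds <- small_dataset()
  n <- nrow(ds$personalities)
  curve <- elbow_curve(ds$personalities, seq_len(n), seed = 2, n_restarts = 5)
  expect_equal(nrow(curve), n)
  expect_true(all(diff(curve$distortion) <= 1e-9))
  expect_lt(curve$distortion[n], 1e-9)
})

test_that("the largest relative distortion drop occurs at the true cluster count", {
  ds <- generate_dataset(generator_config(3, 5, n_trials = 2, trial_length_s = 6,
                                          cluster_sep = 8, seed = 6))
  curve <- elbow_curve(ds$personalities, 1:6, seed = 3, n_restarts = 10)
  drops <- curve$distortion[-nrow(curve)] / curve$distortion[-1]
  expect_equal(curve$P[which.max(drops) + 1], 3)
})

test_that("cluster routing follows the nearest-centroid rule with low-index ties", {
  ds <- small_dataset()
  fit <- fit_kmeans(ds$personalities, 2, seed = 5)
  expect_equal(assign_cluster(fit, fit$centroids[2, ]), 1L)
  mid <- colMeans(fit$centroids)
  expect_equal(assign_cluster(fit, mid), 0L)
  # self-consistency: re-routing training subjects reproduces the assignment
  for (i in seq_len(nrow(ds$personalities))) {
    expect_equal(assign_cluster(fit, ds$personalities[i, ]),
                 unname(fit$assignment[ds$personalities$subject_id[i]]))
  }
  expect_error(assign_cluster(fit, c(1, 2, 3)), "5 components")
})
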