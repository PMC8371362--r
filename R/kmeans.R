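#' k-means clustering of Big-Five personality profiles
#'
#' Plain Lloyd iteration on the 5-dimensional OCEAN vectors: assign each
#' subject to the nearest centroid by squared Euclidean distance, recompute
#' each centroid as the mean of its members, repeat until assignments are
#' stable or `max_iter`. Initial centroids are `P` distinct data points drawn
#' at random; `n_restarts` independent initializations are run and the fit
#' with the lowest distortion (sum of squared distances to assigned
#' centroids) is kept. An emptied cluster is re-seeded with the point
#' farthest from its current assignment's centroid. Initial points are drawn
#' from a canonical (lexicographic) ordering of the profiles, so the fit is
#' invariant to subject order under the same seed.
#'
#' @param profiles data.frame with `subject_id` and the five OCEAN columns
#'   (any five numeric columns after `subject_id`), or a numeric matrix with
#'   rownames as subject ids.
#' @param P number of clusters (1..n subjects).
#' @param seed integer seed for the restarts.
#' @param n_restarts independent random initializations (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @param scale z-score the personality columns first (default FALSE; raw
#'   questionnaire units).
#' @return object of class `personality_kmeans`: `P`, `centroids` (P x 5),
#'   `assignment` (named integer, 0-based cluster per subject), `distortion`,
#'   `n_iter`, `seed`, `scale` (and, when `scale = TRUE`, the centering and
#'   scaling vectors used).
#' @export
fit_kmeans <- function(profiles, P, seed = 1L, n_restarts = 10L,
                       max_iter = 100L, scale = FALSE) {
  X <- profile_matrix(profiles)
  n <- nrow(X)
  if (anyDuplicated(rownames(X))) stopf("duplicate subject_ids in profiles")
  if (P < 1 || P > n) stopf("P = %d must lie in 1..%d (number of subjects)", P, n)
  ctr <- NULL
  scl <- NULL
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  # canonical order makes initialization independent of row permutation
  canon <- do.call(order, as.data.frame(X))
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(X[canon, , drop = FALSE], P, max_iter)
      if (is.null(best) || fit$distortion < best$distortion - 1e-12) best <- fit
    }
  })
  assignment <- integer(n)
  assignment[canon] <- best$assignment
  names(assignment) <- rownames(X)
  structure(
    list(P = as.integer(P), centroids = best$centroids,
         assignment = assignment, distortion = best$distortion,
         n_iter = best$n_iter, seed = as.integer(seed),
         scale = scale, center_vec = ctr, scale_vec = scl),
    class = "personality_kmeans"
  )
}

# One Lloyd run from a random distinct-point initialization. X rows are in
# canonical order; returns 0-based assignment in that order.
lloyd_once <- function(X, P, max_iter) {
  n <- nrow(X)
  uniq <- !duplicated(X)
  pool <- which(uniq)
  if (length(pool) < P) pool <- seq_len(n)   # fewer distinct points than P
  init <- sample(pool, P)
  mu <- X[init, , drop = FALSE]
  assign_old <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(X, mu)
    assign_new <- max.col(-d2, ties.method = "first") - 1L
    for (j in seq_len(P) - 1L) {
      if (!any(assign_new == j)) {
        # re-seed an emptied cluster with the worst-fit point
        worst <- which.max(d2[cbind(seq_len(n), assign_new + 1L)])
        assign_new[worst] <- j
      }
    }
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(P)) {
      mu[j, ] <- colMeans(X[assign_new == (j - 1L), , drop = FALSE])
    }
  }
  d2 <- sq_dist(X, mu)
  list(centroids = mu, assignment = assign_old,
       distortion = sum(d2[cbind(seq_len(n), assign_old + 1L)]), n_iter = it)
}

sq_dist <- function(X, mu) {
  outer(rowSums(X^2), rep(1, nrow(mu))) -
    2 * X %*% t(mu) +
    outer(rep(1, nrow(X)), rowSums(mu^2))
}

profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    X <- profiles
  } else if (is.data.frame(profiles)) {
    stopifnot("subject_id" %in% names(profiles))
    num <- profiles[setdiff(names(profiles), "subject_id")]
    X <- as.matrix(num)
    rownames(X) <- profiles$subject_id
  } else {
    stopf("profiles must be a data.frame or matrix")
  }
  if (ncol(X) != 5) stopf("personality profiles must have 5 components, got %d", ncol(X))
  assert_finite(X, "personality profiles")
  X
}

#' Within-cluster distortion as a function of cluster count
#'
#' Runs [fit_kmeans()] for each candidate `P` with a shared seed policy and
#' reports the distortion (within-cluster sum of squares) — the elbow curve
#' used to pick the cluster count.
#'
#' @param profiles as in [fit_kmeans()].
#' @param P_values sorted candidate cluster counts.
#' @param seed,n_restarts,scale passed to [fit_kmeans()].
#' @return data.frame with columns `P` and `distortion`.
#' @export
elbow_curve <- function(profiles, P_values = 1:10, seed = 1L, n_restarts = 10L,
                        scale = FALSE) {
  stopifnot(!is.unsorted(P_values))
  res <- lapply(P_values, function(P) {
    fit <- fit_kmeans(profiles, P, seed = seed, n_restarts = n_restarts, scale = scale)
    data.frame(P = P, distortion = fit$distortion)
  })
  do.call(rbind, res)
}

#' Route a personality profile to its nearest cluster
#'
#' Nearest-centroid assignment for subjects not seen at fit time (the routing
#' step of the personality-first scheme under leave-one-subject-out). Ties go
#' to the lowest cluster index.
#'
#' @param fit a `personality_kmeans`.
#' @param profile numeric 5-vector (or 1-row data.frame/matrix slice).
#' @return 0-based cluster index.
#' @export
assign_cluster <- function(fit, profile) {
  stopifnot(inherits(fit, "personality_kmeans"))
  if (is.data.frame(profile)) {
    profile <- as.numeric(profile[setdiff(names(profile), "subject_id")])
  }
  profile <- as.numeric(profile)
  if (length(profile) != 5) stopf("profile must have 5 components, got %d", length(profile))
  assert_finite(profile, "profile")
  if (isTRUE(fit$scale)) {
    profile <- (profile - fit$center_vec) / fit$scale_vec
  }
  d2 <- colSums((t(fit$centroids) - profile)^2)
  as.integer(which.min(d2) - 1L)
}

#' @export
print.personality_kmeans <- function(x, ...) {
  cat(sprintf("<personality_kmeans> P = %d, %d subjects, distortion %.4f (%d iter)\n",
              x$P, length(x$assignment), x$distortion, x$n_iter))
  invisible(x)
}
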