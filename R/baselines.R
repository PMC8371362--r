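#' Linear SVM baseline (Pegasos)
#'
#' Linear soft-margin SVM trained with the Pegasos stochastic subgradient
#' method on z-scored features; the conventional shallow baseline the
#' BiLSTM model is compared against. Inputs are flattened feature vectors
#' (one row per sample).
#'
#' @param X numeric matrix, samples x features.
#' @param classes integer 0/1 labels.
#' @param lambda regularization strength.
#' @param n_iter subgradient steps (default `max(2000, 50 * n)`).
#' @param seed RNG seed for the sampling order.
#' @return object of class `linear_svm`.
#' @export
fit_linear_svm <- function(X, classes, lambda = 1e-2, n_iter = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- ifelse(as.integer(classes) == 1L, 1, -1)
  if (length(unique(y)) < 2) stopf("training set contains a single class")
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  Xs <- cbind(Xs, 1)              # bias feature
  p <- ncol(Xs)
  if (is.null(n_iter)) n_iter <- max(2000L, 50L * n)
  w <- numeric(p)
  wavg <- numeric(p)
  local_seed(seed, {
    idx <- sample.int(n, n_iter, replace = TRUE)
    for (t in seq_len(n_iter)) {
      i <- idx[t]
      eta <- 1 / (lambda * t)
      margin <- y[i] * sum(w * Xs[i, ])
      w <- (1 - eta * lambda) * w
      if (margin < 1) w <- w + eta * y[i] * Xs[i, ]
      wavg <- wavg + w
    }
  })
  structure(list(w = wavg / n_iter, center = mu, scale = sg, lambda = lambda),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, X, ...) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  score <- drop(cbind(Xs, 1) %*% object$w)
  as.integer(score > 0)
}

#' Gradient-boosted stump baseline
#'
#' Gradient boosting with depth-1 regression trees (stumps) on the logistic
#' loss — the XGBoost-style comparator. Candidate splits are per-feature
#' quantile thresholds; each round fits a stump to the current negative
#' gradient and adds it with shrinkage.
#'
#' @param X numeric matrix, samples x features.
#' @param classes integer 0/1 labels.
#' @param n_rounds boosting rounds.
#' @param shrinkage learning rate per round.
#' @param n_thresholds candidate thresholds per feature.
#' @param seed unused (the fit is deterministic); kept for interface parity.
#' @return object of class `stump_boost`.
#' @export
fit_stump_boost <- function(X, classes, n_rounds = 60, shrinkage = 0.3,
                            n_thresholds = 8, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.numeric(classes)
  if (length(unique(y)) < 2) stopf("training set contains a single class")
  p <- ncol(X)
  # candidate thresholds: interior quantiles per feature
  qs <- seq(0, 1, length.out = n_thresholds + 2)[-c(1, n_thresholds + 2)]
  thr <- apply(X, 2, stats::quantile, probs = qs, names = FALSE)
  thr <- matrix(thr, nrow = length(qs))
  # mask matrix: n x (p * n_thresholds), 1 where x_j <= threshold
  keep <- logical(p * length(qs))
  Mk <- matrix(0, n, p * length(qs))
  feat_of <- integer(p * length(qs))
  thr_of <- numeric(p * length(qs))
  col <- 0L
  for (j in seq_len(p)) {
    for (q in seq_along(qs)) {
      col <- col + 1L
      Mk[, col] <- as.numeric(X[, j] <= thr[q, j])
      feat_of[col] <- j
      thr_of[col] <- thr[q, j]
      nl <- sum(Mk[, col])
      keep[col] <- nl > 0 && nl < n
    }
  }
  Mk <- Mk[, keep, drop = FALSE]
  feat_of <- feat_of[keep]
  thr_of <- thr_of[keep]
  nl <- colSums(Mk)
  nr <- n - nl
  Fv <- rep(0, n)
  stumps <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    pr <- 1 / (1 + exp(-Fv))
    g <- y - pr                            # negative gradient of logistic loss
    sl <- drop(crossprod(Mk, g))
    sr <- sum(g) - sl
    gain <- sl^2 / nl + sr^2 / nr          # variance reduction up to constants
    b <- which.max(gain)
    left <- Mk[, b] > 0
    vl <- sl[b] / nl[b]
    vr <- sr[b] / nr[b]
    stumps[[r]] <- c(feature = feat_of[b], threshold = thr_of[b],
                     left = shrinkage * vl, right = shrinkage * vr)
    Fv <- Fv + ifelse(left, shrinkage * vl, shrinkage * vr)
  }
  structure(list(stumps = stumps, n_rounds = n_rounds), class = "stump_boost")
}

#' @export
predict.stump_boost <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  Fv <- rep(0, nrow(X))
  for (s in object$stumps) {
    Fv <- Fv + ifelse(X[, s[["feature"]]] <= s[["threshold"]],
                      s[["left"]], s[["right"]])
  }
  pr <- 1 / (1 + exp(-Fv))
  if (type == "prob") pr else as.integer(pr > 0.5)
}
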