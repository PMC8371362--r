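#' Featurize a dataset once for repeated evaluation
#'
#' Runs the preprocessing pipeline over every recording and stacks the
#' resulting samples into one tensor, keeping per-sample provenance. The
#' evaluation protocols slice this object instead of re-filtering signals.
#'
#' @param dataset a `synthetic_eeg_dataset` (or compatible list).
#' @inheritParams featurize_dataset
#' @return object of class `pfeeg_features`: `X4` (F x M x N x B), `meta`
#'   (data.frame subject_id, trial_id per sample), `n_bands`, `n_segments`.
#' @export
prepare_features <- function(dataset, bands = band_set(), window_s = 1,
                             step_s = window_s, n_segments = 9,
                             hp_hz = 1, lp_hz = 16) {
  samples <- featurize_dataset(dataset, bands, window_s, step_s, n_segments,
                               hp_hz, lp_hz)
  if (length(samples) == 0) stopf("no samples could be built from the dataset")
  X4 <- stack_samples(samples)
  meta <- data.frame(
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    trial_id = vapply(samples, function(s) s$trial_id, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(X4 = X4, meta = meta, n_bands = dim(X4)[1],
                 n_channels = dim(X4)[2], n_segments = dim(X4)[3]),
            class = "pfeeg_features")
}

# rating lookup: named vector "subject/trial" -> rating for one axis
rating_map <- function(ratings, axis) {
  stats::setNames(ratings[[axis]], paste(ratings$subject_id, ratings$trial_id))
}

# per-sample ratings for a feature set
sample_ratings <- function(features, ratings, axis) {
  rm <- rating_map(ratings, axis)
  unname(rm[paste(features$meta$subject_id, features$meta$trial_id)])
}

default_model_config <- function(features, use_channel_attention, seed,
                                 model_cfg = NULL) {
  if (is.null(model_cfg)) {
    model_cfg <- model_config(
      n_bands = features$n_bands, n_channels = features$n_channels,
      n_segments = features$n_segments,
      use_channel_attention = use_channel_attention, seed = seed
    )
  } else {
    model_cfg$use_channel_attention <- use_channel_attention
    model_cfg$seed <- as.integer(seed)
  }
  model_cfg
}

# unified fit/predict over the four method families
fit_method <- function(method, X4, classes, model_cfg, train_cfg, seed) {
  switch(method,
    our = ,
    our_c = {
      cfg <- model_cfg
      cfg$use_channel_attention <- (method == "our")
      cfg$seed <- as.integer(seed)
      tc <- train_cfg
      tc$seed <- as.integer(seed)
      train_model(X4, classes, cfg, tc)
    },
    svm = fit_linear_svm(flatten_features(X4), classes, seed = seed),
    xgb = fit_stump_boost(flatten_features(X4), classes, seed = seed),
    stopf("unknown method '%s'", method)
  )
}

predict_method <- function(model, X4) {
  if (inherits(model, "ca_bilstm")) {
    predict(model, X4)$classes
  } else {
    predict(model, flatten_features(X4))
  }
}

# F x M x N x B -> B x (F*M*N): the flattened DE tensors the shallow
# baselines consume
flatten_features <- function(X4) {
  d <- dim(X4)
  t(matrix(X4, prod(d[1:3]), d[4]))
}

new_eval_result <- function(protocol, axis, method, pf, per_unit, mean_acc,
                            per_cluster = NULL) {
  structure(list(protocol = protocol, axis = axis, method = method, pf = pf,
                 per_unit = per_unit, mean_accuracy = mean_acc,
                 per_cluster = per_cluster),
            class = "pfeeg_eval")
}

#' @export
print.pfeeg_eval <- function(x, ...) {
  cat(sprintf("<pfeeg_eval> %s / %s / %s / %s: mean accuracy %.3f over %d units\n",
              x$protocol, x$axis, x$method, ifelse(x$pf, "PF", "noPF"),
              x$mean_accuracy, nrow(x$per_unit)))
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' The cross-subject protocol: each subject in turn is the entire test set.
#' With `pf = TRUE` (personality first) the remaining subjects are
#' re-clustered on their Big-Five vectors each round, the held-out subject is
#' routed to the nearest centroid, and the model is trained only on that
#' cluster's subjects; with `pf = FALSE` one model is trained on all
#' remaining subjects. Median-split label thresholds are computed from
#' training-subject ratings only.
#'
#' @param dataset a `synthetic_eeg_dataset` (needs `personalities`, `ratings`).
#' @param features a [prepare_features()] result (computed here if `NULL`).
#' @param axis `"valence"` or `"arousal"`.
#' @param method `"our"` (channel-attention BiLSTM), `"our_c"` (ablation
#'   without the channel-weight layer), `"svm"` or `"xgb"`.
#' @param pf personality-first scheme on/off.
#' @param P number of personality clusters in PF mode.
#' @param model_cfg optional [model_config()] (widths); attention flag and
#'   seed are set per method/round.
#' @param train_cfg a [train_config()].
#' @param seed master seed; per-round seeds are derived from it.
#' @return a `pfeeg_eval` with `per_unit` = per-subject accuracies (and
#'   routed cluster in PF mode), `mean_accuracy` = unweighted mean over
#'   subjects, and `per_cluster` breakdown in PF mode.
#' @export
evaluate_loso <- function(dataset, features = NULL,
                          axis = c("valence", "arousal"),
                          method = c("our", "our_c", "svm", "xgb"),
                          pf = TRUE, P = 5, model_cfg = NULL,
                          train_cfg = train_config(), seed = 1L) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (is.null(features)) features <- prepare_features(dataset)
  subjects <- dataset$personalities$subject_id
  if (pf && P > length(subjects) - 1) {
    stopf("P = %d exceeds the %d training subjects of a LOSO round",
          P, length(subjects) - 1)
  }
  srat <- sample_ratings(features, dataset$ratings, axis)
  rows <- vector("list", length(subjects))
  preds <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    te <- features$meta$subject_id == s
    tr <- !te
    thr <- binarize_labels(srat[tr])$threshold
    labels <- as.integer(srat > thr)
    rseed <- derive_seed(seed, "loso", s)
    cluster <- NA_integer_
    tr_fit <- tr
    if (pf) {
      pers_tr <- dataset$personalities[subjects != s, , drop = FALSE]
      kfit <- fit_kmeans(pers_tr, P, seed = derive_seed(seed, "km", s))
      prof <- dataset$personalities[subjects == s, , drop = FALSE]
      cluster <- assign_cluster(kfit, prof)
      members <- names(kfit$assignment)[kfit$assignment == cluster]
      tr_cl <- tr & features$meta$subject_id %in% members
      if (!any(tr_cl) || length(unique(labels[tr_cl])) < 2) {
        warnf("cluster %d has no usable training data for subject %s; falling back to the global model",
              cluster, s)
      } else {
        tr_fit <- tr_cl
      }
    }
    model <- fit_method(method, features$X4[, , , tr_fit, drop = FALSE],
                        labels[tr_fit], model_cfg, train_cfg, rseed)
    pred <- predict_method(model, features$X4[, , , te, drop = FALSE])
    preds[[s]] <- pred
    rows[[si]] <- data.frame(
      subject_id = s, n = sum(te), accuracy = mean(pred == labels[te]),
      cluster = cluster, stringsAsFactors = FALSE
    )
  }
  per_subject <- do.call(rbind, rows)
  per_cluster <- NULL
  if (pf) {
    per_cluster <- stats::aggregate(accuracy ~ cluster, per_subject, mean)
  }
  out <- new_eval_result("loso", axis, method, pf, per_subject,
                         mean(per_subject$accuracy), per_cluster)
  out$predictions <- preds
  out
}

#' k-fold cross-validation evaluation
#'
#' The non-cross-subject protocol: samples are pooled (within a personality
#' cluster when `pf = TRUE`, globally otherwise), shuffled with `seed` and
#' split into `k` folds of near-equal size. The median-split threshold is
#' recomputed on each training fold. In PF mode the reported mean is the
#' unweighted average of the per-cluster fold means.
#'
#' @inheritParams evaluate_loso
#' @param k number of folds.
#' @return a `pfeeg_eval`; `per_unit` holds per-fold accuracies (with cluster
#'   in PF mode).
#' @export
evaluate_kfold <- function(dataset, features = NULL,
                           axis = c("valence", "arousal"),
                           method = c("our", "our_c", "svm", "xgb"),
                           pf = FALSE, k = 10, P = 5, model_cfg = NULL,
                           train_cfg = train_config(), seed = 1L) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (is.null(features)) features <- prepare_features(dataset)
  srat <- sample_ratings(features, dataset$ratings, axis)

  run_pool <- function(idx_pool, cluster = NA_integer_) {
    n <- length(idx_pool)
    if (k > n) stopf("k = %d exceeds the %d pooled samples", k, n)
    shuffled <- local_seed(derive_seed(seed, "kfold", cluster), sample(idx_pool))
    fold_of <- sort(rep(seq_len(k), length.out = n))
    rows <- vector("list", k)
    for (f in seq_len(k)) {
      te <- shuffled[fold_of == f]
      tr <- setdiff(shuffled, te)
      thr <- binarize_labels(srat[tr])$threshold
      labels <- as.integer(srat > thr)
      model <- fit_method(method, features$X4[, , , tr, drop = FALSE],
                          labels[tr], model_cfg, train_cfg,
                          derive_seed(seed, "fold", cluster, f))
      pred <- predict_method(model, features$X4[, , , te, drop = FALSE])
      rows[[f]] <- data.frame(fold = f, cluster = cluster, n = length(te),
                              accuracy = mean(pred == labels[te]))
    }
    do.call(rbind, rows)
  }

  if (!pf) {
    per_fold <- run_pool(seq_len(nrow(features$meta)))
    return(new_eval_result("kfold", axis, method, FALSE, per_fold,
                           mean(per_fold$accuracy)))
  }
  kfit <- fit_kmeans(dataset$personalities, P, seed = derive_seed(seed, "km"))
  per_fold <- do.call(rbind, lapply(sort(unique(kfit$assignment)), function(cl) {
    members <- names(kfit$assignment)[kfit$assignment == cl]
    run_pool(which(features$meta$subject_id %in% members), cl)
  }))
  cluster_means <- stats::aggregate(accuracy ~ cluster, per_fold, mean)
  new_eval_result("kfold", axis, method, TRUE, per_fold,
                  mean(cluster_means$accuracy), cluster_means)
}

#' Run the full protocol-by-method-by-variant grid
#'
#' Executes every combination of axis, method and PF variant under one
#' protocol with identical split seeds, so all methods see the same folds or
#' LOSO rounds. A failing cell is recorded as `NA` with a message instead of
#' aborting the grid.
#'
#' @inheritParams evaluate_loso
#' @param protocol `"loso"` or `"kfold"`.
#' @param axes character vector of rating axes.
#' @param methods character vector of methods.
#' @param pf_variants logical vector of PF settings to run.
#' @param ... passed to [evaluate_loso()] / [evaluate_kfold()].
#' @return data.frame with one row per cell: axis, method, pf, accuracy, and
#'   an `error` column (NA on success).
#' @export
run_experiment_grid <- function(dataset, features = NULL,
                                protocol = c("loso", "kfold"),
                                axes = c("valence", "arousal"),
                                methods = c("svm", "xgb", "our_c", "our"),
                                pf_variants = c(FALSE, TRUE), ...) {
  protocol <- match.arg(protocol)
  if (is.null(features)) features <- prepare_features(dataset)
  grid <- expand.grid(axis = axes, method = methods, pf = pf_variants,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    out <- tryCatch({
      ev <- if (protocol == "loso") {
        evaluate_loso(dataset, features, axis = cell$axis,
                      method = cell$method, pf = cell$pf, ...)
      } else {
        evaluate_kfold(dataset, features, axis = cell$axis,
                       method = cell$method, pf = cell$pf, ...)
      }
      data.frame(cell, accuracy = ev$mean_accuracy, error = NA_character_)
    }, error = function(e) {
      data.frame(cell, accuracy = NA_real_, error = conditionMessage(e))
    })
    out
  })
  out <- do.call(rbind, res)
  out$protocol <- protocol
  out
}

#' Pivot a grid result into the standard comparison-table layout
#'
#' Rows are rating axes; columns are SVM / XGB / Our-C / Our, first without
#' then with personality first (8 accuracy columns, in percent).
#'
#' @param grid data.frame from [run_experiment_grid()].
#' @return data.frame with columns axis, then `<method>_noPF` and
#'   `<method>_PF` accuracies in percent.
#' @export
results_table <- function(grid) {
  methods <- c("svm", "xgb", "our_c", "our")
  axes <- unique(grid$axis)
  out <- data.frame(axis = axes, stringsAsFactors = FALSE)
  for (pf in c(FALSE, TRUE)) {
    for (m in methods) {
      col <- paste0(m, ifelse(pf, "_PF", "_noPF"))
      out[[col]] <- vapply(axes, function(a) {
        v <- grid$accuracy[grid$axis == a & grid$method == m & grid$pf == pf]
        if (length(v) == 0) NA_real_ else round(100 * v[1], 1)
      }, numeric(1))
    }
  }
  out
}

#' Train one emotion model per personality cluster
#'
#' Fits k-means on all subjects' personalities and trains one model per
#' cluster on that cluster's samples — the deployable personality-first
#' artifact, and the input to [attention_report()].
#'
#' @inheritParams evaluate_loso
#' @return list with `kmeans` (the cluster fit), `models` (one per cluster),
#'   `threshold` (median-split threshold used), `axis`.
#' @export
fit_cluster_models <- function(dataset, features = NULL,
                               axis = c("valence", "arousal"),
                               method = c("our", "our_c"), P = 5,
                               model_cfg = NULL, train_cfg = train_config(),
                               seed = 1L) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (is.null(features)) features <- prepare_features(dataset)
  srat <- sample_ratings(features, dataset$ratings, axis)
  thr <- binarize_labels(srat)$threshold
  labels <- as.integer(srat > thr)
  kfit <- fit_kmeans(dataset$personalities, P, seed = derive_seed(seed, "km"))
  models <- lapply(sort(unique(kfit$assignment)), function(cl) {
    members <- names(kfit$assignment)[kfit$assignment == cl]
    idx <- features$meta$subject_id %in% members
    fit_method(method, features$X4[, , , idx, drop = FALSE], labels[idx],
               model_cfg, train_cfg, derive_seed(seed, "cluster", cl))
  })
  names(models) <- as.character(sort(unique(kfit$assignment)))
  list(kmeans = kfit, models = models, threshold = thr, axis = axis)
}

#' Per-cluster mean attention matrices and channel importance
#'
#' Averages each cluster model's per-segment attention matrices over that
#' cluster's samples. The mean matrix is column-stochastic, so column sums
#' are uninformative (identically 1); channel importance is therefore the
#' row mass of the mean matrix — how strongly input channel j is mixed into
#' the weighted representation.
#'
#' @param cluster_fit result of [fit_cluster_models()].
#' @param dataset,features as in [evaluate_loso()]; probe samples are the
#'   cluster's own samples.
#' @return list with `attention` (list of M x M column-stochastic matrices
#'   per cluster) and `importance` (data.frame cluster, channel [0-based],
#'   importance = row mean of the mean attention matrix).
#' @export
attention_report <- function(cluster_fit, dataset, features = NULL) {
  if (is.null(features)) features <- prepare_features(dataset)
  kfit <- cluster_fit$kmeans
  att <- list()
  imp <- list()
  for (cl in names(cluster_fit$models)) {
    model <- cluster_fit$models[[cl]]
    if (!model$config$use_channel_attention) {
      stopf("cluster %s model was trained without the channel-attention layer", cl)
    }
    members <- names(kfit$assignment)[kfit$assignment == as.integer(cl)]
    idx <- features$meta$subject_id %in% members
    pr <- predict(model, features$X4[, , , idx, drop = FALSE],
                  want_attention = TRUE)
    W <- apply(pr$attention, c(1, 2), mean)
    att[[cl]] <- W
    imp[[cl]] <- data.frame(cluster = as.integer(cl),
                            channel = seq_len(nrow(W)) - 1L,
                            importance = rowMeans(W))
  }
  list(attention = att, importance = do.call(rbind, imp))
}
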