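#' Mean cross-entropy loss
#'
#' Mean over the batch of `-log P(true class | X)` with the inner sum taken
#' over classes. Probabilities at the true class below `1e-12` are clamped
#' with a warning.
#'
#' @param probs T x B matrix of class probabilities (columns sum to 1).
#' @param classes integer vector of 0-based true classes, length B.
#' @return scalar loss in nats.
#' @export
cross_entropy_loss <- function(probs, classes) {
  probs <- as.matrix(probs)
  B <- ncol(probs)
  stopifnot(length(classes) == B)
  sums <- colSums(probs)
  if (any(abs(sums - 1) > 1e-6)) stopf("probability columns must sum to 1")
  p <- probs[cbind(as.integer(classes) + 1L, seq_len(B))]
  if (any(p < 1e-12)) {
    warnf("probability at true class below 1e-12; clamped")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Training configuration
#'
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient (decoupled, applied to weights
#'   only, not biases).
#' @param patience early-stopping patience: stop when the epoch-mean training
#'   loss has not improved by `min_delta` for this many epochs (`Inf`
#'   disables).
#' @param min_delta minimum loss improvement that resets patience.
#' @param seed seed for initialization and shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200, batch_size = 32, lr = 1e-3,
                         weight_decay = 0, patience = 25, min_delta = 1e-4,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, patience = patience,
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(as.array(p)))),
       v = lapply(params, function(p) array(0, dim(as.array(p)))),
       t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("(_W|_G)", nm)) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    # as.vector: keep plain-vector biases plain (a 1-d array operand would
    # stamp its dim attribute onto the parameter)
    params[[nm]] <- params[[nm]] - as.vector(lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

# Stack a list of feature samples (or a plain list of F x M x N arrays) into
# an (F, M, N, B) batch array.
stack_samples <- function(samples) {
  xs <- lapply(samples, function(s) if (inherits(s, "feature_sample")) s$X else s)
  d <- dim(xs[[1]])
  X4 <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) X4[, , , i] <- xs[[i]]
  X4
}

#' Train a channel-attention BiLSTM classifier
#'
#' Minibatch Adam on the mean cross-entropy loss. Deterministic given
#' `config$seed` (weight initialization uses `model_config$seed`; shuffling
#' uses the training seed). Optionally z-scores each input feature using
#' training-set statistics (stored on the model and re-applied at prediction
#' time).
#'
#' @param X4 feature batch, array F x M x N x B (see [stack_samples()]), or a
#'   list of `feature_sample`/arrays.
#' @param classes integer vector of 0-based labels (both classes must occur).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param normalize `"zscore"` (default) or `"none"`.
#' @return object of class `ca_bilstm`: `params`, `config`, `loss_trace`
#'   (epoch-mean training loss), `normalize`, feature means/sds.
#' @export
train_model <- function(X4, classes, model_cfg, train_cfg = train_config(),
                        normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  if (is.list(X4)) X4 <- stack_samples(X4)
  classes <- as.integer(classes)
  B <- dim(X4)[4]
  stopifnot(length(classes) == B)
  if (length(unique(classes)) < 2) {
    stopf("training set contains a single class (%d); cannot fit a classifier",
          classes[1])
  }
  mu <- sg <- NULL
  if (normalize == "zscore") {
    Xm <- matrix(X4, prod(dim(X4)[1:3]), B)
    mu <- rowMeans(Xm)
    sg <- apply(Xm, 1, stats::sd)
    sg[sg < 1e-8] <- 1
    X4 <- array((Xm - mu) / sg, dim(X4))
  }
  params <- init_params(model_cfg)
  state <- adam_init(params)
  trace <- numeric(0)
  best <- Inf
  wait <- 0
  local_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(B)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, B, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1, B)]
        lg <- loss_and_grads(params, model_cfg,
                             X4[, , , idx, drop = FALSE], classes[idx])
        upd <- adam_step(params, lg$grads, state, train_cfg$lr,
                         train_cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
        nb <- nb + length(idx)
      }
      trace[ep] <- ep_loss / nb
      if (trace[ep] < best - train_cfg$min_delta) {
        best <- trace[ep]
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= train_cfg$patience) break
      }
    }
  })
  structure(list(params = params, config = model_cfg, loss_trace = trace,
                 normalize = normalize, feat_mean = mu, feat_sd = sg),
            class = "ca_bilstm")
}

apply_normalization <- function(model, X4) {
  if (model$normalize == "zscore") {
    d <- dim(X4)
    Xm <- matrix(X4, prod(d[1:3]), d[4])
    X4 <- array((Xm - model$feat_mean) / model$feat_sd, d)
  }
  X4
}

#' Predict with a fitted model
#'
#' @param object a `ca_bilstm` from [train_model()].
#' @param X4 array F x M x N (one sample) or F x M x N x B, or a list of
#'   samples.
#' @param want_attention also return per-segment attention matrices.
#' @param ... unused.
#' @return list with `probs` (T x B), `classes` (0-based argmax) and
#'   optionally `attention`.
#' @export
predict.ca_bilstm <- function(object, X4, want_attention = FALSE, ...) {
  if (is.list(X4) && !is.array(X4)) X4 <- stack_samples(X4)
  if (length(dim(X4)) == 3) dim(X4) <- c(dim(X4), 1L)
  X4 <- apply_normalization(object, X4)
  out <- predict_proba(X4, object$params, object$config,
                       want_attention = want_attention)
  out$classes <- max.col(t(out$probs), ties.method = "first") - 1L
  out
}

#' @export
print.ca_bilstm <- function(x, ...) {
  cat(sprintf("<ca_bilstm> F=%d M=%d N=%d, attention=%s, %d params, %d epochs (final loss %.4f)\n",
              x$config$F, x$config$M, x$config$N,
              ifelse(x$config$use_channel_attention, "on", "off"),
              param_count(x$config), length(x$loss_trace),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON container holding the configuration and every parameter
#' array with its shape.
#'
#' @param model a `ca_bilstm`.
#' @param path file path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `ca_bilstm`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    normalize = model$normalize,
    feat_mean = model$feat_mean,
    feat_sd = model$feat_sd,
    loss_trace = model$loss_trace,
    params = lapply(model$params, function(p) {
      list(dim = dim(as.array(p)), data = as.vector(p))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg <- model_config(cfg$F, cfg$M, cfg$N, cfg$d_a, cfg$d_h, cfg$u, cfg$K,
                      cfg$v, cfg$T, cfg$use_channel_attention, cfg$seed)
  params <- lapply(obj$params, function(p) array(p$data, unlist(p$dim)))
  # vectors (biases) round-trip as 1-d arrays; restore plain vectors
  params <- lapply(params, function(p) if (length(dim(p)) == 1) as.vector(p) else p)
  class(params) <- "ca_bilstm_params"
  structure(list(params = params, config = cfg,
                 loss_trace = obj$loss_trace, normalize = obj$normalize,
                 feat_mean = obj$feat_mean, feat_sd = obj$feat_sd),
            class = "ca_bilstm")
}
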