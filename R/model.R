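#' Channel-attention BiLSTM model configuration
#'
#' Architecture hyper-parameters for the emotion classifier: a per-channel
#' linear embedding (one `d_a x n_bands` matrix per channel), an optional
#' channel-attention layer producing a column-stochastic M x M weight matrix,
#' a bidirectional LSTM over the channel sequence with a ReLU compression to
#' length `K`, a bidirectional LSTM over the segment sequence, and a linear
#' softmax classifier on the final segment encoding.
#'
#' @param n_bands number of band features F per channel.
#' @param n_channels number of EEG channels M.
#' @param n_segments segments per sample N.
#' @param d_a embedding width (rows of each channel embedding).
#' @param d_h attention hidden width.
#' @param u spatial BiLSTM hidden size per direction.
#' @param K compressed channel-sequence length.
#' @param v temporal BiLSTM hidden size per direction.
#' @param n_classes number of output classes T (default 2).
#' @param use_channel_attention include the channel-weight layer; `FALSE` is
#'   the "without channel weighting" ablation, which *skips* the layer (it
#'   does not substitute an identity weight matrix).
#' @param seed seed for weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(n_bands = 5, n_channels = 8, n_segments = 9,
                         d_a = 32, d_h = 32, u = 32, K = 6, v = 64,
                         n_classes = 2, use_channel_attention = TRUE,
                         seed = 1L) {
  stopifnot(n_bands >= 1, n_channels >= 1, n_segments >= 1, d_a >= 1,
            d_h >= 1, u >= 1, K >= 1, v >= 1, n_classes >= 2)
  structure(
    list(F = as.integer(n_bands), M = as.integer(n_channels),
         N = as.integer(n_segments), d_a = as.integer(d_a),
         d_h = as.integer(d_h), u = as.integer(u), K = as.integer(K),
         v = as.integer(v), T = as.integer(n_classes),
         use_channel_attention = isTRUE(use_channel_attention),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# uniform fan-in initialization
uinit <- function(dims, fan_in) {
  a <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -a, a), dims)
}

lstm_init <- function(hidden, input) {
  b <- rep(0, 4 * hidden)
  b[hidden + seq_len(hidden)] <- 1      # forget-gate bias 1
  list(Wx = uinit(c(4 * hidden, input), input),
       Wh = uinit(c(4 * hidden, hidden), hidden),
       b = b)
}

#' Initialize model parameters
#'
#' Uniform fan-in scaled weights, LSTM forget-gate biases set to 1,
#' deterministic given `config$seed`. Attention parameters are only created
#' when the channel-attention layer is enabled.
#'
#' @param config a [model_config()].
#' @return named list of parameter arrays (class `ca_bilstm_params`).
#' @export
init_params <- function(config) {
  local_seed(config$seed, {
    p <- list(
      emb_W = uinit(c(config$d_a, config$F, config$M), config$F),
      emb_b = array(0, c(config$d_a, config$M))
    )
    if (config$use_channel_attention) {
      p$att_H <- uinit(c(config$d_h, config$d_a), config$d_a)
      p$att_B <- array(0, c(config$d_h, config$M))
      p$att_Q <- uinit(c(config$M, config$d_h), config$d_h)
    }
    sp_f <- lstm_init(config$u, config$d_a)
    sp_b <- lstm_init(config$u, config$d_a)
    tm_in <- 2 * config$u * config$K
    tm_f <- lstm_init(config$v, tm_in)
    tm_b <- lstm_init(config$v, tm_in)
    p <- c(p, list(
      sp_f_Wx = sp_f$Wx, sp_f_Wh = sp_f$Wh, sp_f_b = sp_f$b,
      sp_b_Wx = sp_b$Wx, sp_b_Wh = sp_b$Wh, sp_b_b = sp_b$b,
      comp_G = uinit(c(config$M, config$K), config$M),
      comp_b = rep(0, 2 * config$u),
      tm_f_Wx = tm_f$Wx, tm_f_Wh = tm_f$Wh, tm_f_b = tm_f$b,
      tm_b_Wx = tm_b$Wx, tm_b_Wh = tm_b$Wh, tm_b_b = tm_b$b,
      cls_W = uinit(c(config$T, 2 * config$v), 2 * config$v),
      cls_b = rep(0, config$T)
    ))
    class(p) <- "ca_bilstm_params"
    p
  })
}

#' Closed-form parameter count for a model configuration
#'
#' @param config a [model_config()].
#' @return integer number of scalar parameters.
#' @export
param_count <- function(config) {
  with(config, {
    n <- M * (d_a * F + d_a)                               # per-channel embeddings
    if (use_channel_attention) n <- n + d_h * d_a + d_h * M + M * d_h
    n <- n + 2 * (4 * u * (d_a + u) + 4 * u)               # spatial BiLSTM
    n <- n + M * K + 2 * u                                 # compression
    tm_in <- 2 * u * K
    n <- n + 2 * (4 * v * (tm_in + v) + 4 * v)             # temporal BiLSTM
    n + T * 2 * v + T                                      # classifier
  })
}

sigm <- function(x) 1 / (1 + exp(-x))

# TRUE when the compiled kernels should be used (tests flip the option to
# cross-check the two routes against each other).
use_native <- function() {
  isTRUE(getOption("pfeeg.use_native", TRUE))
}

# One LSTM direction over an (input_dim, T, B) array. Returns hidden states
# (hidden, T, B) and a cache for backprop. Dispatches to the compiled kernel
# unless options(pfeeg.use_native = FALSE).
lstm_dir_forward <- function(Wx, Wh, b, X3, reverse = FALSE, want_cache = TRUE) {
  if (use_native()) {
    res <- .lstm_fwd_cpp(Wx, Wh, b, X3, reverse, want_cache)
    return(list(H = res$H, native = res$cache, reverse = reverse))
  }
  lstm_dir_forward_r(Wx, Wh, b, X3, reverse)
}

lstm_dir_backward <- function(Wx, Wh, b, fwd, dH) {
  if (!is.null(fwd$native)) {
    out <- .lstm_bwd_cpp(Wx, Wh, fwd$native, dH, fwd$reverse)
    out$db <- as.vector(out$db)
    return(out)
  }
  lstm_dir_backward_r(Wx, Wh, b, fwd, dH)
}

# -- pure-R reference implementations ---------------------------------------
# The input-side affine map is hoisted out of the time loop as a single GEMM.
lstm_dir_forward_r <- function(Wx, Wh, b, X3, reverse = FALSE) {
  dims <- dim(X3)
  Tlen <- dims[2]
  B <- dims[3]
  hdim <- ncol(Wh)
  X2 <- X3
  dim(X2) <- c(dims[1], Tlen * B)
  GX <- Wx %*% X2 + b
  H <- array(0, c(hdim, Tlen, B))
  h <- matrix(0, hdim, B)
  cc <- matrix(0, hdim, B)
  ord <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  cache <- vector("list", Tlen)
  iu <- seq_len(hdim)
  bofs <- (seq_len(B) - 1L) * Tlen
  for (step in seq_len(Tlen)) {
    t <- ord[step]
    G <- GX[, t + bofs, drop = FALSE] + Wh %*% h
    gi <- sigm(G[iu, , drop = FALSE])
    gf <- sigm(G[hdim + iu, , drop = FALSE])
    gg <- tanh(G[2 * hdim + iu, , drop = FALSE])
    go <- sigm(G[3 * hdim + iu, , drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    cache[[step]] <- list(t = t, h_prev = h, c_prev = cc,
                          i = gi, f = gf, g = gg, o = go, tc = tc)
    h <- go * tc
    cc <- c_new
    H[, t, ] <- h
  }
  list(H = H, cache = cache, X2 = X2)
}

# BPTT for one direction. dH: (hidden, T, B) upstream gradient on outputs.
# Per-step gate gradients are collected and the input-side products are done
# as single GEMMs at the end.
lstm_dir_backward_r <- function(Wx, Wh, b, fwd, dH) {
  hdim <- ncol(Wh)
  dims <- dim(dH)
  B <- dims[3]
  Tlen <- dims[2]
  cache <- fwd$cache
  dWh <- array(0, dim(Wh))
  dGall <- matrix(0, 4 * hdim, Tlen * B)
  dh_next <- matrix(0, hdim, B)
  dc_next <- matrix(0, hdim, B)
  bofs <- (seq_len(B) - 1L) * Tlen
  for (step in rev(seq_along(cache))) {
    cs <- cache[[step]]
    dh <- dH[, cs$t, ]
    dim(dh) <- c(hdim, B)
    dh <- dh + dh_next
    do <- dh * cs$tc
    dc <- dc_next + dh * cs$o * (1 - cs$tc^2)
    dG <- rbind((dc * cs$g) * cs$i * (1 - cs$i),
                (dc * cs$c_prev) * cs$f * (1 - cs$f),
                (dc * cs$i) * (1 - cs$g^2),
                do * cs$o * (1 - cs$o))
    dc_next <- dc * cs$f
    dGall[, cs$t + bofs] <- dG
    dWh <- dWh + dG %*% t(cs$h_prev)
    dh_next <- crossprod(Wh, dG)
  }
  dX <- crossprod(Wx, dGall)
  dim(dX) <- c(ncol(Wx), Tlen, B)
  list(dWx = dGall %*% t(fwd$X2), dWh = dWh, db = rowSums(dGall), dX = dX)
}

check_finite_stage <- function(x, stage) {
  if (!all(is.finite(x))) stopf("non-finite activation in stage '%s'", stage)
  invisible(NULL)
}

fused_dims <- function(cfg) {
  list(F = cfg$F, M = cfg$M, N = cfg$N, d_a = cfg$d_a, u = cfg$u,
       K = cfg$K, v = cfg$v, T = cfg$T)
}

# Full batched forward pass. X4: array (F, M, N, B).
# Returns logits/probs plus (optionally) every intermediate needed by backprop
# and the per-slice attention matrices. When the compiled fused kernel is
# available and no cache is needed, it is used; a non-finite result falls
# back to the staged R path, which names the failing stage in its error.
forward_full <- function(params, cfg, X4, want_cache = FALSE,
                         want_attention = FALSE, check = TRUE) {
  dims <- dim(X4)
  if (length(dims) == 3) {
    dim(X4) <- c(dims, 1L)
    dims <- dim(X4)
  }
  if (!want_cache && use_native()) {
    if (!identical(dims[1:3], c(cfg$F, cfg$M, cfg$N))) {
      stopf("input dims (%s) do not match config F=%d M=%d N=%d",
            paste(dims[1:3], collapse = "x"), cfg$F, cfg$M, cfg$N)
    }
    B <- dims[4]
    X3 <- X4
    dim(X3) <- c(cfg$F, cfg$M, cfg$N * B)
    res <- .nn_fused_cpp(params, fused_dims(cfg), X3, integer(B),
                         cfg$use_channel_attention, TRUE, want_attention)
    if (check && !all(is.finite(res$probs))) {
      # reproduce through the staged path to name the failing stage
      return(withr_native_off(forward_full, params, cfg, X4,
                              want_cache = FALSE,
                              want_attention = want_attention, check = TRUE))
    }
    out <- list(probs = res$probs, logits = NULL)
    if (want_attention && cfg$use_channel_attention) {
      out$attention <- array(res$attention, c(cfg$M, cfg$M, cfg$N, B))
    }
    return(out)
  }
  if (!identical(dims[1:3], c(cfg$F, cfg$M, cfg$N))) {
    stopf("input dims (%s) do not match config F=%d M=%d N=%d",
          paste(dims[1:3], collapse = "x"), cfg$F, cfg$M, cfg$N)
  }
  B <- dims[4]
  NB <- cfg$N * B
  M <- cfg$M

  # (1) per-channel embedding
  A <- array(0, c(cfg$d_a, M, NB))
  Xmats <- vector("list", M)
  for (j in seq_len(M)) {
    Xj <- matrix(X4[, j, , ], cfg$F, NB)
    Xmats[[j]] <- Xj
    A[, j, ] <- params$emb_W[, , j] %*% Xj + params$emb_b[, j]
  }
  if (check) check_finite_stage(A, "channel_embed")

  # (2) channel attention
  if (cfg$use_channel_attention) {
    Amat <- matrix(A, cfg$d_a, M * NB)
    Tn <- tanh(params$att_H %*% Amat + as.vector(params$att_B))
    QT <- params$att_Q %*% Tn                    # (M, M*NB): QT[r, (j,s)]
    S <- array(QT, c(M, M, NB))
    Wraw <- aperm(S, c(2, 1, 3))                 # Wraw[j, k, s]
    Wm <- matrix(Wraw, M, M * NB)
    mx <- Wm[1, ]
    if (M > 1) for (r in 2:M) mx <- pmax(mx, Wm[r, ])
    Wexp <- exp(Wm - rep(mx, each = M))
    Wsm <- Wexp / rep(colSums(Wexp), each = M)   # column-stochastic over j
    Wsm <- array(Wsm, c(M, M, NB))
    if (check) check_finite_stage(Wsm, "channel_attention")
    if (use_native()) {
      Ahat <- .att_mix_fwd_cpp(A, Wsm)
    } else {
      # mix A %*% W per slice, flattened: Ahat[(d,k),s] = sum_j A[d,j,s] W[j,k,s]
      ridx_a <- rep(seq_len(cfg$d_a), times = M)
      ridx_w <- rep(seq_len(M), each = cfg$d_a)
      Ahat2 <- matrix(0, cfg$d_a * M, NB)
      for (j in seq_len(M)) {
        Aj <- A[, j, ]
        dim(Aj) <- c(cfg$d_a, NB)
        Wj <- Wsm[j, , ]
        dim(Wj) <- c(M, NB)
        Ahat2 <- Ahat2 + Aj[ridx_a, , drop = FALSE] * Wj[ridx_w, , drop = FALSE]
      }
      Ahat <- array(Ahat2, c(cfg$d_a, M, NB))
    }
  } else {
    Ahat <- A
    Wsm <- NULL
    Amat <- NULL
    Tn <- NULL
  }

  # (3) spatial BiLSTM over the channel sequence + ReLU compression
  spf <- lstm_dir_forward(params$sp_f_Wx, params$sp_f_Wh, params$sp_f_b, Ahat,
                          want_cache = want_cache)
  spb <- lstm_dir_forward(params$sp_b_Wx, params$sp_b_Wh, params$sp_b_b, Ahat,
                          reverse = TRUE, want_cache = want_cache)
  C <- array(0, c(2 * cfg$u, M, NB))
  C[seq_len(cfg$u), , ] <- spf$H
  C[cfg$u + seq_len(cfg$u), , ] <- spb$H
  if (check) check_finite_stage(C, "spatial_encode")
  # compression is a fixed contraction over channel positions: one GEMM
  Cp <- aperm(C, c(1, 3, 2))                   # (2u, NB, M)
  dim(Cp) <- c(2 * cfg$u * NB, M)
  PreP <- Cp %*% params$comp_G                 # (2u*NB, K)
  dim(PreP) <- c(2 * cfg$u, NB, cfg$K)
  Pre <- aperm(PreP, c(1, 3, 2)) + params$comp_b
  Chat <- Pre * (Pre > 0)

  # (4) temporal BiLSTM over the segment sequence
  D <- array(Chat, c(2 * cfg$u * cfg$K, cfg$N, B))
  tmf <- lstm_dir_forward(params$tm_f_Wx, params$tm_f_Wh, params$tm_f_b, D,
                          want_cache = want_cache)
  tmb <- lstm_dir_forward(params$tm_b_Wx, params$tm_b_Wh, params$tm_b_b, D,
                          reverse = TRUE, want_cache = want_cache)
  eN <- rbind(matrix(tmf$H[, cfg$N, ], cfg$v, B),
              matrix(tmb$H[, cfg$N, ], cfg$v, B))
  if (check) check_finite_stage(eN, "temporal_encode")

  # (5) classifier
  Y <- params$cls_W %*% eN + params$cls_b
  if (check) check_finite_stage(Y, "classifier")
  Ymx <- Y[1, ]
  if (cfg$T > 1) for (r in 2:cfg$T) Ymx <- pmax(Ymx, Y[r, ])
  Ee <- exp(Y - rep(Ymx, each = cfg$T))
  probs <- Ee / rep(colSums(Ee), each = cfg$T)

  out <- list(probs = probs, logits = Y)
  if (want_attention && cfg$use_channel_attention) {
    out$attention <- array(Wsm, c(M, M, cfg$N, B))
  }
  if (want_cache) {
    out$cache <- list(X4 = X4, Xmats = Xmats, A = A, Amat = Amat, Tn = Tn,
                      Wsm = Wsm, Ahat = Ahat, spf = spf, spb = spb, C = C,
                      Cp = Cp, Pre = Pre, D = D, tmf = tmf, tmb = tmb, eN = eN,
                      B = B, NB = NB)
  }
  out
}

# Loss and full parameter gradients for a batch.
# X4: (F, M, N, B); classes: integer 0..T-1 per column.
loss_and_grads <- function(params, cfg, X4, classes, want_grads = TRUE) {
  if (want_grads && use_native()) {
    dims <- dim(X4)
    if (length(dims) == 3) dims <- c(dims, 1L)
    B <- dims[4]
    stopifnot(length(classes) == B)
    X3 <- X4
    dim(X3) <- c(cfg$F, cfg$M, cfg$N * B)
    res <- .nn_fused_cpp(params, fused_dims(cfg), X3, as.integer(classes),
                         cfg$use_channel_attention, FALSE, FALSE)
    if (!is.finite(res$loss)) {
      return(withr_native_off(loss_and_grads, params, cfg, X4, classes,
                              want_grads = TRUE))
    }
    if (isTRUE(res$clamped)) warnf("probability at true class below 1e-12; clamped")
    g <- res$grads
    for (nm in c("sp_f_b", "sp_b_b", "comp_b", "tm_f_b", "tm_b_b", "cls_b",
                 if (cfg$use_channel_attention) NULL)) {
      g[[nm]] <- as.vector(g[[nm]])
    }
    return(list(loss = res$loss, probs = res$probs, grads = g[names(params)]))
  }
  fw <- forward_full(params, cfg, X4, want_cache = want_grads)
  B <- ncol(fw$probs)
  stopifnot(length(classes) == B)
  idx <- cbind(as.integer(classes) + 1L, seq_len(B))
  p_true <- fw$probs[idx]
  if (any(p_true < 1e-12)) {
    warnf("probability at true class below 1e-12; clamped")
    p_true <- pmax(p_true, 1e-12)
  }
  loss <- -mean(log(p_true))
  if (!want_grads) return(list(loss = loss, probs = fw$probs))

  cc <- fw$cache
  M <- cfg$M
  NB <- cc$NB

  dY <- fw$probs
  dY[idx] <- dY[idx] - 1
  dY <- dY / B
  g <- list(
    cls_W = dY %*% t(cc$eN),
    cls_b = rowSums(dY)
  )
  deN <- t(params$cls_W) %*% dY

  dHf <- array(0, c(cfg$v, cfg$N, B))
  dHb <- array(0, c(cfg$v, cfg$N, B))
  dHf[, cfg$N, ] <- deN[seq_len(cfg$v), ]
  dHb[, cfg$N, ] <- deN[cfg$v + seq_len(cfg$v), ]
  bt_f <- lstm_dir_backward(params$tm_f_Wx, params$tm_f_Wh, params$tm_f_b,
                            cc$tmf, dHf)
  bt_b <- lstm_dir_backward(params$tm_b_Wx, params$tm_b_Wh, params$tm_b_b,
                            cc$tmb, dHb)
  g$tm_f_Wx <- bt_f$dWx; g$tm_f_Wh <- bt_f$dWh; g$tm_f_b <- bt_f$db
  g$tm_b_Wx <- bt_b$dWx; g$tm_b_Wh <- bt_b$dWh; g$tm_b_b <- bt_b$db
  dD <- bt_f$dX + bt_b$dX

  dChat <- array(dD, c(2 * cfg$u, cfg$K, NB))
  dPre <- dChat * (cc$Pre > 0)
  g$comp_b <- rowSums(dPre, dims = 1)
  dPreP <- aperm(dPre, c(1, 3, 2))
  dim(dPreP) <- c(2 * cfg$u * NB, cfg$K)
  g$comp_G <- crossprod(cc$Cp, dPreP)
  dCp <- dPreP %*% t(params$comp_G)
  dim(dCp) <- c(2 * cfg$u, NB, M)
  dC <- aperm(dCp, c(1, 3, 2))

  dHsf <- dC[seq_len(cfg$u), , , drop = FALSE]
  dim(dHsf) <- c(cfg$u, M, NB)
  dHsb <- dC[cfg$u + seq_len(cfg$u), , , drop = FALSE]
  dim(dHsb) <- c(cfg$u, M, NB)
  bs_f <- lstm_dir_backward(params$sp_f_Wx, params$sp_f_Wh, params$sp_f_b,
                            cc$spf, dHsf)
  bs_b <- lstm_dir_backward(params$sp_b_Wx, params$sp_b_Wh, params$sp_b_b,
                            cc$spb, dHsb)
  g$sp_f_Wx <- bs_f$dWx; g$sp_f_Wh <- bs_f$dWh; g$sp_f_b <- bs_f$db
  g$sp_b_Wx <- bs_b$dWx; g$sp_b_Wh <- bs_b$dWh; g$sp_b_b <- bs_b$db
  dAhat <- bs_f$dX + bs_b$dX

  if (cfg$use_channel_attention) {
    if (use_native()) {
      mixg <- .att_mix_bwd_cpp(cc$A, cc$Wsm, dAhat)
      dA <- mixg$dA
      dWsm <- mixg$dW
    } else {
      ridx_a <- rep(seq_len(cfg$d_a), times = M)
      ridx_w <- rep(seq_len(M), each = cfg$d_a)
      dAhat2 <- dAhat
      dim(dAhat2) <- c(cfg$d_a * M, NB)
      dA <- array(0, c(cfg$d_a, M, NB))
      dWsm <- array(0, c(M, M, NB))
      for (j in seq_len(M)) {
        Aj <- cc$A[, j, ]
        dim(Aj) <- c(cfg$d_a, NB)
        q <- Aj[ridx_a, , drop = FALSE] * dAhat2
        dim(q) <- c(cfg$d_a, M, NB)
        dWsm[j, , ] <- colSums(q)
        Wj <- cc$Wsm[j, , ]
        dim(Wj) <- c(M, NB)
        tmp <- dAhat2 * Wj[ridx_w, , drop = FALSE]
        dim(tmp) <- c(cfg$d_a, M, NB)         # (d, k, s); sum over k
        dA[, j, ] <- rowSums(aperm(tmp, c(1, 3, 2)), dims = 2)
      }
    }
    WsmMat <- matrix(cc$Wsm, M, M * NB)
    dWsmMat <- matrix(dWsm, M, M * NB)
    dot <- colSums(dWsmMat * WsmMat)
    dWrawMat <- WsmMat * (dWsmMat - rep(dot, each = M))
    dS <- aperm(array(dWrawMat, c(M, M, NB)), c(2, 1, 3))   # back to S[r, j, s]
    dSmat <- matrix(dS, M, M * NB)
    g$att_Q <- dSmat %*% t(cc$Tn)
    dTn <- t(params$att_Q) %*% dSmat
    dHA <- dTn * (1 - cc$Tn^2)
    g$att_H <- dHA %*% t(cc$Amat)
    g$att_B <- rowSums(array(dHA, c(cfg$d_h, M, NB)), dims = 2)
    dA <- dA + array(t(params$att_H) %*% dHA, c(cfg$d_a, M, NB))
  } else {
    dA <- dAhat
  }

  gEW <- array(0, dim(params$emb_W))
  gEb <- array(0, dim(params$emb_b))
  for (j in seq_len(M)) {
    dAj <- matrix(dA[, j, ], cfg$d_a, NB)
    gEW[, , j] <- dAj %*% t(cc$Xmats[[j]])
    gEb[, j] <- rowSums(dAj)
  }
  g$emb_W <- gEW
  g$emb_b <- gEb

  list(loss = loss, probs = fw$probs, grads = g[names(params)])
}

#' Per-channel linear embedding of one segment
#'
#' Column `j` of the result is `emb_W[,,j] %*% x[,j] + emb_b[,j]`: each
#' channel owns its own transformation (M distinct parameter sets).
#'
#' @param x_i F x M band-feature matrix of one segment.
#' @param params model parameters ([init_params()]).
#' @return d_a x M embedded segment.
#' @export
channel_embed <- function(x_i, params) {
  x_i <- as.matrix(x_i)
  M <- dim(params$emb_W)[3]
  if (nrow(x_i) != dim(params$emb_W)[2] || ncol(x_i) != M) {
    stopf("segment is %dx%d but embedding expects F=%d x M=%d",
          nrow(x_i), ncol(x_i), dim(params$emb_W)[2], M)
  }
  out <- matrix(0, dim(params$emb_W)[1], M)
  for (j in seq_len(M)) out[, j] <- params$emb_W[, , j] %*% x_i[, j] + params$emb_b[, j]
  out
}

#' Channel-attention weighting of an embedded segment
#'
#' Raw scores `(Q tanh(H A + B))^T` are normalized column-wise with softmax
#' into a column-stochastic M x M weight matrix `W`, and the embedding is
#' mixed as `A %*% W`. With `use_channel_attention = FALSE` the layer is
#' skipped entirely: the embedding passes through unchanged and no weight
#' matrix is produced (the "-C" ablation).
#'
#' @param A_i d_a x M embedded segment.
#' @param params model parameters.
#' @param use_channel_attention logical.
#' @return list with `A_hat` (d_a x M) and `W` (M x M column-stochastic, or
#'   `NULL` when the layer is disabled).
#' @export
channel_attention <- function(A_i, params, use_channel_attention = TRUE) {
  A_i <- as.matrix(A_i)
  if (!use_channel_attention) return(list(A_hat = A_i, W = NULL))
  Tn <- tanh(params$att_H %*% A_i + params$att_B)
  S <- params$att_Q %*% Tn
  check_finite_stage(S, "channel_attention")
  Wraw <- t(S)
  Wexp <- exp(sweep(Wraw, 2, apply(Wraw, 2, max)))
  W <- sweep(Wexp, 2, colSums(Wexp), "/")
  list(A_hat = A_i %*% W, W = W)
}

#' Spatial encoding of one weighted segment
#'
#' The M columns are consumed as a length-M sequence by a bidirectional LSTM
#' (forward and backward outputs concatenated per position, 2u x M), then
#' compressed to K positions with a ReLU-activated linear map over channel
#' positions.
#'
#' @param A_hat d_a x M weighted embedding.
#' @param params model parameters.
#' @param config a [model_config()].
#' @return 2u x K compressed spatial encoding.
#' @export
spatial_encode <- function(A_hat, params, config) {
  A3 <- array(as.matrix(A_hat), c(nrow(A_hat), ncol(A_hat), 1L))
  spf <- lstm_dir_forward(params$sp_f_Wx, params$sp_f_Wh, params$sp_f_b, A3)
  spb <- lstm_dir_forward(params$sp_b_Wx, params$sp_b_Wh, params$sp_b_b, A3,
                          reverse = TRUE)
  C <- rbind(matrix(spf$H, config$u, config$M), matrix(spb$H, config$u, config$M))
  Pre <- C %*% params$comp_G + params$comp_b
  Pre * (Pre > 0)
}

#' Temporal encoding of a segment sequence
#'
#' Each compressed segment encoding is flattened column-major into a vector
#' of length 2uK; the N-vector sequence runs through a bidirectional LSTM and
#' the encoding at the final position is returned.
#'
#' @param segments list of N matrices (2u x K) from [spatial_encode()].
#' @param params model parameters.
#' @param config a [model_config()].
#' @return numeric vector of length 2v.
#' @export
temporal_encode <- function(segments, params, config) {
  if (length(segments) != config$N) {
    stopf("expected %d segment encodings, got %d", config$N, length(segments))
  }
  D <- array(0, c(2 * config$u * config$K, config$N, 1L))
  for (i in seq_along(segments)) D[, i, 1] <- as.vector(segments[[i]])
  tmf <- lstm_dir_forward(params$tm_f_Wx, params$tm_f_Wh, params$tm_f_b, D,
                          want_cache = FALSE)
  tmb <- lstm_dir_forward(params$tm_b_Wx, params$tm_b_Wh, params$tm_b_b, D,
                          reverse = TRUE, want_cache = FALSE)
  c(tmf$H[, config$N, 1], tmb$H[, config$N, 1])
}

#' Class probabilities for feature samples
#'
#' Runs the full forward pass: per-channel embedding, channel attention (when
#' enabled), spatial BiLSTM with compression per segment, temporal BiLSTM
#' across segments, linear softmax classifier.
#'
#' @param X one F x M x N array, or an F x M x N x B batch.
#' @param params model parameters.
#' @param config a [model_config()].
#' @param want_attention also return the per-segment attention matrices
#'   (array M x M x N x B).
#' @return list with `probs` (T x B matrix; columns sum to 1) and optionally
#'   `attention`.
#' @export
predict_proba <- function(X, params, config, want_attention = FALSE) {
  fw <- forward_full(params, config, X, want_attention = want_attention)
  out <- list(probs = fw$probs)
  if (want_attention) out$attention <- fw$attention
  out
}
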