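test_that("channel embedding is per-channel and affine", {
  cfg <- model_config(n_bands = 4, n_channels = 3, n_segments = 2,
                      d_a = 4, d_h = 3, u = 2, K = 2, v = 3, seed = 1)
  p <- init_params(cfg)
  # identity map: M_j = I, b = 0 reproduces the input
  p_id <- p
  for (j in 1:3) p_id$emb_W[, , j] <- diag(4)
  p_id$emb_b[] <- 0
  withr::with_seed(1, x <- matrix(rnorm(12), 4, 3))
  expect_equal(channel_embed(x, p_id), x)
  # zero input returns the biases
  withr::with_seed(2, p$emb_b[] <- rnorm(12))
  expect_equal(channel_embed(matrix(0, 4, 3), p), p$emb_b, ignore_attr = TRUE)
  # locality: perturbing channel 3 changes only column 3
  a0 <- channel_embed(x, p)
  x2 <- x
  x2[, 3] <- x2[, 3] + 1
  a1 <- channel_embed(x2, p)
  expect_equal(a1[, 1:2], a0[, 1:2])
  expect_false(isTRUE(all.equal(a1[, 3], a0[, 3])))
  expect_error(channel_embed(matrix(0, 5, 3), p), "F=4")
})

test_that("attention weights are column-stochastic with softmax invariances", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  withr::with_seed(3, A <- matrix(rnorm(cfg$d_a * cfg$M), cfg$d_a, cfg$M))
  out <- channel_attention(A, p)
  expect_equal(colSums(out$W), rep(1, cfg$M), tolerance = 1e-6)
  expect_true(all(out$W > 0 & out$W < 1))
  expect_equal(out$A_hat, A %*% out$W)

  # raw scores all equal -> uniform weights, columns of A_hat = row means
  p_flat <- p
  p_flat$att_H[] <- 0
  p_flat$att_Q[] <- 0
  out_u <- channel_attention(A, p_flat)
  expect_equal(out_u$W, matrix(1 / cfg$M, cfg$M, cfg$M))
  expect_equal(out_u$A_hat, matrix(rowMeans(A), cfg$d_a, cfg$M))

  # M = 1: softmax of a single logit is 1
  cfg1 <- model_config(n_bands = 2, n_channels = 1, n_segments = 2,
                       d_a = 3, d_h = 2, u = 2, K = 1, v = 2, seed = 2)
  p1 <- init_params(cfg1)
  withr::with_seed(4, A1 <- matrix(rnorm(3), 3, 1))
  out1 <- channel_attention(A1, p1)
  expect_equal(out1$W, matrix(1, 1, 1))
  expect_equal(out1$A_hat, A1)
})

test_that("the no-attention ablation skips the layer rather than using W = I", {
  cfg_on <- tiny_model_config()
  cfg_off <- tiny_model_config(use_channel_attention = FALSE)
  p_on <- init_params(cfg_on)
  p_off <- init_params(cfg_off)
  expect_null(p_off$att_H)
  b <- random_batch(cfg_on, B = 2)
  # share all non-attention weights
  for (nm in names(p_off)) p_on[[nm]] <- p_off[[nm]]
  off <- predict_proba(b$X, p_off, cfg_off)$probs
  on <- predict_proba(b$X, p_on, cfg_on)$probs
  expect_false(isTRUE(all.equal(off, on)))   # the ablation is not identity-weight
  out <- channel_attention(matrix(1, cfg_on$d_a, cfg_on$M), p_on,
                           use_channel_attention = FALSE)
  expect_null(out$W)
})

test_that("spatial encoding honours ReLU and sequence direction", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  withr::with_seed(5, A <- matrix(rnorm(cfg$d_a * cfg$M), cfg$d_a, cfg$M))
  # forcing a strongly negative pre-activation clamps that entry to 0
  p_neg <- p
  p_neg$comp_b[] <- -100
  expect_equal(spatial_encode(A, p_neg, cfg),
               matrix(0, 2 * cfg$u, cfg$K))
  out <- spatial_encode(A, p, cfg)
  expect_equal(dim(out), c(2 * cfg$u, cfg$K))
  expect_true(all(out >= 0))
  # reversing the channel order changes the encoding (directional recurrence)
  out_rev <- spatial_encode(A[, rev(seq_len(cfg$M))], p, cfg)
  expect_false(isTRUE(all.equal(out, out_rev)))
})

test_that("temporal encoding flattens column-major and sees early segments", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  withr::with_seed(6, segs <- replicate(cfg$N, matrix(rnorm(2 * cfg$u * cfg$K),
                                                      2 * cfg$u, cfg$K),
                                        simplify = FALSE))
  e <- temporal_encode(segs, p, cfg)
  expect_length(e, 2 * cfg$v)
  expect_true(all(is.finite(e)))
  expect_error(temporal_encode(segs[1:2], p, cfg), "expected 3")
  # sensitivity to segment 1 via the forward recurrence
  segs2 <- segs
  segs2[[1]] <- segs2[[1]] + 1
  expect_false(isTRUE(all.equal(e, temporal_encode(segs2, p, cfg))))
  # N = 1 degenerates to a single step
  cfg1 <- tiny_model_config()
  cfg1$N <- 1L
  expect_length(temporal_encode(segs[1], p, cfg1), 2 * cfg$v)
})

test_that("predicted probabilities are a proper softmax", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  b <- random_batch(cfg, B = 4)
  out <- predict_proba(b$X, p, cfg)
  expect_equal(colSums(out$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$probs > 0 & out$probs < 1))
  # zero classifier -> exactly uniform
  p0 <- p
  p0$cls_W[] <- 0
  p0$cls_b[] <- 0
  expect_equal(predict_proba(b$X, p0, cfg)$probs,
               matrix(0.5, 2, 4))
  # two passes are bit-identical
  expect_identical(out$probs, predict_proba(b$X, p, cfg)$probs)
})

test_that("per-segment attention matrices are exported column-stochastic", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  b <- random_batch(cfg, B = 2)
  out <- predict_proba(b$X, p, cfg, want_attention = TRUE)
  expect_equal(dim(out$attention), c(cfg$M, cfg$M, cfg$N, 2))
  sums <- apply(out$attention, 3:4, colSums)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("column-stochasticity holds across random inputs (property)", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  withr::with_seed(8, {
    for (i in 1:10) {
      X <- array(rnorm(cfg$F * cfg$M * cfg$N) * 10^runif(1, -2, 2),
                 c(cfg$F, cfg$M, cfg$N))
      W <- predict_proba(X, p, cfg, want_attention = TRUE)$attention
      expect_true(all(abs(apply(W, 3:4, colSums) - 1) < 1e-6))
    }
  })
})

test_that("parameter count matches the closed form", {
  for (cfg in list(tiny_model_config(),
                   tiny_model_config(use_channel_attention = FALSE),
                   small_eval_model_config())) {
    p <- init_params(cfg)
    expect_equal(sum(vapply(p, length, integer(1))), param_count(cfg))
  }
})

test_that("compiled and reference kernels agree to machine precision", {
  skip_if_not(pfeeg:::use_native())
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  b <- random_batch(cfg, B = 3)
  lg_n <- pfeeg:::loss_and_grads(p, cfg, b$X, b$y)
  lg_r <- withr::with_options(list(pfeeg.use_native = FALSE),
                              pfeeg:::loss_and_grads(p, cfg, b$X, b$y))
  expect_equal(lg_n$loss, lg_r$loss, tolerance = 1e-12)
  for (nm in names(p)) {
    expect_equal(lg_n$grads[[nm]], lg_r$grads[[nm]], tolerance = 1e-10)
  }
})

test_that("shape mismatches and non-finite inputs raise stage-named errors", {
  cfg <- tiny_model_config()
  p <- init_params(cfg)
  bad <- array(0, c(cfg$F + 1, cfg$M, cfg$N))
  expect_error(predict_proba(bad, p, cfg), "do not match config")
  p_bad <- p
  p_bad$att_Q[] <- NaN
  x <- random_batch(cfg, B = 1)$X
  expect_error(predict_proba(x, p_bad, cfg), "channel_attention")
})

test_that("checkpoints round-trip through the JSON container", {
  cfg <- tiny_model_config()
  b <- random_batch(cfg, B = 6, seed = 12)
  m <- train_model(b$X, b$y, cfg, train_config(epochs = 2, batch_size = 3, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, m$params, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict(m2, b$X)$probs, predict(m, b$X)$probs, tolerance = 1e-10)
})
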