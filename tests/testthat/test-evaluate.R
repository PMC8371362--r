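# fast training settings for protocol-level tests: tiny model, few epochs —
# these tests check protocol accounting, not accuracy
fast_mc <- function() model_config(n_bands = 5, n_channels = 8, n_segments = 9,
                                   d_a = 4, d_h = 4, u = 4, K = 2, v = 4)
fast_tc <- function() train_config(epochs = 2, batch_size = 64, lr = 3e-3, seed = 1)

test_that("k-fold partitions samples into near-equal disjoint test folds", {
  ds <- small_dataset()
  feats <- small_features()
  ev <- evaluate_kfold(ds, feats, axis = "valence", method = "xgb",
                       k = 5, seed = 3)
  expect_equal(nrow(ev$per_unit), 5)
  expect_lte(diff(range(ev$per_unit$n)), 1)
  expect_equal(sum(ev$per_unit$n), nrow(feats$meta))
  expect_equal(ev$mean_accuracy, mean(ev$per_unit$accuracy))
  expect_error(evaluate_kfold(ds, feats, method = "xgb",
                              k = nrow(feats$meta) + 1, seed = 1), "exceeds")
})

test_that("identical split seeds give identical folds across methods", {
  ds <- small_dataset()
  feats <- small_features()
  e1 <- evaluate_kfold(ds, feats, axis = "valence", method = "svm", k = 4, seed = 5)
  e2 <- evaluate_kfold(ds, feats, axis = "valence", method = "xgb", k = 4, seed = 5)
  expect_equal(e1$per_unit$n, e2$per_unit$n)
})

test_that("LOSO runs one round per subject and averages over subjects", {
  ds <- small_dataset()
  feats <- small_features()
  ev <- evaluate_loso(ds, feats, axis = "arousal", method = "svm",
                      pf = FALSE, seed = 2)
  expect_equal(nrow(ev$per_unit), nrow(ds$personalities))
  expect_setequal(ev$per_unit$subject_id, ds$personalities$subject_id)
  expect_equal(ev$mean_accuracy, mean(ev$per_unit$accuracy))
})

test_that("PF LOSO routes subjects and reports per-cluster means", {
  ds <- small_dataset()
  feats <- small_features()
  ev <- evaluate_loso(ds, feats, axis = "valence", method = "our",
                      pf = TRUE, P = 2, model_cfg = fast_mc(),
                      train_cfg = fast_tc(), seed = 2)
  expect_true(all(ev$per_unit$cluster %in% 0:1))
  expect_false(is.null(ev$per_cluster))
  expect_true(all(ev$per_cluster$accuracy >= 0 & ev$per_cluster$accuracy <= 1))
  expect_error(evaluate_loso(ds, feats, method = "svm", pf = TRUE,
                             P = nrow(ds$personalities), seed = 1), "exceeds")
})

test_that("no test-label information reaches training (leakage audit)", {
  ds <- small_dataset()
  feats <- small_features()
  subj <- ds$personalities$subject_id[1]
  corrupt <- ds
  sel <- corrupt$ratings$subject_id == subj
  withr::with_seed(1, {
    corrupt$ratings$valence[sel] <- sample(corrupt$ratings$valence[sel])
    corrupt$ratings$valence[sel] <- -corrupt$ratings$valence[sel]
  })
  base <- evaluate_loso(ds, feats, axis = "valence", method = "xgb",
                        pf = TRUE, P = 2, seed = 11)
  pert <- evaluate_loso(corrupt, feats, axis = "valence", method = "xgb",
                        pf = TRUE, P = 2, seed = 11)
  # the corrupted subject's round trains without its ratings, so its model
  # and hence its predictions are bit-identical; only the labels it is
  # scored against (and rounds where it was a *training* subject) may change
  i <- which(base$per_unit$subject_id == subj)
  expect_equal(base$per_unit$cluster[i], pert$per_unit$cluster[i])
  expect_identical(base$predictions[[subj]], pert$predictions[[subj]])
})

test_that("the experiment grid accounts for every cell and survives failures", {
  ds <- small_dataset()
  feats <- small_features()
  grid <- run_experiment_grid(ds, feats, protocol = "kfold",
                              axes = "valence", methods = c("svm", "xgb"),
                              pf_variants = FALSE, k = 3, seed = 4)
  expect_equal(nrow(grid), 2)
  expect_true(all(is.na(grid$error)))
  # an impossible cell is marked, not fatal
  grid2 <- run_experiment_grid(ds, feats, protocol = "kfold",
                               axes = "valence", methods = "svm",
                               pf_variants = FALSE, k = 10000, seed = 4)
  expect_true(is.na(grid2$accuracy))
  expect_match(grid2$error, "exceeds")
})

test_that("the results table has the two-block, four-method layout", {
  grid <- expand.grid(axis = c("valence", "arousal"),
                      method = c("svm", "xgb", "our_c", "our"),
                      pf = c(FALSE, TRUE), stringsAsFactors = FALSE)
  grid$accuracy <- seq(0.5, by = 0.01, length.out = nrow(grid))
  tab <- results_table(grid)
  expect_equal(names(tab),
               c("axis", "svm_noPF", "xgb_noPF", "our_c_noPF", "our_noPF",
                 "svm_PF", "xgb_PF", "our_c_PF", "our_PF"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$svm_noPF[1], 50.0)
})

test_that("attention reports are column-stochastic and per-cluster distinct", {
  ds <- small_dataset()
  feats <- small_features()
  cl <- fit_cluster_models(ds, feats, axis = "valence", P = 2,
                           model_cfg = fast_mc(), train_cfg = fast_tc(),
                           seed = 6)
  rep <- attention_report(cl, ds, feats)
  expect_length(rep$attention, 2)
  for (W in rep$attention) {
    expect_equal(colSums(W), rep(1, ncol(W)), tolerance = 1e-6)
  }
  d <- norm(rep$attention[[1]] - rep$attention[[2]], "F")
  expect_gt(d, 0)
  expect_equal(nrow(rep$importance), 2 * 8)
  # no-attention models cannot produce a report
  cl_c <- fit_cluster_models(ds, feats, axis = "valence", method = "our_c",
                             P = 2, model_cfg = fast_mc(),
                             train_cfg = fast_tc(), seed = 6)
  expect_error(attention_report(cl_c, ds, feats), "without the channel-attention")
})

test_that("flattened features match the tensor layout", {
  feats <- small_features()
  flat <- pfeeg:::flatten_features(feats$X4)
  expect_equal(dim(flat), c(dim(feats$X4)[4], prod(dim(feats$X4)[1:3])))
  expect_equal(flat[3, ], as.vector(feats$X4[, , , 3]))
})
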