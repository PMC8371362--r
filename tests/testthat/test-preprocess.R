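fs <- 32

test_that("common average reference removes the common mode", {
  sig <- matrix(rep(sin(2 * pi * 4 * seq_len(fs * 8) / fs), each = 4),
                nrow = 4, byrow = FALSE)
  sig <- matrix(sin(2 * pi * 4 * seq_len(fs * 8) / fs), 4, fs * 8, byrow = TRUE)
  rec <- eeg_recording("s", 1, sig, fs)
  out <- condition_signal(rec)
  expect_lt(max(abs(out$signal)), 1e-10)
})

test_that("CAR is refused for single-channel recordings", {
  rec <- eeg_recording("s", 1, matrix(rnorm(fs * 4), 1), fs)
  expect_error(condition_signal(rec), "single channel")
  expect_silent(condition_signal(rec, car = FALSE))
})

test_that("sub-band content is removed, in-band content survives CAR + filter", {
  t <- seq_len(fs * 30) / fs
  slow <- matrix(0, 8, length(t))
  slow[1, ] <- sin(2 * pi * 0.2 * t)
  out <- condition_signal(eeg_recording("s", 1, slow, fs))
  expect_lt(sqrt(mean(out$signal[1, ]^2)), 0.05 * sqrt(mean(slow[1, ]^2)))

  # 8 Hz tone on one of 8 otherwise-silent channels: CAR leaves (1 - 1/M) of
  # it on that channel; the 1-15.5 Hz pass-band barely attenuates 8 Hz
  tone <- matrix(0, 8, length(t))
  tone[3, ] <- sin(2 * pi * 8 * t)
  out <- condition_signal(eeg_recording("s", 1, tone, fs), hp_hz = 1, lp_hz = 15.5)
  target <- (1 - 1 / 8) * sqrt(mean(tone[3, ]^2))
  expect_lt(abs(sqrt(mean(out$signal[3, ]^2)) - target) / target, 0.15)
})

test_that("segment counts follow the step-window formula exactly", {
  mk <- function(L) eeg_recording("s", 1, matrix(seq_len(2 * L), 2, L), fs)
  expect_length(segment_trial(mk(100), window_spec(10, 10)), 10)
  expect_length(segment_trial(mk(100), window_spec(10, 5)), 19)
  expect_error(segment_trial(mk(9), window_spec(10)), "width <= L")

  # property: U = floor((L - w)/s) + 1 over an enumeration of small cases,
  # windows half-open [k*s, k*s + w)
  for (L in c(10, 17, 31)) {
    for (w in c(3, 5, 10)) {
      for (s in c(1, 2, 4)) {
        units <- segment_trial(mk(L), window_spec(w, s))
        expect_length(units, (L - w) %/% s + 1)
        k <- length(units) - 1
        expect_equal(units[[k + 1]][1, ], seq(k * s + 1, k * s + w) * 2 - 1)
      }
    }
  }
})

test_that("DE of unit-variance white noise matches the Gaussian closed form", {
  withr::with_seed(11, x <- matrix(rnorm(4096 * 2), 2))
  ident <- band_set(data.frame(name = "all", low = NA_real_, high = NA_real_))
  de <- compute_de(x, ident, fs)
  expect_equal(dim(de), c(1L, 2L))
  expect_lt(max(abs(de - 0.5 * log(2 * pi * exp(1)))), 0.05)
})

test_that("scaling a unit shifts every DE entry by log(c)", {
  withr::with_seed(2, x <- matrix(rnorm(8 * 256), 8))
  d1 <- suppressWarnings(compute_de(x, band_set(), fs))
  d2 <- suppressWarnings(compute_de(2 * x, band_set(), fs))
  expect_equal(d2 - d1, matrix(log(2), nrow(d1), ncol(d1)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a pure 10 Hz tone is attributed to the low-alpha band", {
  x <- matrix(sin(2 * pi * 10 * seq_len(256) / fs), 1)
  de <- compute_de(x, band_set(), fs, check_cycles = FALSE)
  expect_equal(rownames(de)[which.max(de[, 1])], "low_alpha")
})

test_that("degenerate channels hit the variance floor with a warning", {
  x <- matrix(1, 2, 128)
  expect_warning(de <- compute_de(x, band_set(), fs, check_cycles = FALSE),
                 "floor")
  expect_true(all(is.finite(de)))
  expect_equal(unique(as.vector(de)), 0.5 * log(2 * pi * exp(1) * 1e-10))
})

test_that("DE responds to in-band amplitude and only weakly off-band", {
  # 2 Hz sits deep inside delta: the order-4 roll-off leaves < 1% of its
  # power in any other band, so the 10% cross-talk bound is meaningful here
  t <- seq_len(256) / fs
  base <- matrix(sin(2 * pi * 2 * t), 1)
  withr::with_seed(3, noise <- matrix(rnorm(256, sd = 0.3), 1))
  d1 <- suppressWarnings(compute_de(base + noise, band_set(), fs, check_cycles = FALSE))
  d2 <- suppressWarnings(compute_de(3 * base + noise, band_set(), fs, check_cycles = FALSE))
  inc <- d2["delta", 1] - d1["delta", 1]
  expect_gt(inc, 0)
  others <- setdiff(rownames(d1), "delta")
  expect_lt(max(abs(d2[others, 1] - d1[others, 1])), 0.1 * inc)
})

test_that("samples are built from consecutive non-overlapping unit blocks", {
  units <- lapply(1:20, function(i) matrix(i, 2, 3))
  s <- build_samples(units, 9, subject_id = "a", trial_id = 1L)
  expect_length(s, 2)
  expect_equal(dim(s[[1]]$X), c(2, 3, 9))
  expect_equal(s[[1]]$X[1, 1, ], as.numeric(1:9))
  expect_equal(s[[2]]$X[1, 1, ], as.numeric(10:18))
  expect_equal(s[[1]]$segment_range, c(0L, 8L))

  s1 <- build_samples(units[1:9], 9)
  expect_length(s1, 1)
  for (i in 1:9) expect_equal(s1[[1]]$X[, , i], units[[i]])
  expect_warning(s0 <- build_samples(units[1:8], 9), "no samples")
  expect_length(s0, 0)
})

test_that("median-split labels follow the strict-majority rule with ties to 0", {
  r <- binarize_labels(c(-3, -1, 0, 2))
  expect_equal(r$threshold, -0.5)
  expect_equal(r$labels, c(0L, 0L, 1L, 1L))
  r <- binarize_labels(c(1, 1, 2, 2))
  expect_equal(r$threshold, 1.5)
  expect_equal(r$labels, c(0L, 0L, 1L, 1L))
  # a rating equal to the median is a tie -> 0
  expect_equal(binarize_labels(c(1, 2, 3))$labels, c(0L, 0L, 1L))
  expect_error(binarize_labels(c(2, 2, 2)), "identical")
})

test_that("the featurization pipeline is deterministic", {
  ds <- small_dataset()
  one <- function() {
    rec <- ds$recordings[[1]]
    cond <- condition_signal(rec)
    units <- segment_trial(cond, window_spec(fs))
    lapply(units, function(u) compute_de(u, band_set(), fs, check_cycles = FALSE))
  }
  expect_identical(suppressWarnings(one()), suppressWarnings(one()))
})

test_that("every feature sample is finite with F x M x N entries", {
  feats <- small_features()
  expect_true(all(is.finite(feats$X4)))
  expect_equal(dim(feats$X4)[1:3], c(5L, 8L, 9L))
  expect_equal(nrow(feats$meta), dim(feats$X4)[4])
})
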