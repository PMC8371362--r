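#' Window specification for trial segmentation
#'
#' A two-dimensional step window of width `width` samples sliding by `step`
#' samples over the full channel height of the recording. The number of
#' units cut from a trial of length L is `floor((L - width) / step) + 1`.
#'
#' @param width window width in samples.
#' @param step step length in samples (default: `width`, non-overlapping).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(width, step = width) {
  stopifnot(width >= 1, step >= 1)
  structure(list(width = as.integer(width), step = as.integer(step)),
            class = "window_spec")
}

#' Condition a recording: common average reference, then band-pass
#'
#' Subtracts the across-channel mean at every sample (common average
#' reference, CAR), then applies a zero-phase order-4 Butterworth band-pass
#' between `hp_hz` and `lp_hz` to every channel. The default 1-16 Hz band is
#' the conventional setting for low-rate consumer EEG; at `fs = 32` the 16 Hz
#' edge equals Nyquist and is clipped to `0.98 * fs / 2` (see [bw_filter()]).
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz high-pass edge, Hz.
#' @param lp_hz low-pass edge, Hz.
#' @param car apply the common average reference (requires >= 2 channels).
#' @param artifact_removal optional function `matrix -> matrix` applied after
#'   CAR and before filtering, e.g. an ICA-based ocular artifact scrubber.
#'   Default `NULL` (no-op): the synthetic data carries no such artifacts and
#'   real-data users are expected to delegate to dedicated tooling.
#' @return a conditioned [eeg_recording()], same shape.
#' @export
condition_signal <- function(rec, hp_hz = 1, lp_hz = 16, car = TRUE,
                             artifact_removal = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (hp_hz <= 0 || hp_hz >= lp_hz) stopf("need 0 < hp_hz < lp_hz, got %g / %g", hp_hz, lp_hz)
  sig <- rec$signal
  if (car) {
    if (nrow(sig) < 2) {
      stopf("common average reference is undefined for a single channel; use car = FALSE")
    }
    sig <- sweep(sig, 2, colMeans(sig))
  }
  if (!is.null(artifact_removal)) sig <- artifact_removal(sig)
  filt <- t(bw_filter(t(sig), rec$fs, low = hp_hz, high = lp_hz))
  eeg_recording(rec$subject_id, rec$trial_id, filt, rec$fs)
}

#' Cut a recording into data units with a step window
#'
#' Unit `k` (0-based) covers samples `[k * step, k * step + width)` (0-based,
#' half-open); trailing samples that do not fill a window are dropped.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [window_spec()].
#' @return list of `U = floor((L - width)/step) + 1` matrices, channels x width.
#' @export
segment_trial <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "window_spec"))
  L <- ncol(rec$signal)
  if (spec$width > L) {
    stopf("window width %d exceeds trial length %d (constraint: width <= L)",
          spec$width, L)
  }
  U <- (L - spec$width) %/% spec$step + 1L
  lapply(seq_len(U) - 1L, function(k) {
    rec$signal[, k * spec$step + seq_len(spec$width), drop = FALSE]
  })
}

#' Differential entropy band features of one data unit
#'
#' For each band and channel, the channel is zero-phase band-pass filtered,
#' the signal variance is estimated and the differential entropy of a
#' Gaussian with that variance is returned: `0.5 * log(2 * pi * e * var)`
#' nats. Variance is floored at `var_floor` so degenerate (constant)
#' channels produce a finite floor value with a warning rather than -Inf.
#' A band whose edges are both `NA` bypasses filtering (identity band).
#'
#' @param unit channels x width numeric matrix.
#' @param bands a [band_set()].
#' @param fs sampling rate in Hz.
#' @param var_floor variance floor before the log.
#' @param check_cycles warn when the window holds fewer than two cycles of a
#'   band's low edge (the variance estimate for that band is then coarse).
#' @return F x M matrix (bands x channels), rownames = band names.
#' @export
compute_de <- function(unit, bands = band_set(), fs, var_floor = 1e-10,
                       check_cycles = TRUE) {
  unit <- as.matrix(unit)
  stopifnot(fs > 0)
  assert_finite(unit, "data unit")
  M <- nrow(unit)
  w <- ncol(unit)
  out <- matrix(NA_real_, nrow(bands), M, dimnames = list(bands$name, NULL))
  tx <- t(unit)
  floored <- FALSE
  for (b in seq_len(nrow(bands))) {
    lo <- bands$low[b]
    hi <- bands$high[b]
    if (is.na(lo) && is.na(hi)) {
      filt <- tx
    } else {
      if (check_cycles && !is.na(lo) && w < 2 * fs / lo) {
        warnf("window of %d samples holds < 2 cycles of the %g Hz band edge", w, lo)
      }
      filt <- bw_filter(tx, fs,
                        low = if (is.na(lo)) NULL else lo,
                        high = if (is.na(hi)) NULL else hi)
      filt <- as.matrix(filt)
    }
    cmn <- colMeans(filt)
    v <- (colSums(filt^2) - w * cmn^2) / (w - 1)
    v <- pmax(v, 0)
    if (any(v < var_floor)) floored <- TRUE
    v <- pmax(v, var_floor)
    out[b, ] <- 0.5 * log(2 * pi * exp(1) * v)
  }
  if (floored) warnf("variance floored at %g for a degenerate channel/band", var_floor)
  out
}

#' Assemble experimental samples from consecutive DE units
#'
#' Consecutive non-overlapping blocks of `n_segments` DE feature matrices
#' (default 9, the adjacent-segment sample size used throughout) become one
#' sample tensor `X` of shape F x M x N; leftover units are dropped. Labels
#' may be `NA` and attached later (the evaluation protocols binarize ratings
#' with split-local medians).
#'
#' @param de_units ordered list of F x M DE matrices from one trial.
#' @param n_segments segments per sample N.
#' @param label_valence,label_arousal 0/1 labels (or `NA`).
#' @param subject_id,trial_id provenance carried on each sample.
#' @return list of `feature_sample` objects (empty, with a warning, when
#'   fewer than `n_segments` units are supplied).
#' @export
build_samples <- function(de_units, n_segments = 9,
                          label_valence = NA_integer_, label_arousal = NA_integer_,
                          subject_id = NA_character_, trial_id = NA_integer_) {
  stopifnot(n_segments >= 1)
  U <- length(de_units)
  n_samp <- U %/% n_segments
  if (n_samp == 0) {
    warnf("only %d units for %d segments per sample; no samples built", U, n_segments)
    return(list())
  }
  dims <- dim(de_units[[1]])
  lapply(seq_len(n_samp), function(i) {
    idx <- (i - 1L) * n_segments + seq_len(n_segments)
    X <- array(NA_real_, c(dims[1], dims[2], n_segments))
    for (j in seq_along(idx)) X[, , j] <- de_units[[idx[j]]]
    structure(
      list(X = X, label_valence = label_valence, label_arousal = label_arousal,
           subject_id = subject_id, trial_id = trial_id,
           segment_range = c(idx[1] - 1L, idx[length(idx)] - 1L)),
      class = "feature_sample"
    )
  })
}

#' Median-split binarization of affect ratings
#'
#' Label 1 for ratings strictly greater than the median of the supplied
#' rating population, 0 otherwise (ties at the median go to 0). The caller
#' chooses the population: the evaluation protocols pass training-split
#' ratings only, so no test-label information leaks into the threshold.
#'
#' @param ratings numeric vector (>= 2 values, not all identical).
#' @return list with `labels` (integer 0/1 per rating) and `threshold`
#'   (the median used).
#' @export
binarize_labels <- function(ratings) {
  stopifnot(is.numeric(ratings), length(ratings) >= 2)
  if (length(unique(ratings)) == 1) {
    stopf("all ratings identical (%g): no two-part split exists", ratings[1])
  }
  thr <- stats::median(ratings)
  list(labels = as.integer(ratings > thr), threshold = thr)
}

#' Featurize a whole dataset into labelled-later samples
#'
#' Runs conditioning, segmentation, DE extraction and sample assembly over
#' every recording. Labels are left `NA`; evaluation protocols attach them
#' using medians of training-split ratings.
#'
#' @param dataset a `synthetic_eeg_dataset` (or any list with `recordings`).
#' @param bands a [band_set()].
#' @param window_s window width in seconds (default 1, the common DE window).
#' @param step_s step in seconds (default = `window_s`).
#' @param n_segments segments per sample.
#' @param hp_hz,lp_hz conditioning band edges.
#' @return list of `feature_sample`.
#' @export
featurize_dataset <- function(dataset, bands = band_set(), window_s = 1,
                              step_s = window_s, n_segments = 9,
                              hp_hz = 1, lp_hz = 16) {
  samples <- list()
  for (rec in dataset$recordings) {
    cond <- condition_signal(rec, hp_hz = hp_hz, lp_hz = lp_hz)
    spec <- window_spec(round(window_s * rec$fs), round(step_s * rec$fs))
    units <- segment_trial(cond, spec)
    de <- lapply(units, function(u) {
      suppressWarnings(compute_de(u, bands, rec$fs, check_cycles = FALSE))
    })
    if (length(de) < n_segments) next
    samples <- c(samples, build_samples(de, n_segments,
                                        subject_id = rec$subject_id,
                                        trial_id = rec$trial_id))
  }
  samples
}
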