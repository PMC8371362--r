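#' Zero-phase Butterworth filtering
#'
#' Applies a zero-phase band-pass (or one-sided high/low-pass) filter with the
#' squared magnitude response of an order-`order` Butterworth design. This is
#' the transfer function realised by forward-backward ("filtfilt") application
#' of the corresponding Butterworth filter; it is applied multiplicatively in
#' the frequency domain after reflection padding, so no phase distortion and no
#' start-up transient leaks into the output.
#'
#' @param x numeric vector or matrix; matrices are filtered column-wise.
#' @param fs sampling rate in Hz.
#' @param low high-pass edge in Hz, or `NULL` for no high-pass.
#' @param high low-pass edge in Hz, or `NULL` for no low-pass. An edge equal
#'   to the Nyquist frequency `fs/2` is clipped to `0.98 * fs/2` (an order-4
#'   magnitude response at Nyquist is an ill-posed request); an edge above
#'   Nyquist is an error.
#' @param order Butterworth order of the underlying one-pass design (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
bw_filter <- function(x, fs, low = NULL, high = NULL, order = 4) {
  stopifnot(is.numeric(fs), fs > 0, order >= 1)
  edges <- check_band_edges(low, high, fs)
  low <- edges$low
  high <- edges$high
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  assert_finite(xm, "filter input")
  L <- nrow(xm)
  if (L < 2) return(x)

  # reflection padding: odd extension about the end points suppresses edge steps
  pad <- min(L - 1, max(16L, as.integer(ceiling(3 * fs))))
  top <- 2 * xm[rep(1L, pad), , drop = FALSE] - xm[pad + 1L - seq_len(pad), , drop = FALSE]
  bot <- 2 * xm[rep(L, pad), , drop = FALSE] - xm[L - seq_len(pad), , drop = FALSE]
  xp <- rbind(top, xm, bot)
  n <- nrow(xp)

  f <- fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  g <- rep(1, n)
  if (!is.null(high)) g <- g / (1 + (abs(f) / high)^(2 * order))
  if (!is.null(low)) {
    hp <- (abs(f) / low)^(2 * order)
    g <- g * hp / (1 + hp)
    g[f == 0] <- 0
  }
  y <- Re(stats::mvfft(stats::mvfft(xp) * g, inverse = TRUE)) / n
  y <- y[pad + seq_len(L), , drop = FALSE]
  if (vec) drop(y) else y
}

# Validate and (where allowed) clip band edges against Nyquist.
check_band_edges <- function(low, high, fs) {
  nyq <- fs / 2
  if (!is.null(low)) {
    stopifnot(is.numeric(low), low > 0)
    if (low >= nyq) stopf("high-pass edge %g Hz is at or above Nyquist (%g Hz)", low, nyq)
  }
  if (!is.null(high)) {
    stopifnot(is.numeric(high), high > 0)
    if (high > nyq) stopf("low-pass edge %g Hz exceeds Nyquist (%g Hz)", high, nyq)
    if (high == nyq) high <- 0.98 * nyq
  }
  if (!is.null(low) && !is.null(high) && low >= high) {
    stopf("band edges out of order: low %g Hz >= high %g Hz", low, high)
  }
  list(low = low, high = high)
}

#' EEG frequency bands
#'
#' The five-band partition used for differential-entropy features: delta
#' (1-4 Hz), theta (4-8 Hz), low alpha (8-11 Hz), high alpha (11-14 Hz) and
#' beta (14-16 Hz). Band tops at or above Nyquist for a given sampling rate
#' are clipped at filter time, not here.
#'
#' @param bands data.frame with columns `name`, `low`, `high` (Hz), or `NULL`
#'   for the default five bands.
#' @return validated band table (class `band_set`).
#' @export
band_set <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name = c("delta", "theta", "low_alpha", "high_alpha", "beta"),
      low = c(1, 4, 8, 11, 14),
      high = c(4, 8, 11, 14, 16),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in% names(bands)))
  both <- !is.na(bands$low) & !is.na(bands$high)
  if (any(bands$low[both] >= bands$high[both])) stopf("each band needs low < high")
  if (is.unsorted(stats::na.omit(bands$low))) stopf("bands must be ordered by frequency")
  structure(bands, class = c("band_set", "data.frame"))
}
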