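#' Configuration for the synthetic EEG generator
#'
#' Describes a population of subjects whose Big-Five personality vectors form
#' latent clusters and whose EEG carries cluster-specific channel-by-band
#' signal tied to binary affective states. Defaults mirror the scale of the
#' personality-plus-EEG affect datasets this package targets: 8 electrodes at
#' 32 Hz, 36 movie-clip trials per subject, trial lengths around a minute,
#' valence rated on -3..3 and arousal on 0..6.
#'
#' Each cluster `c` (0-based) owns a set of informative channels (default:
#' channel `c %% n_channels`) and a valence band cycling through theta /
#' low-alpha / high-alpha; arousal signal is planted in the beta band on the
#' same channels. The label-to-amplitude polarity alternates with cluster
#' parity: even clusters oscillate in the "high" state, odd clusters in the
#' "low" state. Because the inactive state is indistinguishable from
#' background, a model pooled across clusters faces genuinely ambiguous
#' samples while a per-cluster model does not — the heterogeneity that the
#' personality-first scheme is designed to absorb.
#'
#' @param n_clusters number of latent personality clusters.
#' @param subjects_per_cluster subjects per cluster.
#' @param n_trials trials per subject (even values make the median split of
#'   ratings exact by construction).
#' @param n_channels EEG channels M.
#' @param fs sampling rate in Hz.
#' @param trial_length_s trial length in seconds.
#' @param cluster_sep distance scale between personality cluster centres in
#'   OCEAN space (within-cluster spread is unit isotropic Gaussian).
#' @param signal_snr amplitude of the label-dependent band oscillation
#'   relative to the unit-RMS pink-noise floor; 0 plants no label signal.
#' @param informative_channels optional list mapping cluster index (0-based,
#'   as list names "0", "1", ...) to integer vectors of 0-based channel
#'   indices; default assigns channel `c %% n_channels` to cluster `c`. When
#'   a cluster owns several channels, each subject draws one personal
#'   primary channel from the list (individual functional topography).
#' @param background_jitter_sd standard deviation of the log-normal
#'   per-trial-per-channel background gain jitter (EEG non-stationarity).
#' @param artifact_prob probability that a given (trial, channel) carries a
#'   movement-artifact-like burst: its background is multiplied by
#'   `artifact_gain`. Emulates the residual artifacts that survive when no
#'   component-based artifact removal is applied.
#' @param artifact_gain background amplitude multiplier on artifact trials.
#' @param topo_spread_sd volume-conduction emulation: each subject has a
#'   personal mixing vector that leaks the affective oscillation from the
#'   cluster's informative channel into the other channels, with per-subject
#'   leak weights `|N(0, topo_spread_sd)|` (the informative channel always
#'   has weight 1, so band-power contrast stays maximal there). `0` plants
#'   the signal on the informative channels only.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_clusters = 3,
                             subjects_per_cluster = 5,
                             n_trials = 36,
                             n_channels = 8,
                             fs = 32,
                             trial_length_s = 60,
                             cluster_sep = 6,
                             signal_snr = 1.5,
                             informative_channels = NULL,
                             background_jitter_sd = 0.25,
                             artifact_prob = 0.08,
                             artifact_gain = 6,
                             topo_spread_sd = 0.35,
                             seed = 1L) {
  stopifnot(
    n_clusters >= 1, subjects_per_cluster >= 1, n_trials >= 1,
    n_channels >= 1, fs > 0, trial_length_s > 0
  )
  if (cluster_sep < 0) stopf("cluster_sep must be nonnegative, got %g", cluster_sep)
  if (signal_snr < 0) stopf("signal_snr must be nonnegative, got %g", signal_snr)
  if (trial_length_s * fs < fs) {
    stopf("trial_length_s * fs = %g is below one analysis window (%d samples)",
          trial_length_s * fs, as.integer(fs))
  }
  if (is.null(informative_channels)) {
    informative_channels <- stats::setNames(
      as.list((seq_len(n_clusters) - 1L) %% n_channels),
      as.character(seq_len(n_clusters) - 1L)
    )
  }
  keys <- sort(as.integer(names(informative_channels)))
  if (!identical(keys, seq_len(n_clusters) - 1L)) {
    stopf("informative_channels keys must cover 0..%d", n_clusters - 1L)
  }
  chans <- unlist(informative_channels)
  if (any(chans < 0 | chans >= n_channels)) {
    stopf("informative channel indices must lie in 0..%d", n_channels - 1L)
  }
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      subjects_per_cluster = as.integer(subjects_per_cluster),
      n_trials = as.integer(n_trials),
      n_channels = as.integer(n_channels),
      fs = fs,
      trial_length_s = trial_length_s,
      cluster_sep = cluster_sep,
      signal_snr = signal_snr,
      informative_channels = lapply(informative_channels, as.integer),
      background_jitter_sd = background_jitter_sd,
      artifact_prob = artifact_prob,
      artifact_gain = artifact_gain,
      topo_spread_sd = topo_spread_sd,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# per-cluster valence carrier band (name, centre Hz); arousal always beta.
cluster_valence_band <- function(cluster) {
  carriers <- list(
    theta = 6, low_alpha = 9.5, high_alpha = 12.5
  )
  i <- (cluster %% length(carriers)) + 1L
  list(name = names(carriers)[i], freq = carriers[[i]])
}
AROUSAL_CARRIER_HZ <- 15

#' An EEG recording of one subject-trial
#'
#' @param subject_id character id.
#' @param trial_id integer trial index (1-based).
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, trial_id, signal, fs) {
  signal <- as.matrix(signal)
  stopifnot(nrow(signal) >= 1, ncol(signal) >= 1, fs > 0)
  assert_finite(signal, sprintf("recording %s/trial %s", subject_id, trial_id))
  structure(
    list(subject_id = as.character(subject_id), trial_id = as.integer(trial_id),
         signal = signal, fs = fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s trial %d: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

# 1/f-shaped (pink) noise, unit RMS, length n at rate fs.
pink_noise <- function(n, fs) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- 1 / sqrt(f)
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]), imaginary = 0)
    if (nf > 1) full[n - seq_len(nf - 1) + 1] <- Conj(spec[seq_len(nf - 1)])
  } else {
    full[n - seq_len(nf) + 1] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Balanced 0/1 latent states over n trials (extra 0 when n is odd), shuffled.
balanced_states <- function(n) {
  z <- c(rep(1L, floor(n / 2)), rep(0L, ceiling(n / 2)))
  sample(z)
}

#' Generate a personality-clustered synthetic EEG dataset
#'
#' Personalities are drawn from isotropic unit Gaussians around `n_clusters`
#' centres placed on scaled coordinate axes of OCEAN space (pairwise centre
#' distance `cluster_sep * sqrt(2)`). Each trial's EEG is unit-RMS pink noise
#' on every channel plus, on the trial's cluster-informative channels,
#' band-limited oscillations whose presence is tied to the trial's latent
#' binary valence and arousal states (polarity alternating with cluster
#' parity, see [generator_config()]). Ratings map the latent states to the
#' outer halves of the rating scales with jitter that never crosses the scale
#' midpoint, so a median split recovers the states.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_eeg_dataset`: list with `recordings` (list of
#'   [eeg_recording()]), `personalities` (data.frame subject_id,O,C,E,A,N),
#'   `ratings` (data.frame subject_id,trial_id,valence,arousal),
#'   `true_cluster` (named integer, 0-based), `true_informative_channels`,
#'   `latent` (data.frame of the binary ground-truth states) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    n_sub <- config$n_clusters * config$subjects_per_cluster
    ids <- sprintf("s%02d", seq_len(n_sub))
    cluster <- rep(seq_len(config$n_clusters) - 1L, each = config$subjects_per_cluster)
    names(cluster) <- ids

    centres <- matrix(0, config$n_clusters, 5)
    for (c0 in seq_len(config$n_clusters)) {
      ax <- ((c0 - 1L) %% 5L) + 1L
      centres[c0, ax] <- config$cluster_sep * (1 + (c0 - 1L) %/% 5L)
    }
    pers <- t(vapply(seq_len(n_sub), function(i) {
      centres[cluster[i] + 1L, ] + stats::rnorm(5)
    }, numeric(5)))
    personalities <- data.frame(
      subject_id = ids, O = pers[, 1], C = pers[, 2], E = pers[, 3],
      A = pers[, 4], N = pers[, 5], stringsAsFactors = FALSE
    )

    L <- round(config$trial_length_s * config$fs)
    tt <- seq_len(L) / config$fs
    recordings <- vector("list", n_sub * config$n_trials)
    lat <- rat <- vector("list", n_sub)

    for (i in seq_len(n_sub)) {
      c0 <- cluster[i]
      pol <- ifelse(c0 %% 2L == 0L, 1L, 0L)      # even cluster: state 1 -> burst on
      vband <- cluster_valence_band(c0)
      inf_ch <- config$informative_channels[[as.character(c0)]] + 1L
      zv <- balanced_states(config$n_trials)
      za <- balanced_states(config$n_trials)
      subj_gain <- exp(stats::rnorm(1, 0, 0.1))
      # personal topography: one primary channel drawn from the cluster's
      # informative list, plus subject-specific leakage into every channel
      # (volume conduction through individual anatomy)
      primary <- inf_ch[sample.int(length(inf_ch), 1)]
      topo <- abs(stats::rnorm(config$n_channels, 0, config$topo_spread_sd))
      topo[primary] <- 1
      for (k in seq_len(config$n_trials)) {
        sig <- matrix(0, config$n_channels, L)
        for (m in seq_len(config$n_channels)) {
          g <- exp(stats::rnorm(1, 0, config$background_jitter_sd))
          if (stats::runif(1) < config$artifact_prob) g <- g * config$artifact_gain
          sig[m, ] <- subj_gain * g * pink_noise(L, config$fs)
        }
        von <- as.integer(zv[k] == pol)          # polarity: which state carries the burst
        aon <- as.integer(za[k] == pol)
        if (config$signal_snr > 0 && length(inf_ch) > 0) {
          phv <- stats::runif(1, 0, 2 * pi)
          pha <- stats::runif(1, 0, 2 * pi)
          burst <- von * config$signal_snr * sin(2 * pi * vband$freq * tt + phv) +
                   aon * config$signal_snr * sin(2 * pi * AROUSAL_CARRIER_HZ * tt + pha)
          for (m in seq_len(config$n_channels)) {
            if (topo[m] > 0) sig[m, ] <- sig[m, ] + topo[m] * burst
          }
        }
        recordings[[(i - 1L) * config$n_trials + k]] <-
          eeg_recording(ids[i], k, sig, config$fs)
      }
      # outer-half ratings with a 0.5-unit guard band around the scale midpoint
      val <- ifelse(zv == 1L, stats::runif(config$n_trials, 0.5, 3),
                    stats::runif(config$n_trials, -3, -0.5))
      aro <- ifelse(za == 1L, stats::runif(config$n_trials, 3.5, 6),
                    stats::runif(config$n_trials, 0, 2.5))
      rat[[i]] <- data.frame(subject_id = ids[i], trial_id = seq_len(config$n_trials),
                             valence = val, arousal = aro, stringsAsFactors = FALSE)
      lat[[i]] <- data.frame(subject_id = ids[i], trial_id = seq_len(config$n_trials),
                             z_valence = zv, z_arousal = za, stringsAsFactors = FALSE)
    }

    structure(
      list(
        recordings = recordings,
        personalities = personalities,
        ratings = do.call(rbind, rat),
        true_cluster = cluster,
        true_informative_channels = config$informative_channels,
        latent = do.call(rbind, lat),
        config = config
      ),
      class = "synthetic_eeg_dataset"
    )
  })
}

#' @export
print.synthetic_eeg_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_eeg_dataset> %d subjects (%d clusters), %d trials each, %d ch @ %g Hz\n",
    nrow(x$personalities), x$config$n_clusters, x$config$n_trials,
    x$config$n_channels, x$config$fs
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Layout: `signals/<subject>_trial<k>.csv` (rows = channels, no header),
#' `personalities.csv` (subject_id,O,C,E,A,N), `ratings.csv`
#' (subject_id,trial_id,valence,arousal), ground truth in
#' `truth_clusters.csv` / `truth_latent.csv`, `meta.json` with the sampling
#' rate and generator settings, and `manifest.csv` listing every written file
#' with its md5 checksum.
#'
#' @param dataset a `synthetic_eeg_dataset`.
#' @param directory output directory (created if missing; parent must exist).
#' @return (invisibly) the manifest data.frame (`file`, `md5`, `bytes`).
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_eeg_dataset"))
  if (length(dataset$recordings) == 0) stopf("refusing to write an empty dataset")
  parent <- dirname(normalizePath(directory, mustWork = FALSE))
  if (!dir.exists(parent)) stopf("parent directory does not exist: %s", parent)
  dir.create(directory, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory: %s", directory)
  sig_dir <- file.path(directory, "signals")
  dir.create(sig_dir, showWarnings = FALSE)

  rel <- character(0)
  for (rec in dataset$recordings) {
    f <- file.path("signals", sprintf("%s_trial%02d.csv", rec$subject_id, rec$trial_id))
    utils::write.table(format(rec$signal, digits = 10, trim = TRUE, scientific = TRUE),
                       file.path(directory, f),
                       sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    rel <- c(rel, f)
  }
  wr <- function(df, name) {
    utils::write.csv(df, file.path(directory, name), row.names = FALSE, quote = FALSE)
    name
  }
  rel <- c(rel,
           wr(dataset$personalities, "personalities.csv"),
           wr(dataset$ratings, "ratings.csv"),
           wr(data.frame(subject_id = names(dataset$true_cluster),
                         cluster = as.integer(dataset$true_cluster)),
              "truth_clusters.csv"),
           wr(dataset$latent, "truth_latent.csv"))
  meta <- unclass(dataset$config)
  meta$informative_channels <- NULL
  jsonlite::write_json(
    list(fs = dataset$config$fs, config = meta,
         informative_channels = dataset$config$informative_channels),
    file.path(directory, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  rel <- c(rel, "meta.json")
  paths <- file.path(directory, rel)
  manifest <- data.frame(
    file = rel,
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param directory dataset directory.
#' @return a `synthetic_eeg_dataset` (ground-truth fields present only if the
#'   truth files exist).
#' @export
read_dataset <- function(directory) {
  if (!dir.exists(directory)) stopf("no such directory: %s", directory)
  meta <- jsonlite::read_json(file.path(directory, "meta.json"))
  fs <- as.numeric(meta$fs)
  personalities <- utils::read.csv(file.path(directory, "personalities.csv"),
                                   stringsAsFactors = FALSE)
  ratings <- utils::read.csv(file.path(directory, "ratings.csv"),
                             stringsAsFactors = FALSE)
  sig_files <- sort(list.files(file.path(directory, "signals"), full.names = TRUE))
  recordings <- lapply(sig_files, function(f) {
    nm <- sub("\\.csv$", "", basename(f))
    parts <- regmatches(nm, regexec("^(.*)_trial([0-9]+)$", nm))[[1]]
    sig <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(sig) <- NULL
    eeg_recording(parts[2], as.integer(parts[3]), sig, fs)
  })
  out <- list(recordings = recordings, personalities = personalities,
              ratings = ratings, true_cluster = NULL,
              true_informative_channels = meta$informative_channels,
              latent = NULL, config = meta$config)
  tc <- file.path(directory, "truth_clusters.csv")
  if (file.exists(tc)) {
    df <- utils::read.csv(tc, stringsAsFactors = FALSE)
    out$true_cluster <- stats::setNames(as.integer(df$cluster), df$subject_id)
  }
  tl <- file.path(directory, "truth_latent.csv")
  if (file.exists(tl)) out$latent <- utils::read.csv(tl, stringsAsFactors = FALSE)
  structure(out, class = "synthetic_eeg_dataset")
}
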