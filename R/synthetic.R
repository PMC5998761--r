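#' The five listening-condition class labels
#'
#' Conditions are ordered as they are coded for classification: silent,
#' broadband noise, music, active noise control (ANC) worn during noise, and
#' ANC worn during noise with music played through the headphone.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' eeg_conditions()
eeg_conditions <- function() {
  c("silent", "noise", "music", "anc_noise", "anc_noise_music")
}

#' Clinical EEG rhythm bands used by the synthetic generator
#'
#' Frequency ranges of the delta, theta, alpha and beta rhythms. These are the
#' bands whose power levels distinguish the listening conditions; they differ
#' slightly from the dyadic wavelet bands returned by [band_range()].
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low  = c(0.5, 4, 8, 14),
    high = c(4, 8, 14, 30)
  )
}

#' Standard 19-channel 10-20 montage labels
#'
#' @return Character vector of 19 electrode names.
#' @export
eeg_channels <- function() {
  c(
    "FZ", "CZ", "PZ", "FP1", "FP2", "F3", "F4", "C3", "C4", "P3",
    "P4", "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6"
  )
}

#' Condition-dependent band-power profiles for the synthetic generator
#'
#' One row per listening condition giving the target RMS amplitude (microvolt)
#' of each rhythm band plus a relative amplitude jitter that controls the
#' within-class dispersion of band power over time. The defaults encode the
#' qualitative ordering observed in auditory-stimulus EEG studies: the noise
#' condition carries the highest band amplitudes, the two ANC conditions the
#' lowest, and ANC with music the smallest dispersion (steady, focused
#' listening). The absolute values are free generator parameters, not
#' measurements.
#'
#' @param separation Non-negative scale on the between-class amplitude gap.
#'   `1` keeps the default profiles; `0` collapses every class onto the grand
#'   mean profile (classes become indistinguishable); values > 1 widen the
#'   gaps proportionally. Jitter is unaffected.
#' @return A tibble with columns `condition`, `delta`, `theta`, `alpha`,
#'   `beta` (microvolt RMS) and `jitter` (relative).
#' @export
#' @examples
#' synth_profiles()
#' synth_profiles(separation = 0) # all classes identical
synth_profiles <- function(separation = 1) {
  stopifnot_scalar_number(separation, "separation")
  if (separation < 0) abort("`separation` must be >= 0.")
  prof <- tibble::tibble(
    condition = eeg_conditions(),
    delta = c(20, 24, 19, 17, 16),
    theta = c(10, 13, 9.5, 8.5, 8),
    alpha = c(12, 16, 11, 9, 9.5),
    beta  = c(6, 8, 5.5, 4.5, 4.8),
    jitter = c(0.15, 0.18, 0.15, 0.12, 0.05)
  )
  if (separation != 1) {
    for (b in eeg_bands()$band) {
      mu <- mean(prof[[b]])
      prof[[b]] <- pmax(mu + separation * (prof[[b]] - mu), 0)
    }
  }
  prof
}

#' Configuration of the synthetic multichannel EEG generator
#'
#' Bundles every tunable of the generator: montage, sampling rate, session
#' length, per-condition band-power profiles, and the nuisance components
#' (broadband sensor noise, sub-0.5 Hz baseline drift, and >75 Hz artifact)
#' that the band-limiting filters are expected to remove.
#'
#' @param fs Sampling rate in Hz (default 256).
#' @param channel_labels Ordered electrode names; their number sets the
#'   channel count (default the 19-channel montage of [eeg_channels()]).
#' @param duration_s Session length in seconds per recording (default 420,
#'   i.e. 7 minutes).
#' @param condition_profiles Tibble as returned by [synth_profiles()].
#' @param broadband_noise_rms RMS amplitude (microvolt) of white sensor noise.
#' @param drift_amplitude RMS amplitude (microvolt) of baseline wander below
#'   0.5 Hz.
#' @param hf_artifact_rms RMS amplitude (microvolt) of high-frequency
#'   (>75 Hz) artifact.
#' @param spatial_mixing_strength Number in `[0, 1]`: fraction of each band's
#'   variance carried by a source shared across channels (controls
#'   cross-channel correlation, and with it the effective rank of the
#'   sub-band matrices).
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(duration_s = 10)
#' cfg$fs
synth_config <- function(fs = 256,
                         channel_labels = eeg_channels(),
                         duration_s = 420,
                         condition_profiles = synth_profiles(),
                         broadband_noise_rms = 2,
                         drift_amplitude = 5,
                         hf_artifact_rms = 1,
                         spatial_mixing_strength = 0.5) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (!is.character(channel_labels) || length(channel_labels) < 1L ||
      anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique non-empty channel names.")
  }
  prof <- tibble::as_tibble(condition_profiles)
  needed <- c("condition", eeg_bands()$band, "jitter")
  if (!all(needed %in% names(prof))) {
    abort(sprintf(
      "`condition_profiles` must have columns: %s.",
      paste(needed, collapse = ", ")
    ))
  }
  if (!setequal(prof$condition, eeg_conditions()) ||
      nrow(prof) != length(eeg_conditions())) {
    abort(sprintf(
      "`condition_profiles` must contain exactly the 5 conditions: %s.",
      paste(eeg_conditions(), collapse = ", ")
    ))
  }
  amp <- as.matrix(prof[, eeg_bands()$band])
  if (any(amp < 0) || any(prof$jitter < 0)) {
    abort("All band amplitudes and jitters must be >= 0.")
  }
  for (nm in c("broadband_noise_rms", "drift_amplitude", "hf_artifact_rms")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  stopifnot_scalar_number(spatial_mixing_strength, "spatial_mixing_strength")
  if (spatial_mixing_strength < 0 || spatial_mixing_strength > 1) {
    abort("`spatial_mixing_strength` must be in [0, 1].")
  }
  structure(
    list(
      fs = fs,
      n_channels = length(channel_labels),
      channel_labels = channel_labels,
      duration_s = duration_s,
      condition_profiles = prof,
      broadband_noise_rms = broadband_noise_rms,
      drift_amplitude = drift_amplitude,
      hf_artifact_rms = hf_artifact_rms,
      spatial_mixing_strength = spatial_mixing_strength
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d channels @ %g Hz, %g s per recording\n",
    x$n_channels, x$fs, x$duration_s
  ))
  print(x$condition_profiles)
  invisible(x)
}

# Unit-RMS stochastic signal band-limited to [low, high] Hz (4th-order
# Butterworth on white noise). low = 0 means low-pass only; high = Inf
# means high-pass only.
.butter_cache <- new.env(parent = emptyenv())

band_filter <- function(fs, low, high, order) {
  key <- paste(fs, low, high, order)
  hit <- .butter_cache[[key]]
  if (!is.null(hit)) return(hit)
  nyq <- fs / 2
  flt <- if (low <= 0 && is.finite(high)) {
    signal::butter(order, high / nyq, type = "low")
  } else if (low > 0 && !is.finite(high)) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  .butter_cache[[key]] <- flt
  flt
}

bandlimited_noise <- function(n, fs, low, high, order = 4) {
  x <- rnorm(n)
  flt <- band_filter(fs, low, high, order)
  y <- filtfilt_ss(flt$b, flt$a, x)
  r <- sqrt(mean(y^2))
  if (r == 0) y else y / r
}

#' Generate one synthetic multichannel EEG recording
#'
#' Synthesises a labeled recording for a single listening condition. Each
#' rhythm band is a stationary band-limited stochastic process (white noise
#' through a 4th-order Butterworth band-pass), built from one source shared
#' across channels plus per-channel independent residuals weighted by
#' `spatial_mixing_strength`, scaled to the condition's RMS amplitude and
#' slowly amplitude-modulated with relative depth `jitter` so band power
#' varies between frames. Baseline drift, high-frequency artifact and
#' broadband sensor noise are then added per channel.
#'
#' Identical `(cfg, condition, seed)` always yield an identical recording.
#'
#' @param cfg A [synth_config()].
#' @param condition One of [eeg_conditions()].
#' @param seed Non-negative integer seed.
#' @return An `eeg_recording`: list with `samples` (time-by-channel matrix,
#'   microvolt), `fs`, `channel_labels` and `condition`.
#' @export
#' @examples
#' rec <- synth_recording(synth_config(duration_s = 4), "silent", seed = 1)
#' dim(rec$samples)
synth_recording <- function(cfg, condition, seed) {
  if (!inherits(cfg, "synth_config")) abort("`cfg` must be a synth_config.")
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% eeg_conditions())) {
    abort(sprintf(
      "Unknown condition %s; valid conditions are: %s.",
      deparse(condition), paste(eeg_conditions(), collapse = ", ")
    ))
  }
  n <- round(cfg$fs * cfg$duration_s)
  if (n < 1) abort("`duration_s` too short: no samples to generate.")
  ch <- cfg$n_channels
  prof <- cfg$condition_profiles
  row <- prof[prof$condition == condition, ]
  w <- cfg$spatial_mixing_strength
  bands <- eeg_bands()

  samples <- with_seed(seed, {
    out <- matrix(0, n, ch)
    for (bi in seq_len(nrow(bands))) {
      a <- row[[bands$band[bi]]]
      if (a == 0) next
      shared <- bandlimited_noise(n, cfg$fs, bands$low[bi], bands$high[bi])
      # slow (<0.2 Hz) multiplicative envelope: between-frame power jitter
      env <- 1
      if (row$jitter > 0) {
        env <- pmax(1 + row$jitter * bandlimited_noise(n, cfg$fs, 0, 0.2, 2),
                    0.05)
      }
      for (p in seq_len(ch)) {
        indep <- bandlimited_noise(n, cfg$fs, bands$low[bi], bands$high[bi])
        src <- sqrt(w) * shared + sqrt(1 - w) * indep
        out[, p] <- out[, p] + a * env * src
      }
    }
    if (cfg$drift_amplitude > 0) {
      for (p in seq_len(ch)) {
        out[, p] <- out[, p] +
          cfg$drift_amplitude * bandlimited_noise(n, cfg$fs, 0, 0.25, 2)
      }
    }
    if (cfg$hf_artifact_rms > 0 && cfg$fs / 2 > 80) {
      for (p in seq_len(ch)) {
        out[, p] <- out[, p] +
          cfg$hf_artifact_rms * bandlimited_noise(n, cfg$fs, 80, Inf)
      }
    }
    if (cfg$broadband_noise_rms > 0) {
      out <- out + cfg$broadband_noise_rms * matrix(rnorm(n * ch), n, ch)
    }
    out
  })
  colnames(samples) <- cfg$channel_labels
  new_eeg_recording(samples, cfg$fs, cfg$channel_labels, condition)
}

new_eeg_recording <- function(samples, fs, channel_labels, condition = NULL) {
  stopifnot(is.matrix(samples), ncol(samples) == length(channel_labels))
  if (!all(is.finite(samples))) abort("Recording samples must be finite.")
  structure(
    list(
      samples = samples, fs = fs,
      channel_labels = channel_labels, condition = condition
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)%s\n",
    nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs,
    if (is.null(x$condition)) "" else paste0(", condition: ", x$condition)
  ))
  invisible(x)
}

#' Coerce a recording to a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `time` (s), `channel`, `value` (microvolt).
#' @exportS3Method tibble::as_tibble
as_tibble.eeg_recording <- function(x, ...) {
  n <- nrow(x$samples)
  tibble::tibble(
    time = rep((seq_len(n) - 1) / x$fs, times = ncol(x$samples)),
    channel = rep(x$channel_labels, each = n),
    value = as.vector(x$samples)
  )
}

#' Generate a balanced, labeled set of 512-sample frames
#'
#' Draws `n_per_class` frames for each of the five listening conditions by
#' simulating recordings with [synth_recording()], band-limiting them to
#' 0.5-75 Hz with [eeg_bandlimit()], and segmenting into non-overlapping
#' `frame_len`-sample frames with [eeg_segment()]. If one recording of
#' `cfg$duration_s` does not yield enough frames, additional recordings are
#' simulated internally with derived seeds (frame demand never errors).
#'
#' @inheritParams synth_recording
#' @param n_per_class Frames per condition (>= 1).
#' @param frame_len Samples per frame (default 512).
#' @param bandlimit Apply band-limiting before segmenting (default TRUE; set
#'   FALSE to study raw frames with drift and artifact).
#' @param hp_hz,lp_hz Band-limiting cut-offs passed to [eeg_bandlimit()].
#' @return Tibble with columns `condition` (factor), `frame_id` (integer) and
#'   `frame` (list of `frame_len`-by-channels matrices), `5 * n_per_class`
#'   rows, deterministic per seed.
#' @export
#' @examples
#' frames <- synth_frames(synth_config(duration_s = 8), n_per_class = 2, seed = 1)
#' dplyr::count(frames, condition)
synth_frames <- function(cfg, n_per_class, seed, frame_len = 512,
                         bandlimit = TRUE, hp_hz = 0.5, lp_hz = 75) {
  if (!inherits(cfg, "synth_config")) abort("`cfg` must be a synth_config.")
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be >= 1.")
  }
  n_per_class <- as.integer(n_per_class)
  res <- purrr::map(seq_along(eeg_conditions()), function(ci) {
    cond <- eeg_conditions()[ci]
    frames <- list()
    attempt <- 0L
    while (length(frames) < n_per_class) {
      rec <- synth_recording(
        cfg, cond,
        seed = derive_seed(seed, 100L * ci + attempt)
      )
      if (bandlimit) rec <- eeg_bandlimit(rec, hp_hz = hp_hz, lp_hz = lp_hz)
      seg <- eeg_segment(rec, frame_len = frame_len)
      frames <- c(frames, seg$frame)
      attempt <- attempt + 1L
      if (attempt > 1000L) abort("Frame generation failed to converge.")
    }
    tibble::tibble(
      condition = cond,
      frame_id = seq_len(n_per_class),
      frame = frames[seq_len(n_per_class)]
    )
  })
  out <- dplyr::bind_rows(res)
  out$condition <- factor(out$condition, levels = eeg_conditions())
  out
}

#' Plot a few channels of a recording
#'
#' @param object An `eeg_recording`.
#' @param channels Channel labels to draw (default first 4).
#' @param start,duration Window in seconds.
#' @param ... Unused.
#' @return A ggplot object of stacked channel traces.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_recording <- function(object, channels = NULL, start = 0,
                                   duration = 5, ...) {
  channels <- channels %||% utils::head(object$channel_labels, 4)
  df <- as_tibble.eeg_recording(object)
  df <- dplyr::filter(
    df, .data$channel %in% channels,
    .data$time >= start, .data$time < start + duration
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (µV)",
      title = if (is.null(object$condition)) NULL else
        paste("condition:", object$condition)
    )
}
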