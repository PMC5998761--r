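# Zero-phase IIR filtering via a cascade of second-order sections.
#
# Forward-backward filtering squares the magnitude response and cancels the
# phase, so no group delay is introduced between channels. The transfer
# function is factored into biquads (pairing conjugate poles) because a
# direct-form recursion of a 0.5 Hz high-pass at fs = 256 has poles close
# enough to the unit circle that double precision loses ~7 digits; the
# cascade keeps the operation linear to ~1e-13 relative. Edges are handled
# scipy-style: odd reflection about the end points plus steady-state step
# initial conditions, so a constant input produces its steady-state response
# from sample one.

# real polynomial (descending powers, monic) from a set of roots
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, ri * p)
  Re(p)
}

# factor a transfer function b(z)/a(z) into second-order sections
# (memoised: filters are re-used across channels and recordings)
.sos_cache <- new.env(parent = emptyenv())

sos_sections <- function(b, a) {
  key <- paste(format(c(b, a), digits = 17), collapse = ",")
  hit <- .sos_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- sos_sections_impl(b, a)
  .sos_cache[[key]] <- out
  out
}

sos_sections_impl <- function(b, a) {
  k <- b[1] / a[1]
  zeros <- polyroot(rev(b / b[1]))
  poles <- polyroot(rev(a / a[1]))
  ord <- function(r) r[order(-abs(Im(r)), Re(r))]
  zeros <- ord(zeros)
  poles <- ord(poles)
  ns <- ceiling(length(poles) / 2)
  lapply(seq_len(ns), function(s) {
    i <- (2 * s - 1):min(2 * s, length(poles))
    bs <- poly_from_roots(zeros[i])
    as <- poly_from_roots(poles[i])
    length(bs) <- 3L
    length(as) <- 3L
    bs[is.na(bs)] <- 0
    as[is.na(as)] <- 0
    list(b = bs * if (s == 1) k else 1, a = as)
  })
}

sosfilt_ss <- function(sos, x) {
  for (s in sos) {
    dc_gain <- sum(s$b) / sum(s$a)
    x <- as.numeric(signal::filter(
      s$b, s$a, x,
      init.x = rep(x[1], 2L),
      init.y = rep(x[1] * dc_gain, 2L)
    ))
  }
  x
}

filtfilt_ss <- function(b, a, x) {
  b <- as.numeric(b)
  a <- as.numeric(a)
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  pad <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= pad) {
    abort(sprintf(
      "Signal of length %d is shorter than the filter warm-up (%d samples).",
      n, pad + 1L
    ))
  }
  sos <- sos_sections(b, a)
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- sosfilt_ss(sos, ext)
  y <- rev(sosfilt_ss(sos, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Band-limit a recording to the EEG bandwidth
#'
#' Applies a 4th-order Butterworth high-pass (default 0.5 Hz, removing
#' baseline wander) and low-pass (default 75 Hz, removing high-frequency
#' artifact) to every channel. Both filters run forward and backward
#' (zero-phase), so no group delay is introduced between channels and the
#' effective attenuation is doubled.
#'
#' @param rec An `eeg_recording`.
#' @param hp_hz High-pass cut-off in Hz.
#' @param lp_hz Low-pass cut-off in Hz. Must satisfy
#'   `0 < hp_hz < lp_hz < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A same-shape `eeg_recording`.
#' @export
#' @examples
#' rec <- synth_recording(synth_config(duration_s = 4), "silent", seed = 1)
#' filt <- eeg_bandlimit(rec)
#' dim(filt$samples)
eeg_bandlimit <- function(rec, hp_hz = 0.5, lp_hz = 75, order = 4) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  nyq <- rec$fs / 2
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < nyq)) {
    abort(sprintf(
      "Cut-offs must satisfy 0 < hp_hz < lp_hz < fs/2 = %g Hz (got %g, %g).",
      nyq, hp_hz, lp_hz
    ))
  }
  hp <- signal::butter(order, hp_hz / nyq, type = "high")
  lp <- signal::butter(order, lp_hz / nyq, type = "low")
  out <- apply(rec$samples, 2, function(x) {
    filtfilt_ss(lp$b, lp$a, filtfilt_ss(hp$b, hp$a, x))
  })
  new_eeg_recording(out, rec$fs, rec$channel_labels, rec$condition)
}

#' Segment a recording into non-overlapping frames
#'
#' Frame `i` covers samples `[(i-1) * frame_len + 1, i * frame_len]`; an
#' incomplete tail is discarded. Sample values are copied unmodified and the
#' condition label is propagated to every frame.
#'
#' @param rec An `eeg_recording`.
#' @param frame_len Samples per frame (default 512).
#' @return Tibble with columns `condition`, `frame_id` and `frame` (list of
#'   `frame_len`-by-channels matrices); zero rows if the recording is shorter
#'   than one frame.
#' @export
#' @examples
#' rec <- synth_recording(synth_config(duration_s = 4), "music", seed = 1)
#' nrow(eeg_segment(rec)) # floor(4 * 256 / 512)
eeg_segment <- function(rec, frame_len = 512) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (!is.numeric(frame_len) || frame_len < 1) abort("`frame_len` must be >= 1.")
  frame_len <- as.integer(frame_len)
  n_frames <- nrow(rec$samples) %/% frame_len
  frames <- lapply(seq_len(n_frames), function(i) {
    rec$samples[((i - 1L) * frame_len + 1L):(i * frame_len), , drop = FALSE]
  })
  tibble::tibble(
    condition = rep(rec$condition %||% NA_character_, n_frames),
    frame_id = seq_len(n_frames),
    frame = frames
  )
}
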