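# Recording I/O: a plain CSV dialect (header row of channel labels, one line
# per sample) and minimal EDF (European Data Format) support. No installed R
# package reads or writes EDF, so the small fixed-layout binary format is
# handled here directly: 256-byte ASCII header, 256 bytes per signal, then
# 16-bit little-endian samples in 1-second data records.

#' Write / read a recording as CSV
#'
#' The CSV dialect is a header row of channel labels followed by one row per
#' sample; values are written with 9 significant digits. The sampling rate is
#' not part of the file and must be supplied when reading.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @return `path` invisibly (write); an `eeg_recording` (read).
#' @export
write_eeg_csv <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  txt <- apply(rec$samples, 1, function(r) paste(format_num(r), collapse = ","))
  writeLines(c(paste(rec$channel_labels, collapse = ","), txt), path)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs Sampling rate in Hz of the stored samples.
#' @param condition Optional condition label to attach.
#' @export
read_eeg_csv <- function(path, fs, condition = NULL) {
  if (missing(fs)) {
    abort("`fs` is required: the CSV dialect does not store the sampling rate.")
  }
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  counts <- utils::count.fields(path, sep = ",")
  if (any(counts != length(header))) {
    bad <- which(counts != length(header))[1]
    abort(sprintf(
      "Malformed CSV: header has %d labels but line %d has %d columns.",
      length(header), bad, counts[bad]
    ))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) abort("Malformed CSV: non-numeric sample values.")
  colnames(m) <- header
  new_eeg_recording(m, fs, header, condition)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) abort(sprintf("EDF field too wide: '%s' > %d.", x, width))
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6, mode = "double")
  if (nchar(s) > width) s <- formatC(x, format = "e", digits = 1)
  edf_pad(s, width)
}

#' Write / read a recording in European Data Format (EDF)
#'
#' Minimal EDF support sufficient to round-trip synthetic recordings: all
#' channels share the sampling rate, data records last one second, and
#' samples are quantised to 16-bit integers over a symmetric physical range
#' (so amplitudes are preserved to about 1 part in 32767). The recording is
#' zero-padded to a whole number of records. The sampling rate must be a
#' positive integer.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @return `path` invisibly (write); an `eeg_recording` (read).
#' @export
write_eeg_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  fs <- rec$fs
  if (fs != round(fs) || fs < 1) {
    abort("EDF writer requires an integer sampling rate.")
  }
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  n_rec <- ceiling(n / fs)
  x <- rec$samples
  if (n_rec * fs > n) {
    x <- rbind(x, matrix(0, n_rec * fs - n, ns))
  }
  pmax_ <- max(abs(x), 1e-6)
  pm <- signif(pmax_ * 1.0001, 4)
  gain <- pm / 32767
  dig <- round(x / gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(paste("Startdate 01-JAN-2000 synthetic", rec$condition %||% ""), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  fields <- list(
    list(rec$channel_labels, 16),
    list(rep("", ns), 80),
    list(rep("uV", ns), 8),
    list(rep(edf_num(-pm), ns), 8),
    list(rep(edf_num(pm), ns), 8),
    list(rep("-32767", ns), 8),
    list(rep("32767", ns), 8),
    list(rep("", ns), 80),
    list(rep(as.character(fs), ns), 8),
    list(rep("", ns), 32)
  )
  for (f in fields) for (v in f[[1]]) wr(edf_pad(v, f[[2]]))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_eeg_edf
#' @export
read_eeg_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  rd(80)
  rd(80)
  rd(8)
  rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort("Malformed EDF: bad signal count.")
  sig_field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- sig_field(16)
  sig_field(80)
  sig_field(8)
  pmin_ <- as.numeric(sig_field(8))
  pmax_ <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8))
  dmax <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8))
  sig_field(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)) || any(dmax == dmin)) {
    abort("Malformed EDF: bad signal header fields.")
  }
  if (length(unique(spr)) != 1L) {
    abort("Only EDF files with a common sampling rate are supported.")
  }
  fs <- spr[1] / dur
  out <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = spr[1] * ns, size = 2L,
      endian = "little", signed = TRUE)
    if (length(d) < spr[1] * ns) abort("Malformed EDF: truncated data record.")
    block <- matrix(d, spr[1], ns)
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    out[rows, ] <- block
  }
  for (j in seq_len(ns)) {
    out[, j] <- pmin_[j] + (out[, j] - dmin[j]) *
      (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
  }
  colnames(out) <- labels
  new_eeg_recording(out, fs, labels, NULL)
}

#' Write a generator configuration as a flat key-value file
#'
#' Scalar fields of a [synth_config()] (and the per-condition profile rows,
#' flattened as `profile.<condition>.<band>`) are written as YAML.
#'
#' @param cfg A `synth_config`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_synth_config <- function(cfg, path) {
  if (!inherits(cfg, "synth_config")) abort("`cfg` must be a synth_config.")
  flat <- list(
    fs = cfg$fs,
    channel_labels = paste(cfg$channel_labels, collapse = ","),
    duration_s = cfg$duration_s,
    broadband_noise_rms = cfg$broadband_noise_rms,
    drift_amplitude = cfg$drift_amplitude,
    hf_artifact_rms = cfg$hf_artifact_rms,
    spatial_mixing_strength = cfg$spatial_mixing_strength
  )
  prof <- cfg$condition_profiles
  for (i in seq_len(nrow(prof))) {
    for (col in c(eeg_bands()$band, "jitter")) {
      flat[[paste("profile", prof$condition[i], col, sep = ".")]] <-
        prof[[col]][i]
    }
  }
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  flat <- yaml::read_yaml(path)
  prof <- synth_profiles()
  for (i in seq_len(nrow(prof))) {
    for (col in c(eeg_bands()$band, "jitter")) {
      key <- paste("profile", prof$condition[i], col, sep = ".")
      if (!is.null(flat[[key]])) prof[[col]][i] <- flat[[key]]
      flat[[key]] <- NULL
    }
  }
  known <- c(
    "fs", "channel_labels", "duration_s", "broadband_noise_rms",
    "drift_amplitude", "hf_artifact_rms", "spatial_mixing_strength"
  )
  unknown <- setdiff(names(flat), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  synth_config(
    fs = flat$fs,
    channel_labels = strsplit(flat$channel_labels, ",", fixed = TRUE)[[1]],
    duration_s = flat$duration_s,
    condition_profiles = prof,
    broadband_noise_rms = flat$broadband_noise_rms,
    drift_amplitude = flat$drift_amplitude,
    hf_artifact_rms = flat$hf_artifact_rms,
    spatial_mixing_strength = flat$spatial_mixing_strength
  )
}
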