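#' Singular-value spectrum of a matrix
#'
#' Computes the singular values of a real matrix in non-increasing order.
#' The squared values sum to the squared Frobenius norm of the matrix, so
#' for a sub-band matrix the spectrum is an energy-preserving summary of how
#' strongly that rhythm's activity is concentrated on a few spatial modes.
#'
#' @param M Numeric matrix with finite entries.
#' @return Numeric vector of `min(nrow, ncol)` non-negative singular values.
#' @export
#' @examples
#' singular_values(diag(c(3, 1, 2)))
singular_values <- function(M) {
  if (!is.matrix(M) || !is.numeric(M)) abort("`M` must be a numeric matrix.")
  if (!all(is.finite(M))) abort("`M` must have finite entries.")
  svd(M, nu = 0, nv = 0)$d
}

#' Names of the feature bands
#'
#' @param total Include `"total"` (all 32 features) as a pseudo-band.
#' @return Character vector.
#' @export
feature_bands <- function(total = FALSE) {
  b <- names(CLINICAL_SCALES)
  if (total) c(b, "total") else b
}

# column names delta_1..delta_k, theta_1..., alpha_1..., beta_1...
feature_names <- function(k = 8) {
  as.vector(vapply(
    feature_bands(),
    function(b) paste0(b, "_", seq_len(k)),
    character(k)
  ))
}

#' Singular-value feature vector of one frame
#'
#' Builds the sub-band matrices of a frame and concatenates the first `k`
#' singular values of the delta (`A5`), theta (`D5`), alpha (`D4`) and beta
#' (`D3`) scale matrices, in that fixed order, into a `4 * k`-dimensional
#' feature vector (32-dimensional at the default `k = 8`).
#'
#' @param frame Time-by-channel numeric matrix (e.g. 512 x 19), or a
#'   `subband_matrices` object.
#' @param k Singular values kept per band; must not exceed the channel count.
#' @param levels,wavelet Passed to [subband_matrices()].
#' @return Named numeric vector of length `4 * k` (names `delta_1`, ...,
#'   `beta_k`); each band block is non-increasing and non-negative.
#' @export
#' @examples
#' fv <- frame_features(matrix(rnorm(512 * 19), 512, 19))
#' length(fv)
frame_features <- function(frame, k = 8, levels = 5, wavelet = "db4") {
  sbm <- if (inherits(frame, "subband_matrices")) {
    frame
  } else {
    subband_matrices(frame, levels = levels, wavelet = wavelet)
  }
  limit <- min(dim(sbm[[1]]))
  if (!is.numeric(k) || k < 1 || k > limit) {
    abort(sprintf(
      "`k` must be between 1 and min(dim(frame)) = %d (got %s).",
      limit, deparse(k)
    ))
  }
  k <- as.integer(k)
  vals <- lapply(unname(CLINICAL_SCALES), function(b) {
    singular_values(sbm[[b]])[seq_len(k)]
  })
  out <- unlist(vals)
  names(out) <- feature_names(k)
  out
}

#' Feature table for a set of frames
#'
#' Maps [frame_features()] over the `frame` list-column of a segmented or
#' synthetic frame tibble, returning one row per frame.
#'
#' @param frames Tibble with a `frame` list-column (from [eeg_segment()] or
#'   [synth_frames()]); `condition` and `frame_id` columns are carried over
#'   when present.
#' @inheritParams frame_features
#' @return Tibble with `4 * k` feature columns (`delta_1` ... `beta_k`) plus
#'   any carried metadata columns.
#' @export
#' @examples
#' frames <- synth_frames(synth_config(duration_s = 8), n_per_class = 1, seed = 1)
#' feats <- eeg_features(frames)
#' names(feats)[1:4]
eeg_features <- function(frames, k = 8, levels = 5, wavelet = "db4") {
  if (!is.data.frame(frames) || !("frame" %in% names(frames))) {
    abort("`frames` must be a data frame with a `frame` list-column.")
  }
  mat <- t(vapply(
    frames$frame,
    frame_features,
    numeric(4 * k),
    k = k, levels = levels, wavelet = wavelet
  ))
  out <- tibble::as_tibble(mat)
  meta <- intersect(c("condition", "frame_id"), names(frames))
  dplyr::bind_cols(frames[meta], out)
}

#' Select one band's block of a feature vector or table
#'
#' @param x Either a feature vector from [frame_features()] or a feature
#'   table from [eeg_features()].
#' @param band One of `"delta"`, `"theta"`, `"alpha"`, `"beta"` or
#'   `"total"` (all bands).
#' @return The matching elements (vector input) or columns plus metadata
#'   (data frame input).
#' @export
#' @examples
#' fv <- frame_features(matrix(rnorm(512 * 19), 512, 19))
#' band_subset(fv, "beta")
band_subset <- function(x, band) {
  if (!is.character(band) || length(band) != 1L ||
      !(band %in% feature_bands(total = TRUE))) {
    abort(sprintf(
      "Unknown band %s; valid bands: %s.",
      deparse(band), paste(feature_bands(total = TRUE), collapse = ", ")
    ))
  }
  nm <- if (is.data.frame(x)) names(x) else names(x %||% abort("`x` unnamed"))
  keep <- if (band == "total") {
    grepl(paste0("^(", paste(feature_bands(), collapse = "|"), ")_[0-9]+$"), nm)
  } else {
    grepl(paste0("^", band, "_[0-9]+$"), nm)
  }
  if (is.data.frame(x)) {
    meta <- nm %in% c("condition", "frame_id")
    x[, meta | keep]
  } else {
    x[keep]
  }
}

#' Write a feature table to CSV
#'
#' Numeric columns are written with 9 significant digits so that repeated
#' runs with the same seed produce byte-identical files.
#'
#' @param features Tibble from [eeg_features()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- as.data.frame(features)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features_csv()]
#'
#' @param path CSV file.
#' @return Tibble with a factor `condition` column when present.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("condition" %in% names(df)) {
    df$condition <- factor(df$condition, levels = eeg_conditions())
  }
  tibble::as_tibble(df)
}
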