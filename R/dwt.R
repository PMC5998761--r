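# Daubechies-4 (db4, four vanishing moments) orthonormal filter bank.
# Analysis low-pass taps in ascending index order; the high-pass and the
# synthesis filters follow from the quadrature-mirror relations
#   dec_hi[n] = (-1)^(n+1) dec_lo[M-1-n],  rec = reversed dec.
DB4_DEC_LO <- c(
  -0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
  0.7148465705529157, 0.2303778133088965
)

dwt_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4")) {
    abort("Only the 'db4' mother wavelet is implemented.")
  }
  lo <- DB4_DEC_LO
  m <- length(lo)
  n0 <- seq_len(m) - 1L
  hi <- (-1)^(n0 + 1) * rev(lo)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), m = m)
}

# One analysis step with periodized boundary handling: decimated circular
# convolution, cA[k] = sum_m lo[m] x[(2k + M/2 - m) mod N] (0-based), which
# keeps the transform orthonormal (coefficient energy equals signal energy).
dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L) + flt$m %/% 2L
  cA <- numeric(half)
  cD <- numeric(half)
  for (m0 in 0:(flt$m - 1L)) {
    xi <- x[((base - m0) %% n) + 1L]
    cA <- cA + flt$dec_lo[m0 + 1L] * xi
    cD <- cD + flt$dec_hi[m0 + 1L] * xi
  }
  list(cA = cA, cD = cD)
}

# Inverse step: zero-upsample both branches, circular convolution with the
# synthesis filters at offset M/2 - 1, sum.
idwt_step <- function(cA, cD, flt) {
  n <- 2L * length(cA)
  uA <- numeric(n)
  uD <- numeric(n)
  uA[seq(1L, n, by = 2L)] <- cA
  uD[seq(1L, n, by = 2L)] <- cD
  base <- (seq_len(n) - 1L) + (flt$m %/% 2L - 1L)
  x <- numeric(n)
  for (m0 in 0:(flt$m - 1L)) {
    idx <- ((base - m0) %% n) + 1L
    x <- x + flt$rec_lo[m0 + 1L] * uA[idx] + flt$rec_hi[m0 + 1L] * uD[idx]
  }
  x
}

#' Multi-level discrete wavelet decomposition of one channel
#'
#' Decomposes a single-channel signal with the orthonormal db4 filter bank
#' and periodized boundary extension. Periodization halves the coefficient
#' count exactly at every level (512 samples at 5 levels give detail vectors
#' of length 256, 128, 64, 32, 16 plus a 16-sample approximation) and
#' preserves signal energy in the coefficients.
#'
#' @param x Numeric vector; its length must be divisible by `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @param wavelet Mother wavelet name; only `"db4"` is supported.
#' @return An object of class `dwt_coeffs`: list with `cA` (approximation at
#'   the deepest level) and `cD` (list of detail vectors, level 1 first),
#'   plus `levels`, `wavelet`, `n` and `extension_mode = "periodization"`.
#' @export
#' @examples
#' co <- dwt_decompose(sin(2 * pi * 12 * (0:511) / 256))
#' lengths(co$cD)
dwt_decompose <- function(x, levels = 5, wavelet = "db4") {
  x <- as.numeric(x)
  if (!all(is.finite(x))) abort("Signal must be finite.")
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be >= 1.")
  max_lev <- 0L
  n <- length(x)
  while (n %% 2L == 0L && n >= 2L) {
    max_lev <- max_lev + 1L
    n <- n %/% 2L
  }
  if (levels > max_lev) {
    abort(sprintf(
      "Signal of length %d supports at most %d periodized levels (requested %d).",
      length(x), max_lev, levels
    ))
  }
  flt <- dwt_filters(wavelet)
  cD <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(cur, flt)
    cD[[l]] <- st$cD
    cur <- st$cA
  }
  structure(
    list(
      cA = cur, cD = cD, levels = levels, wavelet = wavelet,
      n = length(x), extension_mode = "periodization"
    ),
    class = "dwt_coeffs"
  )
}

#' @export
print.dwt_coeffs <- function(x, ...) {
  cat(sprintf(
    "<dwt_coeffs> %s, %d levels, %d samples; |cA%d| = %d, |cD| = %s\n",
    x$wavelet, x$levels, x$n, x$levels, length(x$cA),
    paste(lengths(x$cD), collapse = "/")
  ))
  invisible(x)
}

#' Names of the wavelet sub-bands
#'
#' @param levels Decomposition depth.
#' @return Character vector `A<levels>, D<levels>, ..., D1`.
#' @export
subband_names <- function(levels = 5) {
  c(paste0("A", levels), paste0("D", seq(levels, 1)))
}

#' Reconstruct the time-domain signal of a single sub-band
#'
#' Inverts the wavelet transform with every coefficient vector zeroed except
#' the requested band, giving that band's additive contribution to the
#' signal: the sub-band signals of all bands sum to the original signal
#' exactly (orthonormal perfect-reconstruction filter bank).
#'
#' @param coeffs A [dwt_decompose()] result.
#' @param band One of `subband_names(coeffs$levels)`, e.g. `"A5"` or `"D3"`.
#' @return Numeric vector with the original signal length.
#' @export
#' @examples
#' x <- sin(2 * pi * 12 * (0:511) / 256)
#' co <- dwt_decompose(x)
#' alpha <- dwt_reconstruct(co, "D4") # 8-16 Hz content at fs = 256
dwt_reconstruct <- function(coeffs, band) {
  if (!inherits(coeffs, "dwt_coeffs")) {
    abort("`coeffs` must come from dwt_decompose().")
  }
  valid <- subband_names(coeffs$levels)
  if (!is.character(band) || length(band) != 1L || !(band %in% valid)) {
    abort(sprintf(
      "Unknown band %s; valid bands: %s.",
      deparse(band), paste(valid, collapse = ", ")
    ))
  }
  flt <- dwt_filters(coeffs$wavelet)
  keep_a <- band == valid[1]
  det_level <- if (keep_a) 0L else as.integer(sub("^D", "", band))
  cur <- if (keep_a) coeffs$cA else numeric(length(coeffs$cA))
  for (l in seq(coeffs$levels, 1L)) {
    cd <- if (l == det_level) coeffs$cD[[l]] else numeric(length(coeffs$cD[[l]]))
    cur <- idwt_step(cur, cd, flt)
  }
  cur
}

#' Nominal frequency range of a dyadic sub-band
#'
#' For a sampling rate `fs` and decomposition level `l`, detail band `Dl`
#' nominally spans `(fs / 2^(l+1), fs / 2^l)` Hz and the approximation `AL`
#' spans `(0, fs / 2^(L+1))`. At fs = 256 with 5 levels this gives the
#' familiar 0-4 (A5), 4-8 (D5), 8-16 (D4), 16-32 (D3), 32-64 (D2) and
#' 64-128 Hz (D1) ranges.
#'
#' @param band Sub-band name, e.g. `"A5"`, `"D4"`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector `c(low, high)` in Hz.
#' @export
#' @examples
#' band_range("D4", 256) # alpha-scale: 8-16 Hz
band_range <- function(band, fs) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!is.character(band) || length(band) != 1L ||
      !grepl("^[AD][0-9]+$", band)) {
    abort(sprintf("Unknown band %s; expected e.g. 'A5', 'D4'.", deparse(band)))
  }
  lev <- as.integer(sub("^[AD]", "", band))
  if (lev < 1L) abort("Band level must be >= 1.")
  if (startsWith(band, "A")) {
    c(0, fs / 2^(lev + 1))
  } else {
    c(fs / 2^(lev + 1), fs / 2^lev)
  }
}

# Mapping from the four feature-bearing dyadic scales to clinical rhythms.
CLINICAL_SCALES <- c(delta = "A5", theta = "D5", alpha = "D4", beta = "D3")

#' Sub-band matrices of a multichannel frame
#'
#' Decomposes every channel of a frame with [dwt_decompose()], reconstructs
#' each scale's sub-band signal with [dwt_reconstruct()], and stacks the
#' channels as columns, one time-by-channel matrix per scale. With 5 levels
#' this yields six matrices (`A5`, `D5`, ..., `D1`) that sum element-wise to
#' the input frame. The `A5`, `D5`, `D4` and `D3` matrices carry the delta,
#' theta, alpha and beta rhythm content respectively and are the ones used
#' for feature extraction; `D2` and `D1` are computed for completeness.
#'
#' @param frame Numeric matrix, time by channels (e.g. 512 x 19); the row
#'   count must be divisible by `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @param wavelet Mother wavelet (only `"db4"`).
#' @return Object of class `subband_matrices`: named list of matrices, each
#'   the shape of `frame`.
#' @export
#' @examples
#' frame <- matrix(rnorm(512 * 4), 512, 4)
#' sbm <- subband_matrices(frame)
#' names(sbm)
#' max(abs(frame - Reduce(`+`, sbm))) # perfect reconstruction
subband_matrices <- function(frame, levels = 5, wavelet = "db4") {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort("`frame` must be a numeric time-by-channel matrix.")
  }
  bands <- subband_names(levels)
  out <- lapply(bands, function(b) frame * 0)
  names(out) <- bands
  for (p in seq_len(ncol(frame))) {
    co <- dwt_decompose(frame[, p], levels = levels, wavelet = wavelet)
    for (b in bands) out[[b]][, p] <- dwt_reconstruct(co, b)
  }
  structure(out, class = "subband_matrices", levels = levels, wavelet = wavelet)
}

#' @export
print.subband_matrices <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf(
    "<subband_matrices> %s; each %d x %d\n",
    paste(names(x), collapse = ", "), d[1], d[2]
  ))
  invisible(x)
}
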