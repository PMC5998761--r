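# Shared fixtures, built in code at test time.

# Small, fast generator configuration (full 19-channel montage, short session).
quick_cfg <- function(duration_s = 8, ...) {
  synth_config(duration_s = duration_s, ...)
}

# Strongly separated class profiles: adjacent class amplitudes differ by
# 4 uV per band while the within-class spread (2% amplitude jitter plus
# residual nuisance noise) stays well under a fifth of that gap.
separated_profiles <- function() {
  tibble::tibble(
    condition = eeg_conditions(),
    delta = c(4, 8, 12, 16, 20),
    theta = c(20, 16, 12, 8, 4),
    alpha = c(4, 12, 20, 8, 16),
    beta  = c(12, 4, 16, 20, 8),
    jitter = 0.02
  )
}

separated_cfg <- function(duration_s = 8) {
  synth_config(
    duration_s = duration_s,
    condition_profiles = separated_profiles(),
    broadband_noise_rms = 1,
    drift_amplitude = 2,
    hf_artifact_rms = 0.5
  )
}

# Fraction of a signal's periodogram power inside [lo, hi] Hz (FFT oracle,
# independent of the package's filtering code).
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & f >= lo & f <= hi
  sum(p[inband]) / sum(p[half])
}

# Amplitude of a sinusoid at frequency f0 in x, by least-squares projection
# onto sin/cos over the central half of the signal (robust to edge effects).
projected_amplitude <- function(x, fs, f0) {
  n <- length(x)
  mid <- seq(n %/% 4, 3 * n %/% 4)
  t <- (mid - 1) / fs
  a <- 2 * mean(x[mid] * sin(2 * pi * f0 * t))
  b <- 2 * mean(x[mid] * cos(2 * pi * f0 * t))
  sqrt(a^2 + b^2)
}

# Five well-separated Gaussian blobs in feature space (class-mean spacing
# 10x the within-class deviation), for classifier-only tests.
gaussian_blobs <- function(n_per_class = 50, dim = 32, spacing = 10,
                           sd = 1, seed = 1) {
  classes <- eeg_conditions()
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(classes), function(i) {
    mu <- rep(0, dim)
    mu[i] <- spacing * sd
    matrix(stats::rnorm(n_per_class * dim, sd = sd), n_per_class, dim) +
      matrix(mu, n_per_class, dim, byrow = TRUE)
  }))
  list(
    x = X,
    y = factor(rep(classes, each = n_per_class), levels = classes)
  )
}
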