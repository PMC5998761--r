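# Frozen single-level oracle: coefficients computed independently with a
# reference periodized db4 implementation (PyWavelets 1.9, mode
# "periodization") on a deterministic ramp-plus-sine signal.
pywt_x <- c(
  0, 1.0238795325112868, 0.90710678118654764, -0.082683432365089626,
  -0.59999999999999998, 0.11731656763490961, 1.3071067811865476,
  1.6238795325112867, 0.80000000000000038, -0.023879532511286383,
  0.29289321881345154, 1.4826834323650897, 2.2000000000000002,
  1.6826834323650908, 0.69289321881345245, 0.57612046748871315
)
pywt_cA <- c(
  1.0865434656347754, 0.74025264966913218, 0.91223899917716378,
  -0.69345941437976943, 2.0024356333003799, 0.76124813264282243,
  0.80329854964590397, 2.8727233585481624
)
pywt_cD <- c(
  -0.54465564842707914, 0.35871022446923667, -0.00683884949402103,
  -0.36599447361987442, 0.5244331978408503, -0.3756660673253473,
  0.37544335078825541, 0.60025369071721857
)

test_that("one analysis level reproduces the reference coefficients exactly", {
  co <- dwt_decompose(pywt_x, levels = 1)
  expect_equal(co$cD[[1]], pywt_cD, tolerance = 1e-14)
  expect_equal(co$cA, pywt_cA, tolerance = 1e-14)
})

test_that("coefficient lengths follow the halving cascade", {
  co <- dwt_decompose(rnorm(512), levels = 5)
  expect_equal(lengths(co$cD), c(256L, 128L, 64L, 32L, 16L))
  expect_equal(length(co$cA), 16L)
  expect_identical(co$extension_mode, "periodization")
})

test_that("the transform is orthonormal: coefficient energy = signal energy", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(512)
    x <- x / sqrt(sum(x^2))
    co <- dwt_decompose(x)
    expect_equal(sum(co$cA^2) + sum(unlist(co$cD)^2), 1, tolerance = 1e-6)
  }
})

test_that("zero signals give zero coefficients and zero sub-bands", {
  co <- dwt_decompose(numeric(512))
  expect_true(all(co$cA == 0) && all(unlist(co$cD) == 0))
  expect_true(all(dwt_reconstruct(co, "A5") == 0))
  expect_true(all(dwt_reconstruct(co, "D2") == 0))
})

test_that("requesting too many levels names the feasible maximum", {
  expect_error(dwt_decompose(rnorm(96), levels = 6), "at most 5")
  expect_silent(dwt_decompose(rnorm(96), levels = 5))
})

test_that("sub-band signals sum to the original signal (perfect reconstruction)", {
  set.seed(9)
  x <- rnorm(512)
  co <- dwt_decompose(x)
  total <- Reduce(`+`, lapply(subband_names(5), function(b) {
    dwt_reconstruct(co, b)
  }))
  expect_lt(max(abs(total - x)) / max(abs(x)), 1e-8)
  expect_error(dwt_reconstruct(co, "D9"), "valid bands")
})

test_that("a 12 Hz sinusoid concentrates in the D4 (8-16 Hz) sub-band", {
  x <- sin(2 * pi * 12 * (0:511) / 256)
  co <- dwt_decompose(x)
  e <- vapply(subband_names(5), function(b) {
    sum(dwt_reconstruct(co, b)^2)
  }, numeric(1))
  expect_gt(e[["D4"]] / sum(e), 0.8)
})

test_that("sinusoids at each band's centre select their own sub-band", {
  fs <- 256
  for (b in c("D5", "D4", "D3", "D2")) {
    rng <- band_range(b, fs)
    f0 <- mean(rng)
    x <- sin(2 * pi * f0 * (0:511) / fs)
    co <- dwt_decompose(x)
    e <- vapply(subband_names(5), function(bb) {
      sum(dwt_reconstruct(co, bb)^2)
    }, numeric(1))
    expect_gt(e[[b]] / sum(e), 0.8)
  }
})

test_that("dyadic band ranges match the 256 Hz table", {
  expect_equal(band_range("A5", 256), c(0, 4))
  expect_equal(band_range("D5", 256), c(4, 8))
  expect_equal(band_range("D4", 256), c(8, 16))
  expect_equal(band_range("D3", 256), c(16, 32))
  expect_equal(band_range("D2", 256), c(32, 64))
  expect_equal(band_range("D1", 256), c(64, 128))
  expect_error(band_range("E2", 256), "Unknown band")
})

test_that("six sub-band matrices share the frame's shape and sum to it", {
  set.seed(10)
  frame <- matrix(rnorm(512 * 19), 512, 19)
  sbm <- subband_matrices(frame)
  expect_named(sbm, c("A5", "D5", "D4", "D3", "D2", "D1"))
  expect_true(all(vapply(sbm, function(m) all(dim(m) == c(512, 19)), logical(1))))
  total <- Reduce(`+`, sbm)
  expect_lt(max(abs(total - frame)) / max(abs(frame)), 1e-8)

  zero <- subband_matrices(matrix(0, 512, 4))
  expect_true(all(vapply(zero, function(m) all(m == 0), logical(1))))
})

test_that("each sub-band column depends only on its own channel", {
  set.seed(11)
  frame <- matrix(rnorm(512 * 4), 512, 4)
  sbm1 <- subband_matrices(frame)
  frame2 <- frame
  frame2[, 2] <- frame2[, 2] + rnorm(512)
  sbm2 <- subband_matrices(frame2)
  for (b in subband_names(5)) {
    expect_identical(sbm1[[b]][, c(1, 3, 4)], sbm2[[b]][, c(1, 3, 4)])
    expect_false(identical(sbm1[[b]][, 2], sbm2[[b]][, 2]))
  }
})

test_that("only db4 is offered and short frames are rejected", {
  expect_error(dwt_decompose(rnorm(512), wavelet = "sym5"), "db4")
  expect_error(subband_matrices(matrix(rnorm(16 * 3), 16, 3)), "at most 4")
})
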