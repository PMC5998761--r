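test_that("activations match their definitions", {
  expect_equal(activate("sigmoid", 0), 0.5)
  expect_equal(activate("sine", 0), 0)
  expect_equal(activate("radbas", 0), 1)
  u <- seq(-3, 3, by = 0.5)
  expect_equal(activate("sigmoid", u), 1 / (1 + exp(-u)))
  expect_equal(activate("sine", u), sin(u))
  expect_equal(activate("radbas", u), exp(-u^2))
  expect_error(activate("tanh", 0), "sigmoid, sine, radbas")
})

test_that("one-hot class codes follow the reversed-bit convention", {
  blobs <- gaussian_blobs(n_per_class = 10)
  fit <- elm_train(blobs$x, blobs$y, h = 20, seed = 1)
  expect_identical(
    unname(fit$label_codes),
    c("00001", "00010", "00100", "01000", "10000")
  )
  expect_identical(names(fit$label_codes), eeg_conditions())
})

test_that("training is deterministic and shapes are consistent", {
  blobs <- gaussian_blobs(n_per_class = 10)
  f1 <- elm_train(blobs$x, blobs$y, h = 30, C = 2, seed = 42)
  f2 <- elm_train(blobs$x, blobs$y, h = 30, C = 2, seed = 42)
  expect_identical(f1, f2)
  expect_equal(dim(f1$input_weights), c(30, 32))
  expect_length(f1$biases, 30)
  expect_equal(dim(f1$output_weights), c(30, 5))
  f3 <- elm_train(blobs$x, blobs$y, h = 30, C = 2, seed = 43)
  expect_false(identical(f1$input_weights, f3$input_weights))
})

test_that("well-separated blobs are classified perfectly in training", {
  for (seed in 1:10) {
    blobs <- gaussian_blobs(n_per_class = 50, spacing = 10, seed = seed)
    fit <- elm_train(blobs$x, blobs$y,
      h = 200, C = 100,
      activation = "radbas", seed = seed
    )
    expect_equal(unname(fit$train_accuracy), 1)
    expect_identical(predict(fit, blobs$x), blobs$y)
  }
})

test_that("output weights match an independent augmented least-squares solve", {
  set.seed(7)
  for (i in 1:5) {
    n <- 40
    m <- 6
    h <- 15
    C <- 3
    X <- matrix(rnorm(n * m), n, m)
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    fit <- elm_train(X, y, h = h, C = C, activation = "sigmoid", seed = i)
    # recompute H exactly as the model defines it
    Xs <- sweep(sweep(X, 2, fit$scaling$min), 2, fit$scaling$range, "/")
    H <- activate(
      "sigmoid",
      tcrossprod(Xs, fit$input_weights) +
        matrix(fit$biases, n, h, byrow = TRUE)
    )
    q <- length(fit$classes)
    Y <- eegsvd:::one_hot(match(as.character(y), fit$classes), q)
    # independent route: ridge as stacked least squares solved by QR
    B_oracle <- qr.solve(
      rbind(H, diag(1 / sqrt(C), h)),
      rbind(Y, matrix(0, h, q))
    )
    expect_equal(fit$output_weights, B_oracle, tolerance = 1e-6)
  }
})

test_that("weak regularization with h >= n interpolates the training set", {
  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 4), n, 4)
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- elm_train(X, y, h = 60, C = 1e8, activation = "radbas", seed = 3)
  Xs <- sweep(sweep(X, 2, fit$scaling$min), 2, fit$scaling$range, "/")
  H <- activate(
    "radbas",
    tcrossprod(Xs, fit$input_weights) + matrix(fit$biases, n, 60, byrow = TRUE)
  )
  Y <- eegsvd:::one_hot(match(as.character(y), fit$classes), 2)
  expect_lt(max(abs(H %*% fit$output_weights - Y)), 1e-3)
  expect_equal(unname(fit$train_accuracy), 1)
})

test_that("permuting training instances leaves the solution unchanged", {
  blobs <- gaussian_blobs(n_per_class = 8)
  fit <- elm_train(blobs$x, blobs$y, h = 25, seed = 5)
  set.seed(6)
  perm <- sample(nrow(blobs$x))
  fit_p <- elm_train(blobs$x[perm, ], blobs$y[perm], h = 25, seed = 5)
  expect_equal(fit$output_weights, fit_p$output_weights, tolerance = 1e-8)
})

test_that("ties break toward the lowest class index", {
  blobs <- gaussian_blobs(n_per_class = 5)
  fit <- elm_train(blobs$x, blobs$y, h = 10, seed = 1)
  # force an all-equal output row: zero output weights
  fit$output_weights[] <- 0
  pred <- predict(fit, blobs$x[1:3, , drop = FALSE])
  expect_identical(as.character(pred), rep("silent", 3))
  single <- predict(fit, blobs$x[1, , drop = FALSE])
  expect_length(single, 1)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(elm_train(X, rep("a", 10)), "2 distinct classes")
  expect_error(elm_train(X, rep(c("a", "b"), 5), h = 0), ">= 1")
  expect_error(elm_train(X, rep(c("a", "b"), 5), C = -1), "positive")
  fit <- elm_train(X, rep(c("a", "b"), 5), h = 5, seed = 1)
  expect_error(predict(fit, matrix(0, 2, 3)), "expects 2 features")
})

test_that("models round-trip bit-exactly through the text serialization", {
  blobs <- gaussian_blobs(n_per_class = 6)
  fit <- elm_train(blobs$x, blobs$y, h = 12, C = 0.7, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  elm_save(fit, path)
  back <- elm_load(path)
  expect_identical(back$input_weights, fit$input_weights)
  expect_identical(back$output_weights, fit$output_weights)
  expect_identical(back$biases, fit$biases)
  expect_identical(back$scaling, fit$scaling)
  expect_identical(back$C, fit$C)
  expect_identical(predict(back, blobs$x), predict(fit, blobs$x))
})

test_that("tidy and glance summarise a fitted model", {
  blobs <- gaussian_blobs(n_per_class = 6)
  fit <- elm_train(blobs$x, blobs$y, h = 12, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("class", "code", "output_neuron", "weight_norm"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$h, 12)
  expect_equal(gl$n_classes, 5)
})
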