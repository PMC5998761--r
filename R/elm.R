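#' Activation functions available to the ELM hidden layer
#'
#' @return Character vector: `"sigmoid"`, `"sine"`, `"radbas"`.
#' @export
elm_activations <- function() c("sigmoid", "sine", "radbas")

#' Apply an ELM activation element-wise
#'
#' `sigmoid(u) = 1 / (1 + exp(-u))`, `sine(u) = sin(u)`, and the radial
#' basis function `radbas(u) = exp(-u^2)`.
#'
#' @param name One of [elm_activations()].
#' @param u Numeric vector, matrix or array.
#' @return Same shape as `u`.
#' @export
#' @examples
#' activate("radbas", 0)
activate <- function(name, u) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% elm_activations())) {
    abort(sprintf(
      "Unknown activation %s; available: %s.",
      deparse(name), paste(elm_activations(), collapse = ", ")
    ))
  }
  switch(name,
    sigmoid = 1 / (1 + exp(-u)),
    sine = sin(u),
    radbas = exp(-u^2)
  )
}

# One-hot target codes: with q classes, class i is coded by a q-bit string
# with a single 1 at position q - i + 1 (class 1 = 0...01, class q = 10...0).
class_codes <- function(q) {
  vapply(seq_len(q), function(i) {
    bits <- rep("0", q)
    bits[q - i + 1L] <- "1"
    paste(bits, collapse = "")
  }, character(1))
}

one_hot <- function(idx, q) {
  Y <- matrix(0, length(idx), q)
  Y[cbind(seq_along(idx), q - idx + 1L)] <- 1
  Y
}

resolve_classes <- function(y) {
  if (is.factor(y)) {
    cl <- levels(y)[levels(y) %in% unique(as.character(y))]
  } else {
    y <- as.character(y)
    cl <- unique(y)
    if (all(cl %in% eeg_conditions())) {
      cl <- eeg_conditions()[eeg_conditions() %in% cl]
    } else {
      cl <- sort(cl)
    }
  }
  cl
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, !(names(x) %in% c("condition", "frame_id")), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("Features must be a numeric matrix or data frame.")
  }
  x
}

#' Train an extreme learning machine classifier
#'
#' Single-hidden-layer feedforward network: the hidden weights and biases are
#' drawn once from a seeded uniform distribution on `[-1, 1]` and never
#' updated; the output weights are the ridge solution of `min ||H B - Y||^2
#' + (1/C) ||B||^2`, i.e. `B = (H'H + I/C)^{-1} H'Y`, where `H` is the
#' activated hidden matrix and `Y` the 0/1 one-hot target matrix. Features
#' are min-max scaled to `[0, 1]` using statistics of the training data only.
#'
#' @param x Feature matrix or data frame (metadata columns `condition` and
#'   `frame_id` are dropped automatically).
#' @param y Class labels (factor or character), at least two distinct.
#' @param h Hidden-neuron count (default 100).
#' @param C Ridge regularization constant (> 0; larger is weaker, default 1).
#' @param activation One of [elm_activations()] (default `"radbas"`).
#' @param seed Seed for the random hidden layer.
#' @return An object of class `eeg_elm`.
#' @export
#' @examples
#' x <- matrix(rnorm(60 * 4), 60, 4)
#' y <- rep(c("a", "b", "c"), each = 20)
#' x[y == "b", 1] <- x[y == "b", 1] + 5
#' x[y == "c", 2] <- x[y == "c", 2] + 5
#' fit <- elm_train(x, y, h = 50, seed = 1)
#' mean(predict(fit, x) == y)
elm_train <- function(x, y, h = 100, C = 1, activation = "radbas", seed = 1) {
  X <- as_feature_matrix(x)
  if (length(y) != nrow(X)) abort("`y` must have one label per row of `x`.")
  if (!is.numeric(h) || length(h) != 1L || h < 1) abort("`h` must be >= 1.")
  stopifnot_scalar_number(C, "C", positive = TRUE)
  activate(activation, 0) # validates the name
  classes <- resolve_classes(y)
  q <- length(classes)
  if (q < 2L) abort("Training requires at least 2 distinct classes.")
  idx <- match(as.character(y), classes)
  if (anyNA(idx)) abort("Labels outside the factor levels of `y`.")

  m <- ncol(X)
  h <- as.integer(h)
  xmin <- apply(X, 2, min)
  xrange <- apply(X, 2, max) - xmin
  xrange[xrange == 0] <- 1
  Xs <- sweep(sweep(X, 2, xmin), 2, xrange, "/")

  wb <- with_seed(seed, runif(h * (m + 1L), -1, 1))
  W <- matrix(wb[seq_len(h * m)], h, m)
  b <- wb[h * m + seq_len(h)]

  H <- activate(activation, tcrossprod(Xs, W) + matrix(b, nrow(Xs), h, byrow = TRUE))
  Y <- one_hot(idx, q)
  B <- solve(crossprod(H) + diag(1 / C, h), crossprod(H, Y))

  model <- structure(
    list(
      input_weights = W, biases = b, output_weights = B,
      activation = activation, C = C, h = h,
      classes = classes, label_codes = stats::setNames(class_codes(q), classes),
      scaling = list(min = xmin, range = xrange),
      feature_names = colnames(X), m = m, seed = as.integer(seed)
    ),
    class = "eeg_elm"
  )
  model$train_accuracy <- mean(predict(model, X) == classes[idx])
  model
}

#' @export
print.eeg_elm <- function(x, ...) {
  cat(sprintf(
    "<eeg_elm> %d hidden neurons (%s), C = %g, %d features -> %d classes\n",
    x$h, x$activation, x$C, x$m, length(x$classes)
  ))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict class labels with a trained ELM
#'
#' Applies the stored min-max scaling, the random hidden projection, and the
#' solved output weights; the predicted class is the one whose output neuron
#' is maximal, with ties broken toward the lowest class index (so an
#' all-equal output row yields the first class).
#'
#' @param object An `eeg_elm` model.
#' @param newdata Feature matrix or data frame with `object$m` features.
#' @param type `"class"` (default) for a factor of labels, `"score"` for the
#'   raw output-neuron matrix (one column per class, class order).
#' @param ... Unused.
#' @return Factor of length `nrow(newdata)`, or a score matrix.
#' @export
predict.eeg_elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$m) {
    abort(sprintf(
      "Feature dimension mismatch: model expects %d features, got %d.",
      object$m, ncol(X)
    ))
  }
  Xs <- sweep(sweep(X, 2, object$scaling$min), 2, object$scaling$range, "/")
  H <- activate(
    object$activation,
    tcrossprod(Xs, object$input_weights) +
      matrix(object$biases, nrow(Xs), object$h, byrow = TRUE)
  )
  scores <- H %*% object$output_weights
  q <- length(object$classes)
  # column q - i + 1 holds class i; reorder so column i = class i
  by_class <- scores[, q:1, drop = FALSE]
  colnames(by_class) <- object$classes
  if (type == "score") return(by_class)
  idx <- max.col(by_class, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}

#' @rdname elm_save
#' @export
elm_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(s) as.numeric(s)
  model <- structure(
    list(
      input_weights = matrix(num(obj$input_weights), obj$h, obj$m),
      biases = num(obj$biases),
      output_weights = matrix(num(obj$output_weights), obj$h,
        length(obj$classes)),
      activation = obj$activation, C = num(obj$C), h = as.integer(obj$h),
      classes = obj$classes,
      label_codes = stats::setNames(class_codes(length(obj$classes)),
        obj$classes),
      scaling = list(min = num(obj$scaling_min), range = num(obj$scaling_range)),
      feature_names = obj$feature_names,
      m = as.integer(obj$m), seed = as.integer(obj$seed)
    ),
    class = "eeg_elm"
  )
  model$train_accuracy <- num(obj$train_accuracy)
  model
}

#' Save / load an ELM model as a portable text file
#'
#' The model (hidden weights, output weights, scaling parameters, metadata)
#' is written as JSON with doubles encoded at 17 significant digits, which
#' round-trips IEEE doubles exactly: `elm_load(elm_save(m, f))` reproduces
#' `m` bit for bit.
#'
#' @param model An `eeg_elm`.
#' @param path File path.
#' @return `path` (save) or the restored `eeg_elm` (load).
#' @export
elm_save <- function(model, path) {
  if (!inherits(model, "eeg_elm")) abort("`model` must be an eeg_elm.")
  enc <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(
    format = "eegsvd-elm-1",
    h = model$h, m = model$m,
    activation = model$activation, C = enc(model$C),
    classes = model$classes,
    feature_names = model$feature_names,
    input_weights = enc(model$input_weights),
    biases = enc(model$biases),
    output_weights = enc(model$output_weights),
    scaling_min = enc(model$scaling$min),
    scaling_range = enc(model$scaling$range),
    seed = model$seed,
    train_accuracy = enc(model$train_accuracy)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.eeg_elm <- function(x, ...) {
  B <- x$output_weights
  q <- length(x$classes)
  tibble::tibble(
    class = x$classes,
    code = unname(x$label_codes),
    output_neuron = q:1,
    weight_norm = vapply(q:1, function(j) sqrt(sum(B[, j]^2)), numeric(1))
  )
}

#' @exportS3Method generics::glance
glance.eeg_elm <- function(x, ...) {
  tibble::tibble(
    h = x$h, C = x$C, activation = x$activation,
    n_features = x$m, n_classes = length(x$classes),
    train_accuracy = x$train_accuracy
  )
}
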