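#' Confusion matrix of actual versus predicted labels
#'
#' Rows are actual classes, columns predicted classes, entry `[i, j]` the
#' number of instances of class `i` predicted as class `j`.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param classes Class order; defaults to the factor levels of `actual`
#'   (or the canonical condition order when labels are conditions).
#' @return Integer matrix of class `conf_mat` with dimnames.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.")
  }
  classes <- classes %||% resolve_classes(actual)
  a <- as.character(actual)
  p <- as.character(predicted)
  bad <- setdiff(unique(c(a, p)), classes)
  if (length(bad)) {
    abort(sprintf(
      "Unknown label(s): %s (classes: %s).",
      paste(bad, collapse = ", "), paste(classes, collapse = ", ")
    ))
  }
  cm <- table(
    factor(a, levels = classes),
    factor(p, levels = classes)
  )
  out <- matrix(as.integer(cm), length(classes), length(classes),
    dimnames = list(actual = classes, predicted = classes)
  )
  structure(out, class = c("conf_mat", "matrix"))
}

#' @export
print.conf_mat <- function(x, ...) {
  cat("<conf_mat> actual x predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class sensitivity from a confusion matrix
#'
#' The sensitivity of class `i` is the diagonal count over its row total,
#' `SE_i = a_ii / sum_j a_ij * 100` (percent). A class with no evaluated
#' instances has undefined sensitivity and raises an error rather than
#' silently reporting 0.
#'
#' @param cm A confusion matrix ([confusion_matrix()] or a plain square
#'   matrix with dimnames).
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' cm <- confusion_matrix(rep(c("a", "b"), c(10, 10)),
#'   rep(c("a", "b", "b"), c(8, 2, 10)),
#'   classes = c("a", "b")
#' )
#' sensitivities(cm) # a: 80, b: 100
sensitivities <- function(cm) {
  cm <- as_cm(cm)
  totals <- rowSums(cm)
  if (any(totals == 0)) {
    abort(sprintf(
      "Sensitivity undefined: no instances of class(es) %s.",
      paste(rownames(cm)[totals == 0], collapse = ", ")
    ))
  }
  100 * diag(cm) / totals
}

#' @rdname sensitivities
#' @param class Class name or index.
#' @export
sensitivity <- function(cm, class) {
  se <- sensitivities(as_cm(cm))
  if (is.numeric(class)) {
    if (class < 1 || class > length(se)) abort("Class index out of range.")
    unname(se[class])
  } else {
    if (!(class %in% names(se))) {
      abort(sprintf("Unknown class %s.", deparse(class)))
    }
    unname(se[class])
  }
}

as_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    abort("`cm` must be a square confusion matrix.")
  }
  if (any(cm < 0)) abort("Confusion counts must be >= 0.")
  cm
}

#' Overall accuracy: the macro-average of per-class sensitivities
#'
#' `OA = mean(SE_i)` over the classes. Note this is the unweighted macro
#' average, not the pooled fraction of correct predictions; the two differ
#' whenever row totals are unbalanced.
#'
#' @inheritParams sensitivities
#' @return A percentage.
#' @export
overall_accuracy <- function(cm) {
  mean(sensitivities(cm))
}

# Stratified, seeded fold assignment: within each class, instances are
# shuffled and dealt round-robin so per-class fold sizes differ by <= 1.
make_folds <- function(y, folds, seed) {
  y <- as.character(y)
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        abort(sprintf(
          "Class '%s' has %d instances, fewer than %d folds.",
          cl, length(idx), folds
        ))
      }
      idx <- sample(idx)
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the ELM classifier
#'
#' Assigns frames to `folds` stratified, seeded folds; trains an ELM on the
#' remaining folds and predicts the held-out fold, so each instance is tested
#' exactly once. Per-fold confusion matrices are summed into a pooled matrix
#' from which per-class sensitivities and the overall accuracy are computed.
#'
#' @param features Feature table from [eeg_features()] (or any data frame of
#'   numeric features plus a label column).
#' @param band Feature subset to use: `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"` or `"total"` (default).
#' @param folds Number of folds (default 5); every class needs at least
#'   `folds` instances.
#' @param h,C,activation,seed ELM hyper-parameters; see [elm_train()]. `seed`
#'   also fixes the fold assignment.
#' @param classes Optional subset of class labels to keep (e.g.
#'   `c("music", "anc_noise_music")` for a two-class contrast); default all.
#' @param label_col Name of the label column (default `"condition"`).
#' @return Object of class `elm_cv`: pooled and per-fold confusion matrices,
#'   per-class sensitivities (`se`, percent), overall accuracy (`oa`), and
#'   the configuration used.
#' @export
#' @examples
#' frames <- synth_frames(synth_config(duration_s = 24), n_per_class = 10, seed = 1)
#' cv <- elm_cross_validate(eeg_features(frames), band = "alpha", seed = 1)
#' cv$oa
elm_cross_validate <- function(features, band = "total", folds = 5, h = 100,
                               C = 1, activation = "radbas", seed = 1,
                               classes = NULL, label_col = "condition") {
  if (!is.data.frame(features) || !(label_col %in% names(features))) {
    abort(sprintf("`features` must contain a '%s' column.", label_col))
  }
  if (!is.numeric(folds) || folds < 2) abort("`folds` must be >= 2.")
  folds <- as.integer(folds)
  y_all <- features[[label_col]]
  classes <- classes %||% resolve_classes(y_all)
  keep <- as.character(y_all) %in% classes
  features <- features[keep, , drop = FALSE]
  y <- factor(as.character(y_all[keep]), levels = classes)

  sub <- band_subset(
    features[, setdiff(names(features), c(label_col, "frame_id")),
      drop = FALSE
    ],
    band
  )
  X <- as_feature_matrix(sub)
  fold_of <- make_folds(y, folds, seed = derive_seed(seed, 1L))

  fold_cms <- lapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    model <- elm_train(X[tr, , drop = FALSE], y[tr],
      h = h, C = C,
      activation = activation, seed = derive_seed(seed, 10L + f)
    )
    pred <- predict(model, X[!tr, , drop = FALSE])
    confusion_matrix(y[!tr], pred, classes = classes)
  })
  pooled <- Reduce(`+`, lapply(fold_cms, unclass))
  pooled <- structure(pooled, class = c("conf_mat", "matrix"))
  se <- sensitivities(pooled)
  structure(
    list(
      fold_confusions = fold_cms,
      confusion = pooled,
      se = se,
      oa = mean(se),
      config = list(
        band = band, folds = folds, h = h, C = C,
        activation = activation, seed = seed, classes = classes,
        n = nrow(X), fold_assignment = fold_of
      )
    ),
    class = "elm_cv"
  )
}

#' @export
print.elm_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<elm_cv> %d-fold CV, band = %s, activation = %s, h = %d, C = %g\n",
    cfg$folds, cfg$band, cfg$activation, cfg$h, cfg$C
  ))
  cat(sprintf("overall accuracy: %.2f%%\n", x$oa))
  print(round(x$se, 2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.elm_cv <- function(x, ...) {
  tibble::tibble(
    class = names(x$se),
    sensitivity = unname(x$se),
    n = unname(rowSums(x$confusion))
  )
}

#' @exportS3Method generics::glance
glance.elm_cv <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    oa = x$oa, folds = cfg$folds, band = cfg$band,
    activation = cfg$activation, h = cfg$h, C = cfg$C,
    n = cfg$n, seed = cfg$seed
  )
}

#' Plot a cross-validated confusion matrix
#'
#' @param object An `elm_cv` result.
#' @param ... Unused.
#' @return A ggplot tile plot of row-normalised confusion percentages.
#' @exportS3Method ggplot2::autoplot
autoplot.elm_cv <- function(object, ...) {
  cm <- unclass(object$confusion)
  df <- tibble::tibble(
    actual = factor(rep(rownames(cm), ncol(cm)), levels = rev(rownames(cm))),
    predicted = factor(rep(colnames(cm), each = nrow(cm)),
      levels = colnames(cm)
    ),
    pct = 100 * as.vector(cm / rowSums(cm)),
    count = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$actual)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pct)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue",
      limits = c(0, 100), name = "% of row"
    ) +
    ggplot2::labs(
      x = "predicted", y = "actual",
      title = sprintf("overall accuracy %.2f%%", object$oa)
    )
}

#' One-way ANOVA F test for a single feature across classes
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test): `F = (SSB / (g - 1)) / (SSW / (n - g))` with the p-value from the
#' F distribution on `(g - 1, n - g)` degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, at least two groups of at least two values.
#' @return List with elements `statistic` (F) and `p.value`.
#' @export
#' @examples
#' anova_f(c(0, 1, 2, 3), c("a", "a", "b", "b")) # F = 8
anova_f <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.")
  }
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes < 2L)) abort("Every group needs at least 2 values.")
  within_var <- tapply(values, g, stats::var)
  if (all(within_var == 0)) {
    abort("Degenerate input: zero within-group variance in every group.")
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value))
}

#' ANOVA screening of every feature column
#'
#' Applies [anova_f()] to each feature column of a feature table, testing
#' whether its mean differs between listening conditions.
#'
#' @param features Feature table from [eeg_features()].
#' @param label_col Label column name (default `"condition"`).
#' @return Tibble of class `eeg_anova` with columns `feature`, `band`,
#'   `statistic` and `p.value`, one row per feature, in feature order.
#' @export
anova_screen <- function(features, label_col = "condition") {
  if (!is.data.frame(features) || !(label_col %in% names(features))) {
    abort(sprintf("`features` must contain a '%s' column.", label_col))
  }
  cols <- setdiff(names(features), c(label_col, "frame_id"))
  res <- purrr::map_dfr(cols, function(cn) {
    ft <- anova_f(features[[cn]], features[[label_col]])
    tibble::tibble(
      feature = cn,
      band = sub("_[0-9]+$", "", cn),
      statistic = ft$statistic,
      p.value = ft$p.value
    )
  })
  class(res) <- c("eeg_anova", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.eeg_anova <- function(object, ...) {
  df <- object
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$statistic,
    colour = .data$band
  )) +
    ggplot2::geom_point() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "ANOVA F statistic")
}

#' Per-class mean and standard deviation of every feature
#'
#' @param features Feature table from [eeg_features()].
#' @param label_col Label column name (default `"condition"`).
#' @return Tibble with columns `condition`, `feature`, `mean`, `sd`, ordered
#'   by class then feature.
#' @export
class_summary <- function(features, label_col = "condition") {
  if (!is.data.frame(features) || !(label_col %in% names(features))) {
    abort(sprintf("`features` must contain a '%s' column.", label_col))
  }
  cols <- setdiff(names(features), c(label_col, "frame_id"))
  long <- tidyr::pivot_longer(
    features[, c(label_col, cols)],
    dplyr::all_of(cols),
    names_to = "feature", values_to = "value"
  )
  long$feature <- factor(long$feature, levels = cols)
  out <- dplyr::summarise(
    dplyr::group_by(
      long,
      condition = factor(.data[[label_col]]), .data$feature
    ),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
  )
  dplyr::arrange(out, .data$condition, .data$feature)
}

#' Sensitivity/accuracy table over band subsets and activations
#'
#' Runs [elm_cross_validate()] for every combination of feature subset
#' (delta, theta, alpha, beta, total) and activation (sine, sigmoid, radbas),
#' collecting per-class sensitivities and overall accuracy into one table --
#' the standard layout for reporting this pipeline's performance.
#'
#' @inheritParams elm_cross_validate
#' @param bands Band subsets to evaluate.
#' @param activations Activations to evaluate.
#' @return Tibble with one row per band x activation and columns for each
#'   class sensitivity plus `oa`.
#' @export
results_table <- function(features, bands = feature_bands(total = TRUE),
                          activations = c("sine", "sigmoid", "radbas"),
                          folds = 5, h = 100, C = 1, seed = 1,
                          classes = NULL, label_col = "condition") {
  grid <- tidyr::expand_grid(band = bands, activation = activations)
  purrr::pmap_dfr(grid, function(band, activation) {
    cv <- elm_cross_validate(features,
      band = band, folds = folds, h = h,
      C = C, activation = activation, seed = seed, classes = classes,
      label_col = label_col
    )
    dplyr::bind_cols(
      tibble::tibble(band = band, activation = activation),
      tibble::as_tibble(as.list(cv$se)),
      tibble::tibble(oa = cv$oa)
    )
  })
}
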