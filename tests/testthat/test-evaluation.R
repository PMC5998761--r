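test_that("confusion matrix counts actual-by-predicted instances", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
    classes = c("a", "b")
  )
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
    dimnames = list(actual = c("a", "b"), predicted = c("a", "b"))
  ), ignore_attr = "class")
  expect_equal(sum(cm), 3)

  all_right <- confusion_matrix(rep(eeg_conditions(), 3), rep(eeg_conditions(), 3))
  expect_true(all(all_right[upper.tri(all_right) | lower.tri(all_right)] == 0))
  expect_equal(unname(diag(all_right)), rep(3L, 5))

  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(
    confusion_matrix("a", "z", classes = c("a", "b")),
    "Unknown label"
  )
})

test_that("per-class sensitivity follows the row-wise diagonal fraction", {
  cm <- matrix(0L, 5, 5, dimnames = list(
    actual = eeg_conditions(),
    predicted = eeg_conditions()
  ))
  cm[1, ] <- c(7L, 0L, 0L, 0L, 0L)
  cm[2, ] <- c(2L, 8L, 0L, 0L, 0L)
  cm[3, ] <- rep(2L, 5)
  cm[4, ] <- c(0L, 0L, 0L, 5L, 0L)
  cm[5, ] <- c(0L, 0L, 0L, 0L, 4L)
  expect_equal(sensitivity(cm, 1), 100)
  expect_equal(sensitivity(cm, 2), 80)
  expect_equal(sensitivity(cm, 3), 20)
  expect_equal(sensitivity(cm, "noise"), 80)

  cm0 <- cm
  cm0[4, ] <- 0L
  expect_error(sensitivities(cm0), "anc_noise")
})

test_that("overall accuracy is the macro-average of sensitivities", {
  cm <- diag(c(10L, 10L, 10L, 10L, 10L))
  dimnames(cm) <- list(actual = eeg_conditions(), predicted = eeg_conditions())
  expect_equal(overall_accuracy(cm), 100)

  # SEs 80, 60, 100, 40, 20 -> OA 60
  cm2 <- matrix(0L, 5, 5, dimnames = dimnames(cm))
  diag(cm2) <- c(8L, 6L, 10L, 4L, 2L)
  cm2[, 3] <- cm2[, 3] + c(2L, 4L, 0L, 6L, 8L)
  expect_equal(unname(sensitivities(cm2)), c(80, 60, 100, 40, 20))
  expect_equal(overall_accuracy(cm2), 60)

  # macro vs pooled: unbalanced rows where the two disagree
  cm3 <- matrix(c(90L, 10L, 5L, 5L), 2, 2, byrow = TRUE,
    dimnames = list(actual = c("a", "b"), predicted = c("a", "b"))
  )
  pooled_fraction <- 100 * sum(diag(cm3)) / sum(cm3)
  expect_equal(overall_accuracy(cm3), 70)
  expect_false(isTRUE(all.equal(overall_accuracy(cm3), pooled_fraction)))
})

test_that("stratified folds partition every class evenly", {
  frames <- synth_frames(quick_cfg(duration_s = 6), n_per_class = 3, seed = 4)
  feats <- eeg_features(frames)
  cv <- elm_cross_validate(feats, folds = 3, h = 20, seed = 5)
  fold_of <- cv$config$fold_assignment
  expect_length(fold_of, 15)
  expect_true(all(fold_of %in% 1:3))
  # every instance tested exactly once: pooled total equals dataset size
  expect_equal(sum(cv$confusion), 15)
  expect_equal(Reduce(`+`, lapply(cv$fold_confusions, sum)), 15)
  # per-class fold sizes differ by <= 1
  tab <- table(feats$condition, fold_of)
  expect_lte(max(tab) - min(tab), 1)
  # pooled matrix is the element-wise sum of fold matrices
  expect_equal(
    unclass(cv$confusion),
    Reduce(`+`, lapply(cv$fold_confusions, unclass))
  )
  # OA equals the mean of the five sensitivities
  expect_equal(cv$oa, mean(cv$se), tolerance = 1e-10)
  expect_error(elm_cross_validate(feats, folds = 4), "fewer than 4 folds")
})

test_that("two-class contrast runs on a subset of conditions", {
  frames <- synth_frames(separated_cfg(), n_per_class = 10, seed = 6)
  feats <- eeg_features(frames)
  cv <- elm_cross_validate(feats,
    classes = c("music", "anc_noise_music"),
    folds = 5, seed = 6
  )
  expect_equal(dim(cv$confusion), c(2, 2))
  expect_equal(sum(cv$confusion), 20)
  expect_named(cv$se, c("music", "anc_noise_music"))
  expect_equal(cv$oa, mean(cv$se))
})

test_that("ANOVA F matches hand computation and the t-test equivalence", {
  res <- anova_f(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(res$statistic, 8, tolerance = 1e-10)

  expect_equal(anova_f(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$statistic, 0)

  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(30)
    g <- rep(c("a", "b"), 15)
    res <- anova_f(x, g)
    tt <- stats::t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$p.value, tt$p.value, tolerance = 1e-8)
  }

  expect_error(anova_f(c(1, 1, 2, 2), c("a", "a", "a", "a")), "2 groups")
  expect_error(anova_f(c(1, 2, 3), c("a", "a", "b")), "at least 2 values")
  expect_error(anova_f(rep(1, 6), rep(c("a", "b"), 3)), "Degenerate")
})

test_that("feature screening flags class-dependent features", {
  frames <- synth_frames(separated_cfg(), n_per_class = 10, seed = 7)
  feats <- eeg_features(frames)
  scr <- anova_screen(feats)
  expect_equal(nrow(scr), 32)
  expect_true(all(scr$statistic >= 0))
  expect_true(all(scr$p.value >= 0 & scr$p.value <= 1))
  expect_lt(scr$p.value[scr$feature == "alpha_1"], 0.001)
})

test_that("class summaries report per-class means and standard deviations", {
  feats <- tibble::tibble(
    condition = rep(c("silent", "noise"), each = 2),
    alpha_1 = c(2, 4, 10, 10)
  )
  cs <- class_summary(feats)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$mean[cs$condition == "silent"], 3)
  expect_equal(cs$sd[cs$condition == "silent"], sqrt(2))
  expect_equal(cs$sd[cs$condition == "noise"], 0)

  frames <- synth_frames(quick_cfg(duration_s = 4), n_per_class = 2, seed = 8)
  full <- class_summary(eeg_features(frames))
  expect_equal(nrow(full), 5 * 32)
  expect_identical(
    as.character(full$condition[1:32]),
    rep("silent", 32)
  )
})

test_that("tidy, glance and autoplot work on CV results", {
  frames <- synth_frames(quick_cfg(duration_s = 4), n_per_class = 2, seed = 9)
  cv <- elm_cross_validate(eeg_features(frames), folds = 2, h = 15, seed = 1)
  td <- tidy(cv)
  expect_named(td, c("class", "sensitivity", "n"))
  expect_equal(nrow(td), 5)
  gl <- glance(cv)
  expect_equal(gl$folds, 2)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("accuracy recovers monotonically as class profiles separate", {
  oa <- vapply(c(0, 1, 2.5), function(sep) {
    cfg <- synth_config(
      duration_s = 32,
      condition_profiles = synth_profiles(separation = sep)
    )
    frames <- synth_frames(cfg, n_per_class = 15, seed = 31)
    elm_cross_validate(eeg_features(frames), folds = 5, seed = 31)$oa
  }, numeric(1))
  expect_true(all(diff(oa) >= 0))
  expect_gt(oa[3], oa[1] + 20) # the gap is the dominant driver
})
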