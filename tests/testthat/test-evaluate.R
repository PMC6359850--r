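test_that("confusion counts match an exhaustive pairwise oracle", {
  cm <- confusion(c("LR", "LR", "PO"), c("LR", "PO", "PO"))
  expect_equal(cm["LR", "LR"], 1L)
  expect_equal(cm["LR", "PO"], 1L)
  expect_equal(cm["PO", "PO"], 1L)
  expect_equal(sum(cm), 3L)

  withr::with_seed(10, {
    truth <- sample(gait_phases(), 100, replace = TRUE)
    pred <- sample(gait_phases(), 100, replace = TRUE)
  })
  cm <- confusion(truth, pred)
  for (i in gait_phases()) {
    for (j in gait_phases()) {
      oracle <- 0L
      for (k in 1:100) if (truth[k] == i && pred[k] == j) oracle <- oracle + 1L
      expect_equal(cm[i, j], oracle)
    }
  }
  expect_error(confusion(c("LR"), c("LR", "PO")), "equal lengths")
})

test_that("perfect predictions give a diagonal matrix and all metrics 1", {
  truth <- rep(gait_phases(), times = c(30, 30, 13, 27))
  m <- per_class_metrics(confusion(truth, truth))
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$sensitivity == 1))
  expect_true(all(m$per_class$mcc == 1))
  expect_equal(sum(unclass(m$confusion)) - sum(diag(unclass(m$confusion))), 0)
})

test_that("binary metrics match the scalar arithmetic oracle", {
  cm <- structure(matrix(c(8L, 1L, 2L, 9L), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))
  ), class = c("gait_confusion", "matrix"))
  m <- per_class_metrics(cm)
  a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(a$sensitivity, 0.8)
  expect_equal(a$specificity, 0.9)
  expect_equal(a$precision, 8 / 9)
  expect_equal(a$f_score, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(a$mcc, (8 * 9 - 1 * 2) / sqrt(9 * 10 * 11 * 10))
  expect_equal(a$mcc, 0.7035265, tolerance = 1e-6)
  expect_equal(m$accuracy, 17 / 20)
})

test_that("per-class metrics match loop oracles on random confusion matrices", {
  withr::with_seed(21, {
    for (rep_ in 1:20) {
      cm <- matrix(rpois(16, 20), 4, 4, dimnames = list(gait_phases(), gait_phases()))
      m <- per_class_metrics(structure(cm, class = c("gait_confusion", "matrix")))
      total <- sum(cm)
      for (i in 1:4) {
        tp <- cm[i, i]
        fn <- sum(cm[i, ]) - tp
        fp <- sum(cm[, i]) - tp
        tn <- total - tp - fn - fp
        expect_equal(tp + tn + fp + fn, total)
        expect_equal(m$per_class$sensitivity[i], tp / (tp + fn))
        expect_equal(m$per_class$specificity[i], tn / (tn + fp))
        expect_equal(m$per_class$precision[i], tp / (tp + fp))
        expect_equal(
          m$per_class$mcc[i],
          (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
        )
      }
      expect_equal(m$accuracy, sum(diag(cm)) / total)
      # weighted averages: direct formula, invariant to class reordering,
      # bounded by the per-class extremes
      I <- rowSums(cm)
      expect_equal(
        unname(m$weighted["sensitivity"]),
        sum(m$per_class$sensitivity * I) / sum(I)
      )
      expect_gte(m$weighted["mcc"], min(m$per_class$mcc))
      expect_lte(m$weighted["mcc"], max(m$per_class$mcc))
      perm <- sample(4)
      m_perm <- per_class_metrics(structure(cm[perm, perm],
        class = c("gait_confusion", "matrix")
      ))
      expect_equal(m_perm$weighted, m$weighted)
    }
  })
})

test_that("zero-denominator metrics are reported as 0 and flagged", {
  # class PO never predicted and never true -> undefined precision/sensitivity
  cm <- confusion(rep(c("LR", "Swing"), 10), rep(c("LR", "Swing"), 10),
    class_order = c("LR", "PO", "Swing")
  )
  m <- per_class_metrics(cm)
  po <- m$per_class[m$per_class$class == "PO", ]
  expect_equal(po$precision, 0)
  expect_equal(po$sensitivity, 0)
  expect_true(po$undefined)
  expect_false(any(m$per_class$undefined[m$per_class$class != "PO"]))
})

test_that("weighted_average implements the instance-weighted mean", {
  expect_equal(weighted_average(c(0.9, 0.5), c(90, 10)), 0.86)
  expect_equal(weighted_average(c(0.4, 0.8), c(10, 10)), 0.6)
  expect_equal(weighted_average(rep(0.7, 4), c(5, 1, 9, 2)), 0.7)
  expect_error(weighted_average(c(1, 1), c(0, 0)), "positive")
  expect_error(weighted_average(1, c(1, 2)), "equal lengths")
})

test_that("MCC tends to zero for random predictions on a large sample", {
  withr::with_seed(77, {
    truth <- sample(gait_phases(), 20000, replace = TRUE)
    pred <- sample(gait_phases(), 20000, replace = TRUE)
  })
  m <- per_class_metrics(confusion(truth, pred))
  expect_lt(max(abs(m$per_class$mcc)), 0.05)
})

test_that("stratified folds are balanced per class, partition the data, and are seeded", {
  labels <- rep(gait_phases(), times = c(25, 25, 25, 25))
  f <- stratified_kfold(labels, k = 5, seed = 1)
  tab <- table(labels, f)
  expect_true(all(tab == 5))
  expect_equal(sort(unique(f)), 1:5)
  expect_length(f, 100)
  expect_identical(stratified_kfold(labels, k = 5, seed = 1), f)

  # uneven classes still differ by at most one per fold and per class
  labels2 <- rep(gait_phases(), times = c(23, 17, 11, 9))
  f2 <- stratified_kfold(labels2, k = 5, seed = 2)
  tab2 <- table(labels2, f2)
  expect_true(all(apply(tab2, 1, function(r) diff(range(r)) <= 1)))
  expect_error(stratified_kfold(c("LR", "LR", "PO"), k = 2), "at least k")
})

test_that("pooled cross-validation covers every instance and TSVC repairs corrupted streams", {
  d <- small_cohort_features(seed = 30, surfaces = c("LG", "US"), speeds = 1.33, n_strides = 2)
  cv <- crossval_report(d, k = 3,
    control = lmt_control(num_boosting_iterations = 5, prune = FALSE, seed = 1),
    seed = 4
  )
  expect_equal(cv$lmt$n, nrow(d))
  expect_equal(cv$lmt_tsvc$n, nrow(d))
  expect_false(anyNA(cv$predictions$pred))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 8) # 2 conditions x 4 classes
  expect_equal(nrow(glance(cv)), 2)

  # a prediction stream already satisfying the cyclic order is untouched
  clean <- make_phase_stream(4)
  expect_identical(tsvc_correct(clean), clean)

  # 1% isolated outliers: TSVC-corrected accuracy beats raw accuracy
  truth <- make_phase_stream(10)
  cor_ <- corrupt_isolated(truth, n_outliers = ceiling(length(truth) / 100), seed = 3)
  raw_acc <- mean(cor_$stream == truth)
  fixed_acc <- mean(tsvc_correct(cor_$stream) == truth)
  expect_lt(raw_acc, 1)
  expect_gt(fixed_acc, raw_acc)
  expect_equal(fixed_acc, 1)
})

test_that("resubstitution reporting trains once on everything", {
  d <- small_cohort_features(seed = 31, surfaces = "LG", speeds = 1.33, n_strides = 2)
  cv <- crossval_report(d, control = lmt_control(num_boosting_iterations = 5, prune = FALSE, seed = 1),
    report = "resubstitution", with_tsvc = FALSE
  )
  expect_gte(cv$lmt$accuracy, 0.9)
  expect_null(cv$lmt_tsvc)
})

test_that("metrics exports write condition x class x metric rows plus the confusion matrix", {
  d <- small_cohort_features(seed = 32, surfaces = "LG", speeds = 1.33, n_strides = 2)
  cv <- crossval_report(d, k = 3,
    control = lmt_control(num_boosting_iterations = 3, prune = FALSE, seed = 1), seed = 2
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(cv, path)
  long <- utils::read.csv(path)
  expect_equal(nrow(long), 2 * 4 * 5)
  cmfile <- sub("\\.csv$", "_confusion.csv", path)
  expect_true(file.exists(cmfile))
  cm <- utils::read.csv(cmfile)
  expect_equal(nrow(cm), 4)
})
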