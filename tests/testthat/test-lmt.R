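test_that("single-class data collapses to a single leaf predicting that class", {
  d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20), label = rep("Swing", 20))
  m <- train_lmt(d, features = c("x1", "x2"))
  expect_equal(m$tree_size, 1L)
  expect_equal(m$n_leaves, 1L)
  p <- leaf_probabilities(m, c(0, 0))
  expect_equal(unname(p), 1)
  expect_identical(as.character(predict_phase(m, c(5, -5))), "Swing")
})

test_that("a one-threshold separable toy set is split on that feature with perfect training accuracy", {
  d <- make_separable_toy()
  # independent exhaustive oracle: best information-gain split over all
  # midpoints of both features
  ent <- function(y) {
    p <- table(y) / length(y)
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  best <- list(gain = -Inf, feature = NA, thr = NA)
  for (fx in c("x1", "x2")) {
    v <- sort(unique(d[[fx]]))
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      left <- d$label[d[[fx]] <= thr]
      right <- d$label[d[[fx]] > thr]
      gain <- ent(d$label) -
        length(left) / nrow(d) * ent(left) -
        length(right) / nrow(d) * ent(right)
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = fx, thr = thr)
    }
  }
  expect_identical(best$feature, "x1")

  m <- train_lmt(d, features = c("x1", "x2"),
    control = lmt_control(min_instances = 10, prune = FALSE, seed = 1)
  )
  expect_identical(m$feature_names[m$root$feature], "x1")
  expect_equal(m$root$threshold, best$thr)
  pred <- predict(m, d)
  expect_equal(mean(pred == d$label), 1.0)
  # oracle threshold rule agrees with the model on every training point
  rule <- factor(ifelse(d$x1 <= best$thr, "LR", "PO"), levels = c("LR", "PO"))
  expect_identical(as.character(pred), as.character(rule))
})

test_that("the C++ split search agrees with an independent recursive partitioner on the toy set", {
  d <- make_separable_toy(n_per_class = 40, gap = 3, seed = 9)
  sp <- gaitphase:::.best_split_cpp(as.matrix(d[c("x1", "x2")]), as.integer(d$label), 2L)
  fit <- rpart::rpart(label ~ x1 + x2, data = d,
    control = rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2)
  )
  expect_equal(as.character(fit$frame$var[1]), c("x1", "x2")[sp$feature])
  expect_equal(unname(fit$splits[1, "index"]), sp$threshold, tolerance = 1e-8)
})

test_that("with splitting disabled the model is one LogitBoost fit with a monotone objective", {
  d <- small_cohort_features(seed = 6, surfaces = "LG", speeds = 1.33, n_strides = 2)
  m <- train_lmt(d, control = lmt_control(
    min_instances = nrow(d) + 1,
    num_boosting_iterations = 25, prune = FALSE
  ))
  expect_equal(m$n_leaves, 1L)
  fit <- gaitphase:::fit_logitboost(
    as.matrix(d[gait_feature_names()]), droplevels(d$label), n_iter = 25
  )
  expect_true(all(diff(fit$nll_path) <= 1e-9))
  expect_equal(fit$gamma, m$root$gamma)
})

test_that("leaf probabilities are a softmax: strictly positive, sum to 1, symmetric at zero", {
  d <- small_cohort_features(seed = 7, surfaces = "LG", speeds = 1.33, n_strides = 2)
  m <- train_lmt(d, control = lmt_control(num_boosting_iterations = 10, prune = FALSE, seed = 1))
  withr::with_seed(2, {
    for (i in 1:50) {
      x <- rnorm(20, sd = 10)
      p <- leaf_probabilities(m, x)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_true(all(p > 0))
    }
  })
  # all-zero coefficients give uniform probabilities over the 4 phases
  m0 <- m
  zero_leaf <- gaitphase:::.lmt_leaf(
    10L, 0L, matrix(0, 21, 4, dimnames = list(NULL, m$class_order)), 0L, NULL
  )
  m0$root <- zero_leaf
  expect_equal(unname(leaf_probabilities(m0, rep(0, 20))), rep(0.25, 4))
  expect_identical(as.character(predict_phase(m0, rep(0, 20))), m$class_order[1])
  expect_error(leaf_probabilities(m, c(rep(0, 19), NA)), "finite")
})

test_that("the binary logistic form and the softmax normalization agree by direct arithmetic", {
  # binary sigmoid at gamma = 0 is exactly 0.5
  expect_equal(exp(0) / (1 + exp(0)), 0.5)
  withr::with_seed(31, {
    for (i in 1:20) {
      gam <- matrix(rnorm(6), 3, 2) # 2 features + intercept, 2 classes
      x <- rnorm(2)
      s <- as.numeric(t(gam) %*% c(1, x))
      p_impl <- gaitphase:::.lb_softmax(matrix(s, 1, 2))[1, ]
      # scalar re-computation: softmax of a 2-vector equals the sigmoid of
      # the score difference
      p_oracle <- c(
        exp(s[1] - s[2]) / (1 + exp(s[1] - s[2])),
        1 / (1 + exp(s[1] - s[2]))
      )
      expect_equal(unname(p_impl), p_oracle, tolerance = 1e-12)
    }
  })
})

test_that("accepted splits have positive gain and children partition the parent", {
  d <- small_cohort_features(seed = 12, surfaces = c("LG", "US"), speeds = 1.33, n_strides = 2)
  m <- train_lmt(d, control = lmt_control(num_boosting_iterations = 5, prune = FALSE, seed = 1))
  check <- function(node) {
    if (node$type == "split") {
      expect_gt(node$gain, 0)
      expect_equal(node$left$n + node$right$n, node$n)
      check(node$left)
      check(node$right)
    }
  }
  check(m$root)
  expect_lte(m$n_leaves, m$tree_size)
})

test_that("cost-complexity pruning keeps the cross-validated error within one SE of the unpruned tree", {
  d <- small_cohort_features(seed = 20, surfaces = c("LG", "DS"), speeds = c(1.33, 0.6), n_strides = 2)
  m <- train_lmt(d, control = lmt_control(num_boosting_iterations = 5, prune = TRUE, seed = 3))
  pr <- m$pruning
  expect_false(is.null(pr))
  expect_equal(pr$alpha[1], 0) # the unpruned tree is always a candidate
  # the selected pruning strength honors the 1-SE contract against both the
  # CV-minimal tree and the unpruned tree
  expect_lte(pr$cv_error[pr$chosen], min(pr$cv_error) + pr$se + 1e-12)
  expect_lte(pr$cv_error[pr$chosen], pr$cv_error[1] + pr$se + 1e-12)
  # pruning never grows the tree
  m_full <- train_lmt(d, control = lmt_control(num_boosting_iterations = 5, prune = FALSE, seed = 3))
  expect_lte(m$n_leaves, m_full$n_leaves)
  expect_lte(m$tree_size, m_full$tree_size)
})

test_that("serialization round-trips models losslessly for prediction", {
  d <- make_separable_toy(n_per_class = 40, seed = 15)
  m <- train_lmt(d, features = c("x1", "x2"),
    control = lmt_control(min_instances = 10, prune = FALSE, seed = 1)
  )
  txt <- serialize_lmt(m)
  m2 <- deserialize_lmt(txt)
  expect_equal(m2$tree_size, m$tree_size)
  expect_equal(m2$n_leaves, m$n_leaves)
  expect_identical(m2$class_order, m$class_order)
  withr::with_seed(8, X <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("x1", "x2"))))
  expect_identical(predict(m, X), predict(m2, X))
  expect_equal(predict(m, X, type = "prob"), predict(m2, X, type = "prob"), tolerance = 1e-12)

  # file round-trip
  path <- withr::local_tempfile(fileext = ".json")
  serialize_lmt(m, path)
  m3 <- deserialize_lmt(path)
  expect_identical(predict(m, X), predict(m3, X))

  # degenerate documents fail loudly
  expect_error(deserialize_lmt(""), "empty")
  expect_error(deserialize_lmt("{\"schema\": \"other\"}"), "parse error")
  expect_error(deserialize_lmt("{not json"), "parse error")

  # single-leaf model round-trips and predicts its constant class
  d1 <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10), label = rep("TSw", 10))
  s1 <- serialize_lmt(train_lmt(d1, features = c("x1", "x2")))
  expect_identical(as.character(predict_phase(deserialize_lmt(s1), c(1, 2))), "TSw")
})

test_that("training rejects degenerate inputs", {
  expect_error(train_lmt(tibble::tibble(x = 1, label = character(0))), "label|instances")
  d <- tibble::tibble(x = c(1, NA), label = c("LR", "PO"))
  expect_error(train_lmt(d, features = "x"), "finite")
  expect_error(
    train_lmt(tibble::tibble(x = 1:5, label = rep(NA_character_, 5)), features = "x"),
    "no labeled instances"
  )
})
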