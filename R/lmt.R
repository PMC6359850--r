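#' Training configuration for the Logistic Model Tree
#'
#' @param min_instances Minimum number of instances a node must hold to be
#'   considered for splitting (default 15, the standard LMT default).
#' @param num_boosting_iterations Fixed LogitBoost iteration count, or -1
#'   (default) to select it automatically by internal cross-validation.
#' @param fast_regression When `TRUE` (default) the iteration count is chosen
#'   once at the root and reused (as warm-started additional iterations) at
#'   every node; when `FALSE` it is re-selected by cross-validation at each
#'   node, which is substantially slower.
#' @param max_boost_iter Upper bound of the automatic iteration search.
#' @param cv_folds Folds of the internal iteration-selection
#'   cross-validation.
#' @param prune Apply CART-style cost-complexity pruning selected by
#'   cross-validated error with the 1-SE rule (default `TRUE`).
#' @param prune_folds Folds of the pruning cross-validation.
#' @param max_depth Hard depth cap (safety bound; default 30).
#' @param seed Seed controlling only the internal cross-validation fold
#'   assignments; induction is otherwise deterministic given the data.
#' @return An `lmt_control` list.
#' @export
lmt_control <- function(min_instances = 15,
                        num_boosting_iterations = -1,
                        fast_regression = TRUE,
                        max_boost_iter = 200,
                        cv_folds = 5,
                        prune = TRUE,
                        prune_folds = 5,
                        max_depth = 30,
                        seed = NULL) {
  if (min_instances < 2) abort("`min_instances` must be >= 2")
  if (max_boost_iter < 1) abort("`max_boost_iter` must be >= 1")
  structure(
    list(
      min_instances = as.integer(min_instances),
      num_boosting_iterations = as.integer(num_boosting_iterations),
      fast_regression = isTRUE(fast_regression),
      max_boost_iter = as.integer(max_boost_iter),
      cv_folds = as.integer(cv_folds),
      prune = isTRUE(prune),
      prune_folds = as.integer(prune_folds),
      max_depth = as.integer(max_depth),
      seed = seed
    ),
    class = "lmt_control"
  )
}

# ---- internal tree machinery -------------------------------------------

.lmt_leaf <- function(n, err, gamma, depth, class_counts) {
  list(
    type = "leaf", n = n, err = err, gamma = gamma, depth = depth,
    class_counts = class_counts
  )
}

.lmt_node_error <- function(X_node, y_node, gamma) {
  P <- .lb_softmax(.lb_scores(X_node, gamma))
  sum(max.col(P, ties.method = "first") != as.integer(y_node))
}

.lmt_grow <- function(X, yi, y, idx, gamma_parent, depth, control, n_iter, seed) {
  Xn <- X[idx, , drop = FALSE]
  yn <- y[idx]
  n <- length(idx)
  J <- nlevels(y)

  iter_here <- n_iter
  if (!control$fast_regression && control$num_boosting_iterations < 0) {
    iter_here <- .lb_choose_iter(Xn, yn, control$max_boost_iter,
      folds = control$cv_folds, seed = seed, gamma_init = gamma_parent
    )
  }
  fit <- fit_logitboost(Xn, yn, n_iter = iter_here, gamma_init = gamma_parent)
  gamma <- fit$gamma
  err <- .lmt_node_error(Xn, yn, gamma)
  counts <- tabulate(yi[idx], nbins = J)

  pure <- length(unique(yi[idx])) == 1
  if (n < control$min_instances || pure || depth >= control$max_depth) {
    return(.lmt_leaf(n, err, gamma, depth, counts))
  }
  sp <- .best_split_cpp(Xn, yi[idx], J)
  if (sp$feature < 0 || sp$gain <= 1e-12) {
    return(.lmt_leaf(n, err, gamma, depth, counts))
  }
  go_left <- Xn[, sp$feature] <= sp$threshold
  left_idx <- idx[go_left]
  right_idx <- idx[!go_left]
  list(
    type = "split", n = n, err = err, gamma = gamma, depth = depth,
    class_counts = counts,
    feature = sp$feature, threshold = sp$threshold, gain = sp$gain,
    left = .lmt_grow(X, yi, y, left_idx, gamma, depth + 1, control, n_iter, seed),
    right = .lmt_grow(X, yi, y, right_idx, gamma, depth + 1, control, n_iter, seed)
  )
}

.lmt_count <- function(node) {
  if (node$type == "leaf") {
    c(size = 1L, leaves = 1L)
  } else {
    l <- .lmt_count(node$left)
    r <- .lmt_count(node$right)
    c(size = 1L + unname(l["size"]) + unname(r["size"]),
      leaves = unname(l["leaves"]) + unname(r["leaves"]))
  }
}

# single post-order pass: subtree leaf-error count, leaf count, and the
# smallest weakest-link value g(t). `n_total` is the number of training
# instances of the tree, so g is an error *rate* per saved leaf and is
# comparable across trees grown on different amounts of data.
.lmt_annotate <- function(node, n_total) {
  if (node$type == "leaf") {
    return(list(err = node$err, leaves = 1, min_g = Inf))
  }
  l <- .lmt_annotate(node$left, n_total)
  r <- .lmt_annotate(node$right, n_total)
  err <- l$err + r$err
  leaves <- l$leaves + r$leaves
  g <- (node$err - err) / n_total / (leaves - 1)
  list(err = err, leaves = leaves, min_g = min(g, l$min_g, r$min_g))
}

# collapse (bottom-up, single pass) every internal node whose weakest-link
# value is <= alpha; returns list(node, err, leaves)
.lmt_prune_alpha_ <- function(node, alpha, n_total) {
  if (node$type == "leaf") {
    return(list(node = node, err = node$err, leaves = 1))
  }
  l <- .lmt_prune_alpha_(node$left, alpha, n_total)
  r <- .lmt_prune_alpha_(node$right, alpha, n_total)
  node$left <- l$node
  node$right <- r$node
  err <- l$err + r$err
  leaves <- l$leaves + r$leaves
  g <- (node$err - err) / n_total / (leaves - 1)
  if (g <= alpha + 1e-12) {
    leaf <- .lmt_leaf(node$n, node$err, node$gamma, node$depth, node$class_counts)
    return(list(node = leaf, err = node$err, leaves = 1))
  }
  list(node = node, err = err, leaves = leaves)
}

.lmt_prune_alpha <- function(node, alpha, n_total) {
  .lmt_prune_alpha_(node, alpha, n_total)$node
}

# full weakest-link alpha sequence (error-rate scale)
.lmt_alpha_sequence <- function(root, n_total) {
  alphas <- numeric(0)
  tree <- root
  repeat {
    ann <- .lmt_annotate(tree, n_total)
    if (!is.finite(ann$min_g)) break
    alphas <- c(alphas, ann$min_g)
    tree <- .lmt_prune_alpha(tree, ann$min_g, n_total)
  }
  unique(alphas)
}

# probability matrix for many rows, routing recursively
.lmt_predict_probs <- function(node, X, idx, P) {
  if (length(idx) == 0) return(P)
  if (node$type == "leaf") {
    P[idx, ] <- .lb_softmax(.lb_scores(X[idx, , drop = FALSE], node$gamma))
    return(P)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  P <- .lmt_predict_probs(node$left, X, idx[go_left], P)
  .lmt_predict_probs(node$right, X, idx[!go_left], P)
}

# ---- user-facing training ----------------------------------------------

.lmt_feature_cols <- function(data, label, features) {
  if (!is.null(features)) return(features)
  std <- intersect(gait_feature_names(), names(data))
  if (length(std) == 20) return(std)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, c(label, "end_index", "time"))
}

#' Train a Logistic Model Tree
#'
#' Grows a binary decision tree by the C4.5-style criterion of maximum
#' information gain on the class variable (candidate thresholds at midpoints
#' between consecutive distinct sorted feature values), fits an additive
#' logistic model at every node by LogitBoost with simple-linear-regression
#' base learners (each child warm-started from its parent's model), and
#' prunes by CART cost-complexity pruning with the iteration count and
#' pruning strength chosen by internal stratified cross-validation.
#' Splitting stops when a node holds fewer than `min_instances` instances,
#' is pure, or admits no positive-gain split.
#'
#' @param data Data frame with one row per instance: a label column plus
#'   numeric feature columns.
#' @param label Name of the label column (default `"label"`).
#' @param features Character vector of feature column names; defaults to the
#'   20 gait features when present, otherwise all numeric columns except
#'   bookkeeping ones.
#' @param control An [lmt_control()].
#' @return An `lmt_model` with fields `root`, `class_order`,
#'   `feature_names`, `n_boost_iter`, `tree_size`, `n_leaves`, `n_train`,
#'   and (when pruning ran) `pruning`, the cost-complexity cross-validation
#'   trace (`alpha`, `cv_error`, `se`, `chosen`).
#' @examples
#' d <- tibble::tibble(
#'   x1 = c(rnorm(30, -2), rnorm(30, 2)), x2 = rnorm(60),
#'   label = rep(c("LR", "PO"), each = 30)
#' )
#' m <- train_lmt(d, control = lmt_control(prune = FALSE, seed = 1))
#' glance(m)
#' @export
train_lmt <- function(data, label = "label", features = NULL,
                      control = lmt_control()) {
  if (!label %in% names(data)) abort(paste0("no label column `", label, "`"))
  features <- .lmt_feature_cols(data, label, features)
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0) {
    abort(paste0("missing feature column(s): ", paste(missing_f, collapse = ", ")))
  }
  keep <- !is.na(data[[label]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) abort("no labeled instances to train on")
  y <- droplevels(factor(data[[label]]))
  X <- as.matrix(data[features])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) abort("features must be finite")
  yi <- as.integer(y)
  J <- nlevels(y)
  p <- ncol(X)
  N <- nrow(X)

  if (J == 1) {
    gamma <- matrix(0, p + 1, 1, dimnames = list(c("(intercept)", features), levels(y)))
    root <- .lmt_leaf(N, 0L, gamma, 0L, N)
    model <- structure(
      list(
        root = root, class_order = levels(y), feature_names = features,
        n_boost_iter = 0L, control = control, tree_size = 1L, n_leaves = 1L,
        n_train = N
      ),
      class = "lmt_model"
    )
    return(model)
  }

  n_iter <- control$num_boosting_iterations
  if (n_iter < 0 && control$fast_regression) {
    n_iter <- .lb_choose_iter(X, y, control$max_boost_iter,
      folds = control$cv_folds, seed = control$seed
    )
  } else if (n_iter < 0) {
    n_iter <- control$max_boost_iter # per-node CV overrides inside .lmt_grow
  }

  gamma0 <- matrix(0, p + 1, J)
  root <- .lmt_grow(X, yi, y, seq_len(N), gamma0, 0L, control, n_iter, control$seed)

  pruning <- NULL
  if (control$prune && root$type == "split") {
    pr <- .lmt_cv_prune(root, X, y, yi, control, n_iter)
    if (is.list(pr) && !is.null(pr$root)) {
      root <- pr$root
      pruning <- pr$info
    } else {
      root <- pr
    }
  }

  cnt <- .lmt_count(root)
  structure(
    list(
      root = root, class_order = levels(y), feature_names = features,
      n_boost_iter = n_iter, control = control, pruning = pruning,
      tree_size = unname(cnt["size"]), n_leaves = unname(cnt["leaves"]),
      n_train = N
    ),
    class = "lmt_model"
  )
}

# cost-complexity pruning with pruning strength selected by k-fold CV and
# the 1-SE rule
.lmt_cv_prune <- function(root, X, y, yi, control, n_iter) {
  N <- nrow(X)
  alphas <- .lmt_alpha_sequence(root, N)
  if (length(alphas) == 0) return(root)
  # candidate alphas: 0 (full tree), midpoints between knots, and the top
  # knot (root collapse); thinned to a manageable grid
  if (length(alphas) > 1) {
    cand <- c(0, (alphas[-length(alphas)] + alphas[-1]) / 2, alphas[length(alphas)])
  } else {
    cand <- c(0, alphas)
  }
  cand <- sort(unique(cand))
  if (length(cand) > 20) {
    cand <- sort(unique(c(0, stats::quantile(cand[-1], probs = seq(0, 1, length.out = 19), type = 1))))
  }

  k <- min(control$prune_folds, min(table(y)))
  if (k < 2) return(root)
  fold <- stratified_kfold(y, k = k, seed = control$seed)
  errs <- matrix(0, length(cand), k) # held-out error counts
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2) next
    sub <- .lmt_grow(
      X, yi, y, tr,
      matrix(0, ncol(X) + 1, nlevels(y)), 0L, control, n_iter, control$seed
    )
    for (a in seq_along(cand)) {
      pr <- .lmt_prune_alpha(sub, cand[a], length(tr))
      P <- .lmt_predict_probs(pr, X, te, matrix(NA_real_, N, nlevels(y)))
      pred <- max.col(P[te, , drop = FALSE], ties.method = "first")
      errs[a, f] <- sum(pred != yi[te])
    }
  }
  cv_err <- rowSums(errs) / N
  best <- which.min(cv_err)
  # 1-SE rule with the binomial standard error of the best estimate
  se <- sqrt(cv_err[best] * (1 - cv_err[best]) / N)
  chosen <- max(which(cv_err <= cv_err[best] + se))
  list(
    root = .lmt_prune_alpha(root, cand[chosen], N),
    info = list(
      alpha = cand, cv_error = cv_err, se = se,
      chosen = chosen, k = k
    )
  )
}

#' @export
print.lmt_model <- function(x, ...) {
  cat(sprintf(
    "<lmt_model> %d classes (%s), %d features; tree size %d, %d leaves; %d boosting iterations\n",
    length(x$class_order), paste(x$class_order, collapse = ", "),
    length(x$feature_names), x$tree_size, x$n_leaves, x$n_boost_iter
  ))
  invisible(x)
}

# coerce prediction input (vector / matrix / data frame) to a feature matrix
.lmt_newdata <- function(model, newdata) {
  p <- length(model$feature_names)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != p) {
      abort(sprintf("expected a feature vector of length %d", p))
    }
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, model$feature_names))
  } else if (is.data.frame(newdata)) {
    missing_f <- setdiff(model$feature_names, names(newdata))
    if (length(missing_f) > 0) {
      abort(paste0("missing feature column(s): ", paste(missing_f, collapse = ", ")))
    }
    newdata <- as.matrix(newdata[model$feature_names])
  }
  storage.mode(newdata) <- "double"
  if (!all(is.finite(newdata))) abort("features must be finite")
  newdata
}

#' Per-class leaf probabilities for one feature vector
#'
#' Routes the feature vector to its terminal leaf and evaluates the leaf's
#' logistic model: per-class linear scores are exponentiated and normalized
#' across classes (softmax), which reduces to the binary logistic sigmoid
#' when only two classes are present. Scores are clipped to +/- 500 before
#' exponentiation so probabilities stay finite and strictly positive.
#'
#' @param model An `lmt_model`.
#' @param x Numeric feature vector in `model$feature_names` order.
#' @return Named numeric vector of class probabilities summing to 1.
#' @export
leaf_probabilities <- function(model, x) {
  X <- .lmt_newdata(model, x)
  P <- .lmt_predict_probs(model$root, X, 1L, matrix(NA_real_, 1, length(model$class_order)))
  setNames(as.numeric(P[1, ]), model$class_order)
}

#' Predict gait phases with a Logistic Model Tree
#'
#' @param object An `lmt_model`.
#' @param newdata Data frame with the model's feature columns, a numeric
#'   matrix, or a single feature vector.
#' @param type `"class"` (default) for predicted labels or `"prob"` for the
#'   per-class probability matrix.
#' @param ... Unused.
#' @return A factor of predicted classes (ties broken toward the first class
#'   in `class_order`) or a probability matrix with one row per instance.
#' @export
predict.lmt_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- .lmt_newdata(object, newdata)
  n <- nrow(X)
  P <- .lmt_predict_probs(object$root, X, seq_len(n),
    matrix(NA_real_, n, length(object$class_order))
  )
  colnames(P) <- object$class_order
  if (type == "prob") return(P)
  cls <- object$class_order[max.col(P, ties.method = "first")]
  factor(cls, levels = object$class_order)
}

#' @rdname predict.lmt_model
#' @param model An `lmt_model`.
#' @param features Feature vector or data frame (see `newdata`).
#' @export
predict_phase <- function(model, features) {
  predict(model, features, type = "class")
}

#' @export
tidy.lmt_model <- function(x, ...) {
  rows <- list()
  walk <- function(node, id, path) {
    rows[[length(rows) + 1]] <<- tibble(
      node = id, depth = node$depth, type = node$type, n = node$n,
      feature = if (node$type == "split") x$feature_names[node$feature] else NA_character_,
      threshold = if (node$type == "split") node$threshold else NA_real_,
      path = path
    )
    if (node$type == "split") {
      walk(node$left, paste0(id, "L"), paste0(path, "/", x$feature_names[node$feature], "<=", signif(node$threshold, 4)))
      walk(node$right, paste0(id, "R"), paste0(path, "/", x$feature_names[node$feature], ">", signif(node$threshold, 4)))
    }
  }
  walk(x$root, "0", "")
  dplyr::bind_rows(rows)
}

#' @export
glance.lmt_model <- function(x, ...) {
  tibble(
    tree_size = x$tree_size, n_leaves = x$n_leaves,
    n_boost_iter = x$n_boost_iter, n_train = x$n_train,
    n_features = length(x$feature_names),
    n_classes = length(x$class_order)
  )
}
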