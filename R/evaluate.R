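#' Confusion matrix for gait-phase predictions
#'
#' @param truth,pred Equal-length label vectors (character or factor); rows
#'   of the result are true classes, columns predicted classes.
#' @param class_order Class order for rows/columns; defaults to the gait
#'   phases when all labels are phases, otherwise the sorted union.
#' @return A `gait_confusion`: an integer matrix with `class_order` as
#'   dimnames.
#' @examples
#' confusion(c("LR", "LR", "PO"), c("LR", "PO", "PO"))
#' @export
confusion <- function(truth, pred, class_order = NULL) {
  if (length(truth) != length(pred)) abort("`truth` and `pred` must have equal lengths")
  tr <- as.character(truth)
  pr <- as.character(pred)
  if (is.null(class_order)) {
    u <- unique(c(tr, pr))
    class_order <- if (all(u %in% gait_phases())) gait_phases() else sort(u)
  }
  tf <- factor(tr, levels = class_order)
  pf <- factor(pr, levels = class_order)
  cm <- table(true = tf, predicted = pf)
  m <- matrix(as.integer(cm), nrow = length(class_order), dimnames = dimnames(cm))
  structure(m, class = c("gait_confusion", "matrix"))
}

#' Weighted average of per-class metrics
#'
#' Instance-weighted average `sum(m_i * I_i) / sum(I_i)` of a per-class
#' metric, where `I_i` is the number of instances of class `i`.
#'
#' @param values Per-class metric values.
#' @param counts Per-class instance counts (same length, sum > 0).
#' @return The weighted mean.
#' @examples
#' weighted_average(c(0.9, 0.5), c(90, 10)) # 0.86
#' @export
weighted_average <- function(values, counts) {
  if (length(values) != length(counts)) abort("`values` and `counts` must have equal lengths")
  if (any(counts < 0)) abort("`counts` must be nonnegative")
  total <- sum(counts)
  if (total <= 0) abort("`counts` must sum to a positive number")
  sum(values * counts) / total
}

#' Per-class and weighted classification metrics
#'
#' One-vs-rest metrics from a confusion matrix: for class `i`,
#' `TP = cm[i, i]`, `FN = rowsum - TP`, `FP = colsum - TP`,
#' `TN = total - TP - FN - FP`; sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, F-score
#' `2 * prec * sens / (prec + sens)`, and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Ratios with a zero denominator are reported as 0 and flagged rather than
#' propagated as `NaN`, so weighted averages stay computable. Weighted
#' averages use the true-class instance counts.
#'
#' @param cm A `gait_confusion` (or plain square count matrix).
#' @return A `gait_metrics` object: list with `confusion`, `per_class`
#'   tibble (class, support, sensitivity, specificity, precision, f_score,
#'   mcc, undefined flag), `weighted` named vector, `accuracy`, `n`.
#' @examples
#' cm <- confusion(rep(gait_phases(), 25), rep(gait_phases(), 25))
#' per_class_metrics(cm)$accuracy
#' @export
per_class_metrics <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`cm` must be a square confusion matrix")
  total <- sum(m)
  if (total <= 0) abort("confusion matrix is empty")
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))

  tp <- unname(diag(m))
  fn <- unname(rowSums(m)) - tp
  fp <- unname(colSums(m)) - tp
  tn <- total - tp - fn - fp

  safe_div <- function(num, den) {
    und <- den == 0
    list(value = ifelse(und, 0, num / ifelse(und, 1, den)), undefined = und)
  }
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  fs <- safe_div(2 * prec$value * sens$value, prec$value + sens$value)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)

  any_undefined <- sens$undefined | spec$undefined | prec$undefined |
    fs$undefined | mcc$undefined
  per_class <- tibble(
    class = classes,
    support = as.integer(rowSums(m)),
    sensitivity = sens$value,
    specificity = spec$value,
    precision = prec$value,
    f_score = fs$value,
    mcc = mcc$value,
    undefined = any_undefined
  )
  I <- per_class$support
  weighted <- c(
    sensitivity = weighted_average(per_class$sensitivity, I),
    specificity = weighted_average(per_class$specificity, I),
    precision = weighted_average(per_class$precision, I),
    f_score = weighted_average(per_class$f_score, I),
    mcc = weighted_average(per_class$mcc, I)
  )
  structure(
    list(
      confusion = cm, per_class = per_class, weighted = weighted,
      accuracy = sum(tp) / total, n = total
    ),
    class = "gait_metrics"
  )
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf("<gait_metrics> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  print(x$per_class)
  cat("weighted:", paste(sprintf("%s=%.4f", names(x$weighted), x$weighted), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.gait_metrics <- function(x, ...) {
  dplyr::select(x$per_class, -"undefined")
}

#' @export
glance.gait_metrics <- function(x, ...) {
  dplyr::bind_cols(
    tibble(accuracy = x$accuracy, n = x$n),
    tibble::as_tibble_row(setNames(as.list(x$weighted), paste0("weighted_", names(x$weighted))))
  )
}

#' Stratified k-fold assignment
#'
#' Assigns each instance to one of `k` folds so that, within every class,
#' fold sizes differ by at most one instance; class proportions per fold
#' therefore match the global proportions to within one instance.
#'
#' @param labels Class label vector (character or factor).
#' @param k Number of folds.
#' @param seed Optional seed making the assignment reproducible.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @examples
#' table(stratified_kfold(rep(gait_phases(), 25), k = 5, seed = 1))
#' @export
stratified_kfold <- function(labels, k = 5, seed = NULL) {
  y <- factor(labels)
  if (k < 2) abort("`k` must be >= 2")
  counts <- table(y)
  if (any(counts < k)) {
    abort(paste0(
      "every class needs at least k = ", k, " instances; short: ",
      paste(names(counts)[counts < k], collapse = ", ")
    ))
  }
  assign_folds <- function() {
    fold <- integer(length(y))
    start <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold across classes so global sizes stay even
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    fold
  }
  if (!is.null(seed)) {
    withr::with_seed(seed, assign_folds())
  } else {
    assign_folds()
  }
}

#' Cross-validated evaluation of the LMT, with and without TSVC
#'
#' Pooled stratified k-fold cross-validation of [train_lmt()]: each fold's
#' instances are predicted by a model trained on the remaining folds, the
#' per-window predictions are pooled, and metrics are computed on the pooled
#' confusion matrix. When `with_tsvc` is `TRUE` the pooled predictions are
#' additionally corrected by [tsvc_correct()] applied per contiguous
#' recording (in window order) before computing a second set of metrics, so
#' the report mirrors the LMT vs LMT + TSVC comparison. A resubstitution
#' variant (train on everything, evaluate on the same instances) is
#' available via `report`.
#'
#' @param data Feature tibble (e.g. from [extract_features_cohort()]) with a
#'   label column, feature columns, and — for TSVC — a recording id column
#'   and `end_index` giving window order.
#' @param k Number of folds.
#' @param control An [lmt_control()] for the fold models.
#' @param with_tsvc Also report TSVC-corrected metrics.
#' @param label,features,recording Column names.
#' @param seed Seed for the fold assignment.
#' @param report `"pooled_cv"` (default) or `"resubstitution"`.
#' @return A `gait_cv` list: `lmt` and (optionally) `lmt_tsvc`
#'   `gait_metrics`, plus `folds`, `predictions` (tibble with `truth`,
#'   `pred`, `pred_tsvc`), and `k`.
#' @export
crossval_report <- function(data, k = 5, control = lmt_control(),
                            with_tsvc = TRUE, label = "label",
                            features = NULL, recording = "recording",
                            seed = NULL, report = c("pooled_cv", "resubstitution")) {
  report <- match.arg(report)
  data <- data[!is.na(data[[label]]), , drop = FALSE]
  if (nrow(data) == 0) abort("no labeled instances")
  features <- .lmt_feature_cols(data, label, features)
  lab_chr <- as.character(data[[label]])
  truth <- if (all(lab_chr %in% gait_phases())) phase_factor(lab_chr) else factor(lab_chr)
  truth <- droplevels(truth)
  n <- nrow(data)

  pred <- factor(rep(NA_character_, n), levels = levels(truth))
  if (report == "pooled_cv") {
    folds <- stratified_kfold(truth, k = k, seed = seed)
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- train_lmt(data[tr, , drop = FALSE], label = label,
        features = features, control = control
      )
      p <- predict(model, data[!tr, , drop = FALSE])
      pred[!tr] <- as.character(p)
    }
  } else {
    folds <- rep(0L, n)
    model <- train_lmt(data, label = label, features = features, control = control)
    pred <- predict(model, data)
  }

  out <- list(
    lmt = per_class_metrics(confusion(truth, pred)),
    folds = folds, k = k, report = report
  )
  predictions <- tibble(truth = truth, pred = pred)

  if (with_tsvc) {
    pred_tsvc <- as.character(pred)
    if (recording %in% names(data)) {
      groups <- split(seq_len(n), data[[recording]])
    } else {
      groups <- list(seq_len(n))
    }
    for (g in groups) {
      ord <- if ("end_index" %in% names(data)) g[order(data$end_index[g])] else g
      pred_tsvc[ord] <- tsvc_correct(as.character(pred[ord]))
    }
    pred_tsvc <- factor(pred_tsvc, levels = levels(truth))
    out$lmt_tsvc <- per_class_metrics(confusion(truth, pred_tsvc))
    predictions$pred_tsvc <- pred_tsvc
  }
  out$predictions <- predictions
  structure(out, class = "gait_cv")
}

#' @export
print.gait_cv <- function(x, ...) {
  cat(sprintf(
    "<gait_cv> %s, k = %d | LMT accuracy %.4f%s\n",
    x$report, x$k, x$lmt$accuracy,
    if (!is.null(x$lmt_tsvc)) sprintf(", LMT+TSVC accuracy %.4f", x$lmt_tsvc$accuracy) else ""
  ))
  invisible(x)
}

#' @export
tidy.gait_cv <- function(x, ...) {
  out <- dplyr::bind_cols(condition = "LMT", tidy(x$lmt))
  if (!is.null(x$lmt_tsvc)) {
    out <- dplyr::bind_rows(out, dplyr::bind_cols(condition = "LMT+TSVC", tidy(x$lmt_tsvc)))
  }
  out
}

#' @export
glance.gait_cv <- function(x, ...) {
  out <- dplyr::bind_cols(condition = "LMT", glance(x$lmt))
  if (!is.null(x$lmt_tsvc)) {
    out <- dplyr::bind_rows(out, dplyr::bind_cols(condition = "LMT+TSVC", glance(x$lmt_tsvc)))
  }
  out
}

#' Flat CSV export of a metrics report
#'
#' Writes rows of condition x class x metric value, plus the labeled
#' confusion matrix alongside (`<path>_confusion.csv`).
#'
#' @param cv A `gait_cv` or `gait_metrics`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(cv, path) {
  if (inherits(cv, "gait_metrics")) {
    cv <- list(lmt = cv)
    class(cv) <- "gait_cv"
    cv$lmt_tsvc <- NULL
  }
  long <- tidy.gait_cv(cv) |>
    tidyr::pivot_longer(
      cols = c("sensitivity", "specificity", "precision", "f_score", "mcc"),
      names_to = "metric", values_to = "value"
    )
  write.csv(as.data.frame(long), path, row.names = FALSE)
  cm <- as.data.frame(unclass(cv$lmt$confusion))
  cm <- cbind(true_class = rownames(cm), cm)
  write.csv(cm, sub("\\.csv$", "_confusion.csv", path), row.names = FALSE)
  invisible(path)
}
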