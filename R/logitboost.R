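# Multiclass LogitBoost with simple-linear-regression base learners.
#
# Each iteration fits, per class, a weighted simple linear regression of the
# working response on the single best feature, then applies the multiclass
# centering (J-1)/J * (f_j - mean_k f_k). Because every base learner is
# linear in one feature, the whole committee collapses to one linear score
# per class: F_j(x) = gamma[1, j] + sum_k gamma[k+1, j] * x_k. Class
# probabilities are the softmax of the scores, which reduces to the logistic
# sigmoid e^F / (1 + e^F) in the two-class case.
#
# A backtracking step-size search (1, 1/2, 1/4, 1/8) keeps the training
# negative log-likelihood non-increasing; boosting stops early when no step
# improves it.

# working-response clip (Friedman et al.; WEKA uses the same bound)
.lb_zmax <- 3
.lb_score_clip <- 500

.lb_softmax <- function(F) {
  F <- pmin(pmax(F, -.lb_score_clip), .lb_score_clip)
  F <- F - apply(F, 1, max)
  # floor keeps every probability strictly positive after exponentiation
  E <- exp(pmax(F, -700))
  E / rowSums(E)
}

.lb_nll <- function(P, Y) {
  -sum(log(pmax(rowSums(P * Y), 1e-300)))
}

# scores for design matrix X (n x p) under coefficients gamma ((p+1) x J)
.lb_scores <- function(X, gamma) {
  sweep(X %*% gamma[-1, , drop = FALSE], 2, -gamma[1, ], "-")
}

#' Fit a multiclass LogitBoost committee of simple linear regressions
#'
#' Stagewise additive logistic regression: at each iteration the working
#' responses and weights are recomputed from the current class
#' probabilities, one weighted simple linear regression (best single
#' feature) is fitted per class, and the centred update is added to the
#' per-class linear scores. The committee is returned collapsed to one
#' coefficient vector per class (intercept + one coefficient per feature).
#'
#' @param X Numeric matrix (n x p) of features.
#' @param y Factor of class labels (levels define the class order).
#' @param n_iter Number of boosting iterations.
#' @param gamma_init Optional (p+1) x J warm-start coefficient matrix.
#' @param X_val,y_val Optional validation set; when given, the
#'   misclassification error after each iteration is recorded.
#' @return List with `gamma` ((p+1) x J matrix), `nll_path` (training
#'   negative log-likelihood after each completed iteration), `val_error`
#'   (per-iteration validation error, if requested) and `n_iter_done`.
#' @keywords internal
fit_logitboost <- function(X, y, n_iter, gamma_init = NULL,
                           X_val = NULL, y_val = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  classes <- levels(y)
  J <- length(classes)
  yi <- as.integer(y)
  Y <- matrix(0, n, J)
  Y[cbind(seq_len(n), yi)] <- 1

  gamma <- gamma_init %||% matrix(0, p + 1, J)
  F <- .lb_scores(X, gamma)
  P <- .lb_softmax(F)
  nll <- .lb_nll(P, Y)
  nll_path <- numeric(0)
  val_error <- if (!is.null(X_val)) numeric(0) else NULL
  if (!is.null(X_val)) {
    F_val <- .lb_scores(as.matrix(X_val), gamma)
    yvi <- as.integer(y_val)
  }

  ones <- rep(1, n)
  for (m in seq_len(n_iter)) {
    W <- P * (1 - P)
    Z <- (Y - P) / pmax(W, 1e-8)
    Z <- pmin(pmax(Z, -.lb_zmax), .lb_zmax)

    delta <- matrix(0, p + 1, J)
    for (j in seq_len(J)) {
      w <- W[, j]
      z <- Z[, j]
      sw <- sum(w)
      if (sw <= 1e-12) next
      wz <- w * z
      swz <- sum(wz)
      swx <- crossprod(X, w)[, 1]
      swxz <- crossprod(X, wz)[, 1]
      swxx <- crossprod(X^2, w)[, 1]
      Sxx <- swxx - swx^2 / sw
      Sxz <- swxz - swx * swz / sw
      ok <- Sxx > 1e-12
      b <- ifelse(ok, Sxz / Sxx, 0)
      Szz <- sum(w * z^2) - swz^2 / sw
      sse <- Szz - ifelse(ok, b * Sxz, 0)
      k <- which.min(sse) # ties -> lowest feature index
      a <- (swz - b[k] * swx[k]) / sw
      delta[1, j] <- a
      delta[k + 1, j] <- b[k]
    }
    # multiclass centering: f*_j = (J-1)/J * (f_j - mean_k f_k)
    delta <- (J - 1) / J * (delta - rowMeans(delta))

    # backtracking so the training objective never increases
    step <- 1
    accepted <- FALSE
    for (try in 1:4) {
      gamma_new <- gamma + step * delta
      F_new <- .lb_scores(X, gamma_new)
      P_new <- .lb_softmax(F_new)
      nll_new <- .lb_nll(P_new, Y)
      if (nll_new <= nll + 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    gamma <- gamma_new
    P <- P_new
    nll <- nll_new
    nll_path <- c(nll_path, nll)
    if (!is.null(X_val)) {
      F_val <- .lb_scores(as.matrix(X_val), gamma)
      pred <- max.col(F_val, ties.method = "first")
      val_error <- c(val_error, mean(pred != yvi))
    }
  }

  dimnames(gamma) <- list(c("(intercept)", colnames(X)), classes)
  list(
    gamma = gamma, nll_path = nll_path, val_error = val_error,
    n_iter_done = length(nll_path)
  )
}

# choose the boosting iteration count by stratified k-fold CV (argmin of the
# summed held-out misclassification error; ties toward fewer iterations)
.lb_choose_iter <- function(X, y, max_iter, folds = 5, seed = NULL,
                            gamma_init = NULL) {
  n <- nrow(X)
  k <- min(folds, min(table(y)))
  if (k < 2 || n < 10) return(max(1L, min(10L, max_iter)))
  fold <- stratified_kfold(y, k = k, seed = seed)
  errs <- matrix(NA_real_, max_iter, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_logitboost(
      X[tr, , drop = FALSE], y[tr], n_iter = max_iter,
      gamma_init = gamma_init,
      X_val = X[!tr, , drop = FALSE], y_val = y[!tr]
    )
    e <- fit$val_error
    if (length(e) == 0) e <- rep(mean(max.col(.lb_scores(
      X[!tr, , drop = FALSE], gamma_init %||% matrix(0, ncol(X) + 1, nlevels(y))
    ), ties.method = "first") != as.integer(y[!tr])), 1)
    errs[, f] <- c(e, rep(e[length(e)], max_iter - length(e)))
  }
  total <- rowSums(errs)
  which.min(total) # first minimum -> fewest iterations
}
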