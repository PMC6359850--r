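#' Sliding-window specification
#'
#' Windowing used throughout the pipeline: a 0.1-s window advanced in 0.01-s
#' steps (90% overlap) over a 200 Hz signal gives 20-sample windows stepping
#' 2 samples at a time, so consecutive windows share 18 of 20 samples.
#'
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A `window_spec` list with elements `window_s`, `step_s`,
#'   `sample_rate_hz`, `window_samples`, `step_samples`.
#' @examples
#' window_spec()
#' @export
window_spec <- function(window_s = 0.1, step_s = 0.01, sample_rate_hz = 200) {
  ws <- as.integer(round(window_s * sample_rate_hz))
  ss <- as.integer(round(step_s * sample_rate_hz))
  if (ws < 2) abort("window must span at least 2 samples")
  if (ss < 1) abort("step must span at least 1 sample")
  if (ss > ws) abort("step must not exceed the window length")
  structure(
    list(
      window_s = window_s, step_s = step_s, sample_rate_hz = sample_rate_hz,
      window_samples = ws, step_samples = ss
    ),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf(
    "<window_spec> %g s window (%d samples), %g s step (%d samples), %g Hz\n",
    x$window_s, x$window_samples, x$step_s, x$step_samples, x$sample_rate_hz
  ))
  invisible(x)
}

#' Start indices of sliding windows
#'
#' @param n_samples Signal length.
#' @param spec A [window_spec()].
#' @return Integer vector of 1-based start indices:
#'   `1, 1 + step, 1 + 2 step, ...`; the number of windows is
#'   `floor((n_samples - window_samples) / step_samples) + 1`.
#' @examples
#' length(sliding_window_starts(200, window_spec())) # 91
#' @export
sliding_window_starts <- function(n_samples, spec = window_spec()) {
  if (n_samples < spec$window_samples) {
    abort("signal shorter than one window")
  }
  seq.int(1L, n_samples - spec$window_samples + 1L, by = spec$step_samples)
}

#' Sign-sum of a window
#'
#' Scores each sample +1 if positive, -1 if negative, 0 if exactly zero, and
#' returns the sum. A crude but cheap descriptor of which side of zero a
#' signal spends the window on.
#'
#' @param x Nonempty numeric vector.
#' @return Integer-valued sum in `[-length(x), length(x)]`.
#' @examples
#' sign_sum(c(1.5, -0.2, 3, 0))
#' @export
sign_sum <- function(x) {
  if (length(x) == 0) abort("`x` must be nonempty")
  sum(sign(x))
}

#' Count strict local maxima
#'
#' Number of interior samples strictly greater than both neighbours. No
#' prominence or width thresholds are applied; a plateau therefore counts
#' zero times (no strict maximum) rather than once per plateau sample.
#'
#' @param x Numeric vector.
#' @return Nonnegative integer count (0 if `length(x) < 3`).
#' @examples
#' count_peaks(c(0, 1, 0, 1, 0))
#' @export
count_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(0L)
  mid <- x[2:(n - 1)]
  sum(mid > x[1:(n - 2)] & mid > x[3:n])
}

#' Principal (dominant non-DC) frequency of a window
#'
#' Frequency of the discrete Fourier bin with the greatest magnitude,
#' excluding the DC bin (which would dominate any offset-bearing channel and
#' carries no rhythm information). Ties are broken toward the lowest
#' frequency; a window with no non-DC energy (e.g. a constant) reports 0.
#'
#' @param x Numeric vector (length >= 2).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Frequency in Hz of the dominant non-DC bin, up to Nyquist.
#' @examples
#' t <- (0:19) / 200
#' principal_frequency(sin(2 * pi * 10 * t), 200) # 10
#' @export
principal_frequency <- function(x, sample_rate_hz) {
  n <- length(x)
  if (n < 2) abort("need at least 2 samples")
  mag <- Mod(fft(x))
  bins <- 2:(floor(n / 2) + 1L)
  m <- mag[bins]
  if (max(m) <= sqrt(.Machine$double.eps) * max(mag[1], n, 1)) return(0)
  # magnitudes within 1e-9 relative of the maximum count as tied; the
  # lowest such frequency wins
  k <- bins[which(m >= max(m) * (1 - 1e-9))[1]]
  (k - 1) * sample_rate_hz / n
}

#' Pearson correlation within a window
#'
#' Pearson correlation between two equally long windows (used for the
#' vertical-vs-heading acceleration axes). Returns 0 when either input has
#' zero variance, so the feature stays defined on degenerate windows.
#'
#' @param y,z Numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' window_correlation(1:5, 2 * (1:5) + 1)
#' @export
window_correlation <- function(y, z) {
  n <- length(y)
  if (length(z) != n) abort("`y` and `z` must have equal lengths")
  if (n < 2) abort("need at least 2 samples")
  if (var(y) <= 0 || var(z) <= 0) return(0)
  r <- cor(y, z)
  max(-1, min(1, r))
}

#' Names of the 20 window features, in canonical order
#'
#' @return Character vector of 20 stable snake_case feature names.
#' @export
gait_feature_names <- function() {
  c(
    "ka_mean", "angvel_x_mean", "angvel_y_mean", "acc_y_mean", "acc_z_mean",
    "ka_var", "ka_maxdiff", "angvel_x_maxdiff", "ka_min", "angvel_y_min",
    "acc_y_max",
    "angvel_x_signsum", "angvel_y_signsum", "angvel_z_signsum",
    "acc_x_signsum", "acc_y_signsum", "acc_z_signsum",
    "acc_res_npeaks", "angvel_y_prinfreq", "acc_zy_corr"
  )
}

# internal: required signal channel columns
gait_channels <- function() {
  c("ka", "angvel_x", "angvel_y", "angvel_z", "acc_x", "acc_y", "acc_z")
}

# internal: window matrix (one row per window) for one channel
.win_matrix <- function(v, starts, len) {
  idx <- outer(starts, 0:(len - 1L), "+")
  matrix(v[idx], nrow = length(starts), ncol = len)
}

.row_min <- function(M) as.numeric(do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j])))
.row_max <- function(M) as.numeric(do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j])))

#' Extract the 20-feature vector from every sliding window
#'
#' Slides a window over a multichannel gait signal and computes, per window,
#' the fixed 20-feature vector: means of knee angle, angular velocity x/y and
#' acceleration y/z; knee-angle variance (population form), range
#' (max - min) of knee angle and angular-velocity x; knee-angle minimum,
#' angular-velocity-y minimum, acceleration-y maximum; sign-sums of all three
#' angular-velocity and acceleration axes; peak count of the resultant
#' acceleration; principal frequency of angular-velocity y; and the Pearson
#' correlation between the z- and y-axis acceleration. Each window is
#' labeled by its last sample's phase (the most recent information a
#' real-time controller would act on).
#'
#' @param signal A `gait_signal` tibble (see [simulate_cohort()]) or any data
#'   frame with columns `ka`, `angvel_x/y/z`, `acc_x/y/z` and optionally
#'   `label`.
#' @param spec A [window_spec()]; its `sample_rate_hz` must match the signal.
#' @return A tibble with one row per window: `end_index` (1-based index of
#'   the window's last sample), `label` (phase of that sample, or `NA`), and
#'   the 20 feature columns of [gait_feature_names()].
#' @examples
#' rec <- simulate_cohort(sim_config(n_strides = 2, seed = 1))
#' feats <- extract_features(rec$signal)
#' dim(feats)
#' @export
extract_features <- function(signal, spec = window_spec()) {
  missing_ch <- setdiff(gait_channels(), names(signal))
  if (length(missing_ch) > 0) {
    abort(paste0("signal is missing channel column(s): ", paste(missing_ch, collapse = ", ")))
  }
  n <- nrow(signal)
  starts <- sliding_window_starts(n, spec)
  L <- spec$window_samples
  fs <- spec$sample_rate_hz
  W <- length(starts)
  ends <- starts + L - 1L

  ch <- lapply(signal[gait_channels()], as.numeric)
  if (any(!vapply(ch, function(v) all(is.finite(v)), logical(1)))) {
    abort("signal channels must be finite")
  }
  M <- lapply(ch, .win_matrix, starts = starts, len = L)

  pop_var <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / ncol(m)
  }

  # resultant acceleration peak count, vectorized over windows
  acc_res <- resultant(ch$acc_x, ch$acc_y, ch$acc_z)
  R <- .win_matrix(acc_res, starts, L)
  mid <- R[, 2:(L - 1), drop = FALSE]
  npeaks <- rowSums(mid > R[, 1:(L - 2), drop = FALSE] & mid > R[, 3:L, drop = FALSE])

  # principal frequency of angular-velocity y per window
  FT <- mvfft(t(M$angvel_y))
  magmat <- Mod(FT)
  bins <- 2:(floor(L / 2) + 1L)
  mags <- magmat[bins, , drop = FALSE]
  colmax <- apply(mags, 2, max)
  # near-ties (1e-9 relative) resolve to the lowest frequency, matching
  # principal_frequency()
  rel <- sweep(mags, 2, pmax(colmax, .Machine$double.xmin), "/")
  tied <- t(rel) >= 1 - 1e-9 # windows x bins
  best_bin <- max.col(tied * rev(seq_len(ncol(tied)))[col(tied)], ties.method = "first")
  prinfreq <- (bins[best_bin] - 1) * fs / L
  dc <- magmat[1, ]
  prinfreq[colmax <= sqrt(.Machine$double.eps) * pmax(dc, L, 1)] <- 0

  # z-y acceleration correlation per window (population moments)
  Y <- M$acc_y
  Z <- M$acc_z
  my <- rowMeans(Y); mz <- rowMeans(Z)
  sy2 <- rowMeans(Y^2) - my^2
  sz2 <- rowMeans(Z^2) - mz^2
  cyz <- rowMeans(Y * Z) - my * mz
  denom <- sqrt(pmax(sy2, 0) * pmax(sz2, 0))
  corr <- ifelse(denom <= sqrt(.Machine$double.eps) * pmax(abs(my) * abs(mz), 1),
    0, cyz / denom
  )
  corr <- pmax(-1, pmin(1, corr))

  out <- tibble(
    end_index = ends,
    label = if ("label" %in% names(signal)) phase_factor(signal$label[ends]) else phase_factor(rep(NA, W)),
    ka_mean = rowMeans(M$ka),
    angvel_x_mean = rowMeans(M$angvel_x),
    angvel_y_mean = rowMeans(M$angvel_y),
    acc_y_mean = rowMeans(M$acc_y),
    acc_z_mean = rowMeans(M$acc_z),
    ka_var = pop_var(M$ka),
    ka_maxdiff = .row_max(M$ka) - .row_min(M$ka),
    angvel_x_maxdiff = .row_max(M$angvel_x) - .row_min(M$angvel_x),
    ka_min = .row_min(M$ka),
    angvel_y_min = .row_min(M$angvel_y),
    acc_y_max = .row_max(M$acc_y),
    angvel_x_signsum = rowSums(sign(M$angvel_x)),
    angvel_y_signsum = rowSums(sign(M$angvel_y)),
    angvel_z_signsum = rowSums(sign(M$angvel_z)),
    acc_x_signsum = rowSums(sign(M$acc_x)),
    acc_y_signsum = rowSums(sign(M$acc_y)),
    acc_z_signsum = rowSums(sign(M$acc_z)),
    acc_res_npeaks = as.numeric(npeaks),
    angvel_y_prinfreq = prinfreq,
    acc_zy_corr = corr
  )
  out
}

#' Extract features from every recording of a cohort
#'
#' @param cohort A `gait_cohort` (list of recordings from
#'   [simulate_preset()]).
#' @inheritParams extract_features
#' @return A tibble of window features with a leading `recording` id column.
#' @export
extract_features_cohort <- function(cohort, spec = window_spec()) {
  purrr::map_dfr(cohort, function(rec) {
    f <- extract_features(rec$signal, spec)
    dplyr::bind_cols(tibble(recording = rec$meta$recording_id), f)
  })
}

#' Write an ARFF-compatible header for the feature matrix
#'
#' Emits `@relation` / `@attribute` declarations matching the feature CSV
#' (20 numeric attributes plus the nominal phase label), for cross-checking
#' feature exports against WEKA-family tools.
#'
#' @param path File path or connection to write to.
#' @param relation Relation name.
#' @return Invisibly, the header lines.
#' @export
write_arff_header <- function(path, relation = "gait_features") {
  lines <- c(
    paste0("@relation ", relation),
    "",
    paste0("@attribute ", gait_feature_names(), " numeric"),
    paste0("@attribute label {", paste(gait_phases(), collapse = ","), "}"),
    "",
    "@data"
  )
  writeLines(lines, path)
  invisible(lines)
}
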