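#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward
#' ([signal::filtfilt()]), giving zero phase lag and an effective magnitude
#' response equal to the squared one-pass response. The defaults (4th order,
#' 10 Hz cut-off) are the standard choice for human-movement kinematics,
#' where essentially all signal power lies below 10 Hz.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param sample_rate_hz Sampling rate of `x` in Hz.
#' @param cutoff_hz Cut-off frequency in Hz; must lie below the Nyquist
#'   frequency `sample_rate_hz / 2`.
#' @param order Filter order (per pass).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' noisy <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 60 * t)
#' smooth <- butterworth_lowpass(noisy, 200)
#' @export
butterworth_lowpass <- function(x, sample_rate_hz, cutoff_hz = 10, order = 4) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (sample_rate_hz <= 0) abort("`sample_rate_hz` must be positive")
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    abort("`cutoff_hz` must lie in (0, sample_rate_hz / 2)")
  }
  if (length(x) <= 3 * order) {
    abort("signal too short to filter: need length > 3 * order")
  }
  bf <- signal::butter(order, 2 * cutoff_hz / sample_rate_hz, type = "low")
  # reflect-pad both ends (odd symmetry about the end points) so the
  # forward-backward pass is free of edge transients
  n <- length(x)
  # pad beyond the filter settling length so startup transients decay
  # before the retained segment
  pad <- min(n - 1L, as.integer(ceiling(10 * sample_rate_hz / cutoff_hz)))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  y[(pad + 1):(pad + n)]
}

#' Linear resampling to a new uniform rate
#'
#' Linearly interpolates a uniformly sampled signal onto a new uniform time
#' grid starting at the same first sample (time 0), emulating the
#' re-interpolation of motion-capture kinematics to an IMU-like 200 Hz rate.
#'
#' @param x Numeric vector sampled at `from_hz`.
#' @param from_hz Original sampling rate (Hz).
#' @param to_hz Target sampling rate (Hz), default 200.
#' @return Numeric vector sampled at `to_hz` spanning the same duration; the
#'   first sample is preserved exactly.
#' @examples
#' resample_linear(c(0, 1, 2, 3), from_hz = 100, to_hz = 200)
#' @export
resample_linear <- function(x, from_hz, to_hz = 200) {
  if (from_hz <= 0 || to_hz <= 0) abort("sampling rates must be positive")
  if (length(x) < 2) abort("need at least 2 samples to resample")
  if (from_hz == to_hz) return(as.numeric(x))
  n <- length(x)
  duration <- (n - 1) / from_hz
  t_old <- (seq_len(n) - 1) / from_hz
  t_new <- seq(0, by = 1 / to_hz, length.out = floor(duration * to_hz + 1e-9) + 1)
  approx(t_old, x, xout = t_new, method = "linear", rule = 2)$y
}

#' Resultant (Euclidean norm) of a three-axis signal
#'
#' Per-sample magnitude `sqrt(ax^2 + ay^2 + az^2)` of a triaxial signal,
#' used as a supplementary orientation-free channel for angular velocity and
#' acceleration.
#'
#' @param ax,ay,az Numeric vectors of equal length (one per axis).
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' resultant(3, 4, 0)
#' @export
resultant <- function(ax, ay, az) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    abort("`ax`, `ay`, `az` must have equal lengths")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Label samples with gait phases from stride event annotations
#'
#' Partitions a signal into the four gait phases from per-stride event
#' indices. Intervals are half-open (`[start, end)`) so every in-stride
#' sample carries exactly one label: LR covers `[initial_contact,
#' mid_stance)`, PO `[mid_stance, foot_off)`, Swing `[foot_off,
#' max_knee_flexion)`, and TSw `[max_knee_flexion, next_initial_contact)`.
#' Samples outside any stride are `NA`.
#'
#' @param annotations Data frame with one row per stride and integer columns
#'   `initial_contact`, `mid_stance`, `foot_off`, `max_knee_flexion`,
#'   `next_initial_contact` (1-based sample indices, strictly increasing
#'   within a row, non-overlapping across rows).
#' @param n_samples Total number of samples to label.
#' @return Factor vector of length `n_samples` with levels `gait_phases()`;
#'   `NA` outside strides.
#' @examples
#' ann <- tibble::tibble(
#'   initial_contact = 1, mid_stance = 31, foot_off = 61,
#'   max_knee_flexion = 74, next_initial_contact = 101
#' )
#' table(label_phases(ann, 100))
#' @export
label_phases <- function(annotations, n_samples) {
  cols <- c(gait_events(), "next_initial_contact")
  if (!all(cols %in% names(annotations))) {
    abort(paste0("`annotations` must contain columns: ", paste(cols, collapse = ", ")))
  }
  labels <- rep(NA_character_, n_samples)
  if (nrow(annotations) == 0) return(phase_factor(labels))
  ann <- annotations[order(annotations$initial_contact), cols, drop = FALSE]
  prev_end <- 0L
  for (s in seq_len(nrow(ann))) {
    ev <- as.integer(ann[s, ])
    if (any(diff(ev) <= 0)) {
      abort("stride events must be strictly increasing within each stride")
    }
    if (ev[1] <= prev_end) abort("strides must not overlap")
    if (ev[1] < 1 || ev[5] > n_samples + 1) {
      abort("stride event indices out of range")
    }
    phases <- gait_phases()
    for (p in 1:4) {
      labels[ev[p]:(ev[p + 1] - 1L)] <- phases[p]
    }
    prev_end <- ev[5] - 1L
  }
  phase_factor(labels)
}
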