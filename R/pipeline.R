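#' Run the streaming recognition loop over a signal
#'
#' Realizes the real-time loop an orthosis controller would run: slide a
#' 0.1-s window in 0.01-s steps, extract the 20 features, classify the
#' window with the LMT, pass the prediction through the TSVC corrector, and
#' emit one label per window aligned to the window's *last* sample (the
#' decision applies "now"). TSVC's Rule B may hold one instance, so the
#' decision latency is at most one window step; held instances are flushed
#' at end of stream and emission order equals window order.
#'
#' @param model A trained `lmt_model`.
#' @param signal A `gait_signal` tibble (or data frame with the 7 channel
#'   columns).
#' @param spec A [window_spec()].
#' @param tsvc Apply TSVC correction (default `TRUE`).
#' @return Tibble with one row per window: `end_index`, `time` (if present
#'   in the signal), `label_raw` (LMT output) and `label` (after TSVC; equal
#'   to `label_raw` when `tsvc = FALSE`), plus the detected gait events as
#'   attribute `"events"` (also retrievable with [detect_events()]).
#' @examples
#' rec <- simulate_cohort(sim_config(n_strides = 2, seed = 5, noise_sd = 0))
#' feats <- extract_features(rec$signal)
#' model <- train_lmt(feats, control = lmt_control(prune = FALSE, seed = 1,
#'                                                 num_boosting_iterations = 5))
#' head(run_stream(model, rec$signal))
#' @export
run_stream <- function(model, signal, spec = window_spec(), tsvc = TRUE) {
  feats <- extract_features(signal, spec)
  raw <- predict(model, feats)
  corrected <- if (tsvc) phase_factor(tsvc_correct(as.character(raw))) else phase_factor(as.character(raw))
  out <- tibble(end_index = feats$end_index)
  if ("time" %in% names(signal)) out$time <- signal$time[feats$end_index]
  out$label_raw <- phase_factor(as.character(raw))
  out$label <- corrected
  attr(out, "events") <- detect_events(out$label, index = out$end_index)
  out
}

#' Evaluate ground-truth self-consistency of a recording
#'
#' Sanity check used by the simulator's tests: windows labeled from the
#' ground-truth annotations, "predicted" by those same labels, must give
#' accuracy 1.
#'
#' @param recording A `gait_recording`.
#' @param spec A [window_spec()].
#' @return The `gait_metrics` of truth vs truth.
#' @keywords internal
#' @export
self_consistency <- function(recording, spec = window_spec()) {
  feats <- extract_features(recording$signal, spec)
  feats <- feats[!is.na(feats$label), ]
  per_class_metrics(confusion(feats$label, feats$label))
}
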