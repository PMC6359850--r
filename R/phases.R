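#' Gait phases and their cyclic order
#'
#' A stride is partitioned into four phases bounded by four gait events:
#' Loading Response (`LR`, initial contact to mid-stance), Push-Off (`PO`,
#' mid-stance to foot-off), `Swing` (foot-off to maximum knee flexion), and
#' Terminal Swing (`TSw`, maximum knee flexion to the next initial contact).
#' The phases repeat cyclically: LR -> PO -> Swing -> TSw -> LR.
#'
#' @return `gait_phases()` returns the four phase names in cycle order.
#' @examples
#' gait_phases()
#' phase_successor("TSw")
#' @export
gait_phases <- function() {
  c("LR", "PO", "Swing", "TSw")
}

#' @rdname gait_phases
#' @param phase Character vector of phase names.
#' @return `phase_successor()` returns, for each element, the next phase in
#'   the gait cycle.
#' @export
phase_successor <- function(phase) {
  cyc <- gait_phases()
  succ <- setNames(cyc[c(2, 3, 4, 1)], cyc)
  bad <- !(phase %in% cyc)
  if (any(bad)) {
    abort(paste0("unknown gait phase(s): ", paste(unique(phase[bad]), collapse = ", ")))
  }
  unname(succ[as.character(phase)])
}

#' @rdname gait_phases
#' @param x Character vector (or factor) of phase names; `NA` allowed.
#' @return `phase_factor()` returns `x` as a factor with levels in cycle order.
#' @export
phase_factor <- function(x) {
  factor(as.character(x), levels = gait_phases())
}

# internal: named gait events in stride order
gait_events <- function() {
  c("initial_contact", "mid_stance", "foot_off", "max_knee_flexion")
}
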