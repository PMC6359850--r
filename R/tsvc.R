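#' Transition Sequence Verification and Correction (TSVC)
#'
#' Streaming post-classifier that enforces the cyclic gait-phase order
#' LR -> PO -> Swing -> TSw -> LR on a stream of per-window predictions.
#' Two rules fire only when the three previously accepted labels are
#' identical (a stable history `h`):
#'
#' * **Rule A** (no lookahead): an incoming label that differs from `h` and
#'   is *not* the next phase in the cycle is an impossible transition and is
#'   relabeled to `h` (e.g. `LR, LR, LR, Swing` becomes `LR, LR, LR, LR`).
#' * **Rule B** (one-instance lookahead): an incoming label that *is* the
#'   next phase might be a legitimate transition or an isolated outlier, so
#'   it is held pending. If the following label returns to `h`, the pending
#'   instance was an isolated outlier and is relabeled to `h` (e.g.
#'   `LR, LR, LR, PO, LR` becomes all `LR`); otherwise it is released
#'   unchanged.
#'
#' The first three instances pass through uncorrected (no history), and when
#' the three previous labels are not identical no relabeling is applied.
#' Emission order equals arrival order; after [tsvc_flush()] the number of
#' emitted labels equals the number consumed, so the only latency is Rule
#' B's single-instance lookahead (10 ms at the default window step).
#'
#' @return `tsvc_state()` returns a fresh streaming state.
#' @examples
#' tsvc_correct(c("LR", "LR", "LR", "Swing"))
#' tsvc_correct(c("LR", "LR", "LR", "PO", "LR"))
#' tsvc_correct(c("LR", "LR", "LR", "PO", "PO")) # legitimate transition kept
#' @export
tsvc_state <- function() {
  structure(
    list(history = character(0), pending = NULL, emitted_count = 0L),
    class = "tsvc_state"
  )
}

# append an accepted label to the (<= 3 long) history
.tsvc_push <- function(state, label) {
  state$history <- c(state$history, label)
  if (length(state$history) > 3) {
    state$history <- state$history[-1]
  }
  state$emitted_count <- state$emitted_count + 1L
  state
}

#' @rdname tsvc_state
#' @param state A `tsvc_state`.
#' @param incoming One incoming phase label.
#' @return `tsvc_step()` returns `list(state = <updated state>, emitted =
#'   <character vector of 0, 1 or 2 labels emitted now>)`.
#' @export
tsvc_step <- function(state, incoming) {
  incoming <- as.character(incoming)
  if (length(incoming) != 1 || !(incoming %in% gait_phases())) {
    abort("`incoming` must be a single valid gait phase label")
  }
  emitted <- character(0)
  h <- state$history
  stable <- length(h) == 3 && length(unique(h)) == 1

  if (!is.null(state$pending)) {
    ref <- state$pending$history_label
    if (incoming == ref) {
      # isolated outlier: relabel the pending instance to the history label
      emitted <- c(ref, incoming)
      state$pending <- NULL
      state <- .tsvc_push(state, ref)
      state <- .tsvc_push(state, incoming)
      return(list(state = state, emitted = emitted))
    }
    # transition confirmed (or stream moved on): release pending unchanged
    released <- state$pending$label
    state$pending <- NULL
    state <- .tsvc_push(state, released)
    emitted <- released
    h <- state$history
    stable <- length(h) == 3 && length(unique(h)) == 1
    # fall through: the incoming label is now processed against the
    # updated history
  }

  if (stable && incoming != h[3]) {
    if (incoming == phase_successor(h[3])) {
      # Rule B: plausible next phase; hold for one-instance lookahead
      state$pending <- list(label = incoming, history_label = h[3])
      return(list(state = state, emitted = emitted))
    }
    # Rule A: impossible transition; relabel to the previous instance
    state <- .tsvc_push(state, h[3])
    return(list(state = state, emitted = c(emitted, h[3])))
  }

  state <- .tsvc_push(state, incoming)
  list(state = state, emitted = c(emitted, incoming))
}

#' @rdname tsvc_state
#' @return `tsvc_flush()` returns `list(state, emitted)`, releasing any
#'   pending instance unchanged at end of stream.
#' @export
tsvc_flush <- function(state) {
  emitted <- character(0)
  if (!is.null(state$pending)) {
    emitted <- state$pending$label
    state$pending <- NULL
    state <- .tsvc_push(state, emitted)
  }
  list(state = state, emitted = emitted)
}

#' Batch TSVC correction of a label sequence
#'
#' Folds [tsvc_step()] over a finite sequence and flushes, returning a
#' corrected sequence of the same length. Labels only ever change to the
#' immediately preceding accepted label. Applying `tsvc_correct()` to its
#' own output leaves it unchanged.
#'
#' @param labels Character vector or factor of phase labels.
#' @return Corrected labels; a factor with levels `gait_phases()` if the
#'   input was a factor, otherwise a character vector.
#' @export
tsvc_correct <- function(labels) {
  was_factor <- is.factor(labels)
  lab <- as.character(labels)
  out <- character(length(lab))
  k <- 0L
  state <- tsvc_state()
  for (x in lab) {
    res <- tsvc_step(state, x)
    state <- res$state
    ne <- length(res$emitted)
    if (ne > 0) {
      out[(k + 1):(k + ne)] <- res$emitted
      k <- k + ne
    }
  }
  res <- tsvc_flush(state)
  ne <- length(res$emitted)
  if (ne > 0) {
    out[(k + 1):(k + ne)] <- res$emitted
    k <- k + ne
  }
  stopifnot(k == length(lab))
  if (was_factor) phase_factor(out) else out
}

#' Detect gait events from a corrected phase sequence
#'
#' Each transition to the next phase in the cycle marks a gait event:
#' TSw -> LR is initial contact, LR -> PO is mid-stance, PO -> Swing is
#' foot-off, and Swing -> TSw is maximum knee flexion. The event index is
#' the first sample of the new phase. Transitions that do not follow the
#' cycle (possible only in uncorrected streams) are ignored.
#'
#' @param labels Phase label sequence (character or factor).
#' @param index Optional vector of sample indices aligned with `labels`
#'   (e.g. window end indices); defaults to `seq_along(labels)`.
#' @return Tibble with columns `index`, `event`, `from`, `to`.
#' @examples
#' detect_events(c("TSw", "TSw", "LR", "LR", "PO"))
#' @export
detect_events <- function(labels, index = seq_along(labels)) {
  lab <- as.character(labels)
  n <- length(lab)
  if (length(index) != n) abort("`index` must align with `labels`")
  if (n < 2) {
    return(tibble(index = integer(0), event = character(0), from = character(0), to = character(0)))
  }
  prev <- lab[-n]
  cur <- lab[-1]
  change <- which(cur != prev & cur == phase_successor(prev))
  ev_map <- setNames(gait_events()[c(2, 3, 4, 1)], gait_phases())
  # LR->PO = mid_stance, PO->Swing = foot_off, Swing->TSw = max_knee_flexion,
  # TSw->LR = initial_contact; keyed by the phase being left
  tibble(
    index = index[change + 1L],
    event = unname(ev_map[prev[change]]),
    from = prev[change],
    to = cur[change]
  )
}
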