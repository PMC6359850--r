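# shared fixtures, all generated in code

# two-feature toy set separable by a single axis threshold on x1
make_separable_toy <- function(n_per_class = 30, gap = 4, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      x1 = c(rnorm(n_per_class, -gap / 2, 0.5), rnorm(n_per_class, gap / 2, 0.5)),
      x2 = rnorm(2 * n_per_class),
      label = factor(rep(c("LR", "PO"), each = n_per_class), levels = c("LR", "PO"))
    )
  })
}

# small labeled feature table from the simulator (few strides, two classes
# of conditions), for classifier tests that need realistic structure
small_cohort_features <- function(seed = 11, n_subjects = 1,
                                  surfaces = c("LG", "US"),
                                  speeds = c(1.33, 0.6), n_strides = 2) {
  coh <- simulate_preset("training",
    seed = seed, n_subjects = n_subjects,
    surfaces = surfaces, speeds = speeds, n_strides = n_strides
  )
  feats <- extract_features_cohort(coh)
  feats[!is.na(feats$label), ]
}

# clean cyclic phase stream with given run lengths per phase
make_phase_stream <- function(n_strides = 5, run_lengths = c(LR = 12, PO = 12, Swing = 8, TSw = 10)) {
  rep(rep(gait_phases(), times = n_strides), times = rep(unname(run_lengths[gait_phases()]), n_strides))
}

# corrupt a stream with isolated single-instance outliers at safe positions
# (>= 3 clean labels before, clean label after, away from run boundaries)
corrupt_isolated <- function(stream, n_outliers = 5, seed = 1) {
  withr::with_seed(seed, {
    n <- length(stream)
    runs <- rle(stream)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    # candidate positions: at least 4 into a run and at least 2 before its end
    cand <- unlist(lapply(seq_along(starts), function(i) {
      lo <- starts[i] + 4L
      hi <- ends[i] - 2L
      if (hi >= lo) lo:hi else integer(0)
    }))
    cand <- cand[cand > 4 & cand < n]
    pos <- sort(sample(cand, min(n_outliers, length(cand))))
    # enforce spacing so outliers do not interact
    keep <- c(TRUE, diff(pos) > 6)
    pos <- pos[keep]
    out <- stream
    for (p in pos) {
      others <- setdiff(gait_phases(), out[p])
      out[p] <- sample(others, 1)
    }
    list(stream = out, positions = pos)
  })
}
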