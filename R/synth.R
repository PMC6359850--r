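#' Simulation configuration for one synthetic gait recording
#'
#' Configures the stylized gait simulator. One recording is a sequence of
#' `n_strides` strides of one subject walking on one surface at one speed.
#' Surfaces are level ground (`LG`), 7 degree down-slope (`DS`) and up-slope
#' (`US`), and 5 degree right (`RS`) and left (`LS`) cross-slopes; surfaces
#' act as mild additive/gain modifications of the stride templates. Slower
#' speeds lengthen the stride, shrink stance-phase knee motion, and increase
#' inter-stride variability and noise (both scale with
#' `reference speed / speed_mps`, reference 1.33 m/s).
#'
#' @param surface One of `"LG"`, `"DS"`, `"US"`, `"RS"`, `"LS"`.
#' @param speed_mps Walking speed in m/s (> 0); 1.33 is the self-paced
#'   reference.
#' @param n_strides Number of strides (>= 1).
#' @param sample_rate_hz Sampling rate in Hz (default 200).
#' @param noise_sd Additive Gaussian noise standard deviations per channel:
#'   a length-7 vector in channel order (ka, angvel x/y/z, acc x/y/z), or a
#'   single scalar applied to all channels. Units: deg, rad/s, m/s^2.
#' @param variability_scale Nonnegative scale of inter-stride template
#'   jitter (amplitudes, event timing, stride duration); 0 gives identical
#'   strides.
#' @param seed Integer seed; identical configs (including seed) give
#'   bit-identical output.
#' @param event_fractions Named fractions of the stride at which mid-stance
#'   and foot-off occur and near which the swing knee-flexion peak is
#'   centred.
#' @return A `sim_config` list.
#' @examples
#' sim_config(surface = "US", speed_mps = 0.8, n_strides = 5, seed = 42)
#' @export
sim_config <- function(surface = "LG",
                       speed_mps = 1.33,
                       n_strides = 10,
                       sample_rate_hz = 200,
                       noise_sd = c(0.5, 0.05, 0.05, 0.05, 0.25, 0.25, 0.25),
                       variability_scale = 1,
                       seed = 1,
                       event_fractions = c(
                         mid_stance = 0.30,
                         foot_off = 0.60,
                         max_knee_flexion = 0.73
                       )) {
  surface <- match.arg(surface, c("LG", "DS", "US", "RS", "LS"))
  if (!is.numeric(speed_mps) || speed_mps <= 0) abort("`speed_mps` must be positive")
  if (!is.numeric(n_strides) || n_strides < 1) abort("`n_strides` must be >= 1")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) abort("`sample_rate_hz` must be positive")
  if (any(noise_sd < 0)) abort("`noise_sd` must be nonnegative")
  if (variability_scale < 0) abort("`variability_scale` must be nonnegative")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 7)
  if (length(noise_sd) != 7) abort("`noise_sd` must have length 1 or 7")
  fr <- event_fractions
  if (!all(c("mid_stance", "foot_off", "max_knee_flexion") %in% names(fr))) {
    abort("`event_fractions` must name mid_stance, foot_off, max_knee_flexion")
  }
  if (!(0 < fr["mid_stance"] && fr["mid_stance"] < fr["foot_off"] &&
    fr["foot_off"] < fr["max_knee_flexion"] && fr["max_knee_flexion"] < 1)) {
    abort("event fractions must satisfy 0 < mid_stance < foot_off < max_knee_flexion < 1")
  }
  structure(
    list(
      surface = surface, speed_mps = speed_mps, n_strides = as.integer(n_strides),
      sample_rate_hz = sample_rate_hz,
      noise_sd = setNames(as.numeric(noise_sd), gait_channels()),
      variability_scale = variability_scale, seed = as.integer(seed),
      event_fractions = fr
    ),
    class = "sim_config"
  )
}

# reference self-paced speed (m/s) used for speed scalings
.ref_speed <- 1.33

# raised-cosine bump of unit height centred at `center` with half-width `width`
.bump <- function(u, center, width) {
  d <- abs(u - center)
  ifelse(d < width, 0.5 * (1 + cos(pi * d / width)), 0)
}

# asymmetric raised-cosine bump: different half-widths left/right of center
.bump2 <- function(u, center, w_left, w_right) {
  d <- u - center
  ifelse(d < 0, .bump(d, 0, w_left), .bump(d, 0, w_right))
}

# surface-condition template modifiers
.surface_params <- function(surface) {
  switch(surface,
    LG = list(st = 0.0, sw = 0.0, ml = 0.0),
    DS = list(st = -3.0, sw = -2.0, ml = 0.0),
    US = list(st = 4.0, sw = 2.5, ml = 0.0),
    RS = list(st = 1.5, sw = 0.5, ml = 0.45),
    LS = list(st = 1.5, sw = 1.0, ml = -0.45)
  )
}

# deterministic stride template on phase fraction u in [0, 1)
# returns the 7 channels given per-stride effective parameters
.stride_template <- function(u, speed, surface, a_st, a_sw, u_fo, u_mkf) {
  sp <- .surface_params(surface)
  # knee flexion angle (deg): stance flexion wave, plus a swing flexion peak
  # confined to (u_fo, 1) so stance knee motion is set by a_st alone
  ka <- 3 +
    a_st * .bump(u, 0.16, 0.18) +
    a_sw * .bump2(u, u_mkf, (u_mkf - u_fo) * 0.95, (1 - u_mkf) * 0.85)

  # thigh angular velocity; x tied to the knee-angle rate so its zero
  # crossings sit near knee-angle extrema. Returned in rad per unit stride
  # fraction; the caller divides by the stride duration to get rad/s.
  n <- length(u)
  dka <- c(ka[2] - ka[1], (ka[3:n] - ka[1:(n - 2)]) / 2, ka[n] - ka[n - 1])
  angvel_x <- 0.6 * (dka * n) * pi / 180
  angvel_y <- 1.1 * sin(2 * pi * u - 0.4) + 0.35 * sin(4 * pi * u + 0.8)
  angvel_z <- 0.30 * sin(2 * pi * u + 1.1) + sp$ml * 0.4

  # thigh acceleration (m/s^2); z carries gravity during stance
  swing_mid <- (u_fo + 1) / 2
  acc_z <- 9.81 - 3.2 * .bump(u, swing_mid, (1 - u_fo) * 0.55) +
    0.9 * sin(4 * pi * u + 0.3)
  acc_y <- 2.4 * sin(2 * pi * u + 2.3) + 1.6 * .bump(u, u_fo, 0.10) +
    0.5 * sin(6 * pi * u)
  acc_x <- 1.0 * sin(2 * pi * u + 1.7) + sp$ml + 0.3 * sin(4 * pi * u)

  list(
    ka = ka, angvel_x = angvel_x, angvel_y = angvel_y, angvel_z = angvel_z,
    acc_x = acc_x, acc_y = acc_y, acc_z = acc_z
  )
}

#' Simulate a labeled synthetic gait recording
#'
#' Generates `n_strides` concatenated stylized strides of knee flexion angle,
#' triaxial thigh angular velocity and triaxial thigh acceleration, with
#' ground-truth gait events and per-sample phase labels. The templates are
#' qualitative, not biomechanically validated: the knee angle shows a stance
#' flexion wave whose amplitude shrinks at slower speeds and a swing flexion
#' peak near 60 degrees whose maximum defines the max-knee-flexion event; the
#' x-axis angular velocity crosses zero near knee-angle extrema; the z-axis
#' acceleration carries a gravity-scale offset during stance. Stride duration
#' grows as speed drops (about 1.1 s at the 1.33 m/s reference). Inter-stride
#' jitter perturbs amplitudes, event timing and stride duration.
#'
#' @param config A [sim_config()].
#' @return A `gait_recording` list with elements:
#'   * `signal`: a `gait_signal` tibble with columns `time`, `ka`,
#'     `angvel_x/y/z`, `acc_x/y/z`, `label` and attribute `sample_rate_hz`;
#'   * `annotations`: tibble with one row per stride (1-based sample indices
#'     `initial_contact < mid_stance < foot_off < max_knee_flexion <
#'     next_initial_contact`);
#'   * `config`: the configuration used;
#'   * `meta`: list with `recording_id` (settable by cohort generators).
#' @examples
#' rec <- simulate_cohort(sim_config(n_strides = 3, seed = 7))
#' rec$annotations
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config()")
  withr::local_seed(config$seed)

  fs <- config$sample_rate_hz
  speed <- config$speed_mps
  jit <- config$variability_scale * (.ref_speed / speed)
  noise <- config$noise_sd * (.ref_speed / speed)
  fr <- config$event_fractions

  stride_time0 <- 1.1 * sqrt(.ref_speed / speed)
  sp <- .surface_params(config$surface)
  a_st0 <- 2 + 16 * (speed / .ref_speed)^1.2 + sp$st
  a_sw0 <- 55 + 2 * (speed / .ref_speed) + sp$sw

  channels <- gait_channels()
  sig <- setNames(vector("list", 7), channels)
  for (c_ in channels) sig[[c_]] <- vector("list", config$n_strides)
  ann <- vector("list", config$n_strides)
  offset <- 0L

  for (s in seq_len(config$n_strides)) {
    stride_time <- stride_time0 * exp(rnorm(1, 0, 0.04 * jit))
    a_st <- a_st0 * exp(rnorm(1, 0, 0.06 * jit))
    a_sw <- a_sw0 * exp(rnorm(1, 0, 0.03 * jit))
    u_ms <- fr["mid_stance"] + rnorm(1, 0, 0.012 * jit)
    u_fo <- fr["foot_off"] + rnorm(1, 0, 0.012 * jit)
    u_mkf <- fr["max_knee_flexion"] + rnorm(1, 0, 0.012 * jit)
    u_ms <- min(max(u_ms, 0.15), 0.45)
    u_fo <- min(max(u_fo, u_ms + 0.1), 0.80)
    u_mkf <- min(max(u_mkf, u_fo + 0.05), 0.92)

    n_s <- max(as.integer(round(stride_time * fs)), 40L)
    u <- (seq_len(n_s) - 1) / n_s
    tpl <- .stride_template(u, speed, config$surface, a_st, a_sw, u_fo, u_mkf)
    # angvel_x comes back in rad per unit stride fraction -> rad/s
    tpl$angvel_x <- tpl$angvel_x / (n_s / fs)
    for (k in seq_along(channels)) {
      ch <- channels[k]
      v <- tpl[[ch]]
      if (noise[ch] > 0) v <- v + rnorm(n_s, 0, noise[ch])
      sig[[ch]][[s]] <- v
    }

    ic <- offset + 1L
    ms <- offset + as.integer(round(u_ms * n_s)) + 1L
    fo <- offset + as.integer(round(u_fo * n_s)) + 1L
    nic <- offset + n_s + 1L
    # max knee flexion = realized argmax of the (noisy) knee angle in swing
    ka_stride <- sig$ka[[s]]
    rel_fo <- fo - offset
    mkf <- offset + rel_fo - 1L + which.max(ka_stride[rel_fo:n_s])
    if (mkf <= fo) mkf <- fo + 1L
    if (mkf >= nic) mkf <- nic - 1L
    ann[[s]] <- c(
      initial_contact = ic, mid_stance = ms, foot_off = fo,
      max_knee_flexion = mkf, next_initial_contact = nic
    )
    offset <- offset + n_s
  }

  annotations <- as_tibble(do.call(rbind, ann))
  n <- offset
  labels <- label_phases(annotations, n)
  signal <- tibble(time = (seq_len(n) - 1) / fs)
  for (ch in channels) signal[[ch]] <- unlist(sig[[ch]], use.names = FALSE)
  signal$label <- labels
  attr(signal, "sample_rate_hz") <- fs
  class(signal) <- c("gait_signal", class(signal))

  structure(
    list(
      signal = signal, annotations = annotations, config = config,
      meta = list(recording_id = "rec1")
    ),
    class = "gait_recording"
  )
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> %s | %s, %.2f m/s, %d strides, %d samples @ %g Hz\n",
    x$meta$recording_id, x$config$surface, x$config$speed_mps,
    x$config$n_strides, nrow(x$signal), x$config$sample_rate_hz
  ))
  invisible(x)
}

#' Simulate a multi-subject cohort preset
#'
#' Two presets mirror the study design the simulator emulates: `"training"`
#' (30 virtual subjects, 4 speeds (self-paced ~ N(1.33, 0.04), 0.8, 0.6,
#' 0.4 m/s), 5 surfaces, 10 strides per condition) and `"validation"` (12
#' virtual subjects, self-paced only with a larger speed spread
#' ~ N(1.41, 0.34), 5 surfaces, 6 strides). Any dimension can be overridden
#' to run reduced cohorts.
#'
#' @param preset `"training"` or `"validation"`.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param n_subjects,surfaces,speeds,n_strides Optional overrides of the
#'   preset dimensions. `speeds` applies to the training preset's fixed
#'   speeds; the self-paced speed is always drawn per subject.
#' @param ... Further arguments passed to [sim_config()] (e.g. `noise_sd`,
#'   `variability_scale`).
#' @return A `gait_cohort`: a list of `gait_recording`s, one per
#'   subject x surface x speed condition, each with metadata (`subject`,
#'   `surface`, `speed_mps`, `recording_id`).
#' @examples
#' coh <- simulate_preset("validation", seed = 3, n_subjects = 2,
#'                        surfaces = "LG", n_strides = 2)
#' length(coh)
#' @export
simulate_preset <- function(preset = c("training", "validation"),
                            seed = 1,
                            n_subjects = NULL,
                            surfaces = NULL,
                            speeds = NULL,
                            n_strides = NULL,
                            ...) {
  preset <- match.arg(preset)
  surfaces <- surfaces %||% c("LG", "DS", "US", "RS", "LS")
  if (preset == "training") {
    n_subjects <- n_subjects %||% 30L
    n_strides <- n_strides %||% 10L
    fixed_speeds <- speeds %||% c(NA, 0.8, 0.6, 0.4) # NA = self-paced draw
    sp_mean <- 1.33
    sp_sd <- 0.04
  } else {
    n_subjects <- n_subjects %||% 12L
    n_strides <- n_strides %||% 6L
    fixed_speeds <- speeds %||% NA
    sp_mean <- 1.41
    sp_sd <- 0.34
  }

  withr::local_seed(seed)
  n_rec <- n_subjects * length(surfaces) * length(fixed_speeds)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n_rec)
  sp_speed <- pmax(rnorm(n_subjects, sp_mean, sp_sd), 0.3)

  cohort <- vector("list", n_rec)
  i <- 0L
  for (subj in seq_len(n_subjects)) {
    for (surf in surfaces) {
      for (v in fixed_speeds) {
        i <- i + 1L
        speed <- if (is.na(v)) sp_speed[subj] else v
        cfg <- sim_config(
          surface = surf, speed_mps = speed, n_strides = n_strides,
          seed = rec_seeds[i], ...
        )
        rec <- simulate_cohort(cfg)
        rec$meta <- list(
          recording_id = sprintf("S%02d_%s_%s", subj, surf,
            if (is.na(v)) "SP" else sprintf("%.1f", v)
          ),
          subject = subj, surface = surf, speed_mps = speed
        )
        cohort[[i]] <- rec
      }
    }
  }
  structure(cohort, class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d recordings\n", length(x)))
  invisible(x)
}

#' Read and write gait signal CSVs with annotation sidecars
#'
#' The CSV dialect has one row per sample with header columns `time`, `ka`,
#' `angvel_x`, `angvel_y`, `angvel_z`, `acc_x`, `acc_y`, `acc_z`, `label`
#' (empty when unlabeled). `write_gait_csv()` also writes a JSON sidecar
#' (`<path>.json`) holding the stride annotations and the simulation
#' configuration, which `read_gait_csv()` restores when present.
#'
#' @param recording A `gait_recording` (or a list with at least `$signal`).
#' @param path CSV file path.
#' @return `write_gait_csv()` returns `path` invisibly; `read_gait_csv()`
#'   returns a `gait_recording`.
#' @export
write_gait_csv <- function(recording, path) {
  sig <- as.data.frame(recording$signal)
  sig$label <- as.character(sig$label)
  sig$label[is.na(sig$label)] <- ""
  write.csv(sig, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    sample_rate_hz = attr(recording$signal, "sample_rate_hz") %||%
      recording$config$sample_rate_hz,
    annotations = recording$annotations,
    config = if (!is.null(recording$config)) unclass(recording$config),
    meta = recording$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_gait_csv
#' @export
read_gait_csv <- function(path) {
  sig <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", gait_channels())
  missing_c <- setdiff(need, names(sig))
  if (length(missing_c) > 0) {
    abort(paste0("gait CSV is missing column(s): ", paste(missing_c, collapse = ", ")))
  }
  sig <- as_tibble(sig)
  if ("label" %in% names(sig)) {
    lab <- as.character(sig$label)
    lab[lab == ""] <- NA_character_
    sig$label <- phase_factor(lab)
  }
  annotations <- NULL
  config <- NULL
  meta <- list(recording_id = basename(path))
  sidecar_path <- paste0(path, ".json")
  fs <- NULL
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    fs <- sidecar$sample_rate_hz
    if (!is.null(sidecar$annotations)) annotations <- as_tibble(sidecar$annotations)
    if (!is.null(sidecar$meta)) meta <- sidecar$meta
    config <- sidecar$config
  }
  if (is.null(fs)) {
    dt <- diff(sig$time)
    fs <- 1 / stats::median(dt)
  }
  attr(sig, "sample_rate_hz") <- fs
  class(sig) <- c("gait_signal", class(sig))
  structure(
    list(signal = sig, annotations = annotations, config = config, meta = meta),
    class = "gait_recording"
  )
}
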