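#' Simulator parameters for labelled motion recordings
#'
#' Defines the statistical conditions the simulator emulates: non-fall
#' activities of daily living stay strictly inside the sensor envelopes
#' (|accel| < `accel_bound`, |gyro| < `gyro_bound` on every axis), while a
#' fall adds a short transient whose gyroscope peak exceeds the gyro envelope
#' by a large margin (`fall_spike_factor` times the bound).
#'
#' @param rate sampling rate, samples/second.
#' @param duration recording length, seconds.
#' @param accel_bound ADL accelerometer envelope, m/s^2.
#' @param gyro_bound ADL gyroscope envelope, rad/s.
#' @param class_amplitudes named fractions of the envelope, in (0,1), for the
#'   five non-fall classes; ordered so the classes are mutually
#'   distinguishable in power-feature space.
#' @param fall_spike_factor fall gyro peak as a multiple (> 1) of `gyro_bound`.
#' @param fall_spike_width duration of the fall transient, seconds.
#' @param noise_sd white-noise standard deviations, `c(accel, gyro)`, in
#'   channel units (m/s^2 and rad/s).
#' @param seed base integer seed; per-recording seeds are derived from it.
#' @return A list of class `motion_model_params`.
#' @export
motion_model_params <- function(rate = 10,
                                duration = 5,
                                accel_bound = 1.5,
                                gyro_bound = 120,
                                class_amplitudes = c(still = 0,
                                                     lying_down = 0.2,
                                                     sitting_up = 0.4,
                                                     bending = 0.6,
                                                     standing_up = 0.8),
                                fall_spike_factor = 2.5,
                                fall_spike_width = 0.5,
                                noise_sd = c(accel = 0.05, gyro = 2),
                                seed = 0L) {
  if (rate <= 0 || duration <= 0) {
    fd_stop("rate and duration must be positive", "falldetect_parameter_error")
  }
  nonfall <- setdiff(MOTION_CLASSES, "fall")
  if (!all(nonfall %in% names(class_amplitudes))) {
    fd_stop("class_amplitudes must name every non-fall class",
            "falldetect_parameter_error")
  }
  if (any(class_amplitudes >= 1) || any(class_amplitudes < 0)) {
    fd_stop("non-fall class amplitudes must lie in [0, 1)",
            "falldetect_parameter_error")
  }
  if (fall_spike_factor <= 1) {
    fd_stop("fall_spike_factor must exceed 1 (falls break the gyro envelope)",
            "falldetect_parameter_error")
  }
  if (length(noise_sd) != 2L || any(noise_sd < 0)) {
    fd_stop("noise_sd must be two non-negative values c(accel, gyro)",
            "falldetect_parameter_error")
  }
  structure(list(rate = rate, duration = duration,
                 accel_bound = accel_bound, gyro_bound = gyro_bound,
                 class_amplitudes = class_amplitudes[nonfall],
                 fall_spike_factor = fall_spike_factor,
                 fall_spike_width = fall_spike_width,
                 noise_sd = stats::setNames(as.numeric(noise_sd),
                                            c("accel", "gyro")),
                 seed = as.integer(seed)),
            class = "motion_model_params")
}

# Per-class channel mixing: each non-fall class excites the six channels in a
# distinct fixed pattern (fractions of the class amplitude), so classes differ
# in direction as well as magnitude of their power signature.
CLASS_CHANNEL_PATTERN <- rbind(
  still       = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
  lying_down  = c(0.6, 0.2, 1.0, 0.8, 1.0, 0.3),
  sitting_up  = c(1.0, 0.5, 0.2, 1.0, 0.6, 0.2),
  standing_up = c(0.3, 1.0, 0.5, 0.2, 1.0, 0.7),
  bending     = c(0.8, 0.3, 0.6, 0.5, 0.3, 1.0)
)
colnames(CLASS_CHANNEL_PATTERN) <- c("ax", "ay", "az", "gx", "gy", "gz")

# Raised-cosine bump of given peak amplitude, centred in [t0, t0+width].
raised_cosine <- function(t, t0, width, amplitude) {
  s <- numeric(length(t))
  inside <- t >= t0 & t <= t0 + width
  s[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / width))
  s
}

# Deterministic per-recording seed derived from (base seed, class, trial),
# kept below 2^31 - 1. Arithmetic in doubles to avoid integer overflow.
derive_seed <- function(base, class_index, trial) {
  m <- 2147483647
  h <- (as.numeric(base) %% m)
  h <- (h * 48271 + class_index * 97561 + trial * 1009 + 12345) %% m
  as.integer(h)
}

#' Generate one synthetic motion recording
#'
#' `still` is zero-mean sensor noise only. Each other non-fall class is one
#' smooth raised-cosine bump per channel — class-specific amplitude and
#' channel pattern — plus noise, clipped to 99.5% of the envelope so every
#' sample respects the ADL bounds. `fall` is a moderate non-fall baseline plus
#' a transient gyroscope spike of width `fall_spike_width` whose peak exceeds
#' `fall_spike_factor * gyro_bound` on one axis.
#'
#' @param cls a motion class (see [MOTION_CLASSES]).
#' @param params a [motion_model_params()] object; `params$seed` makes the
#'   output fully deterministic.
#' @return A [signal_window].
#' @examples
#' w <- generate_motion("fall", motion_model_params(seed = 1))
#' max(abs(c(w$gx, w$gy, w$gz)))  # >= 300 rad/s with defaults
#' @export
generate_motion <- function(cls, params = motion_model_params()) {
  cls <- as_motion_class(cls)
  p <- params
  n <- round(p$rate * p$duration)
  if (n < 2) {
    fd_stop("duration * rate must give at least 2 samples",
            "falldetect_parameter_error")
  }
  t <- seq(0, by = 1 / p$rate, length.out = n)
  bounds <- c(ax = p$accel_bound, ay = p$accel_bound, az = p$accel_bound,
              gx = p$gyro_bound, gy = p$gyro_bound, gz = p$gyro_bound)
  sds <- c(rep(p$noise_sd[["accel"]], 3), rep(p$noise_sd[["gyro"]], 3))
  names(sds) <- names(bounds)

  withr::local_seed(p$seed)
  base_cls <- if (cls == "fall") "bending" else cls
  amp <- if (cls == "fall") 0.5 else p$class_amplitudes[[base_cls]]
  pattern <- CLASS_CHANNEL_PATTERN[base_cls, ]

  # ADL bump occupies the middle half of the window
  bump_t0 <- 0.25 * p$duration
  bump_width <- 0.5 * p$duration
  chans <- lapply(names(bounds), function(ch) {
    s <- raised_cosine(t, bump_t0, bump_width, amp * pattern[[ch]] * bounds[[ch]])
    s <- s + stats::rnorm(n, sd = sds[[ch]])
    # hard envelope: ADL samples (and the fall baseline outside the spike)
    # never touch the camera-trigger thresholds
    pmin(pmax(s, -0.995 * bounds[[ch]]), 0.995 * bounds[[ch]])
  })
  names(chans) <- names(bounds)

  if (cls == "fall") {
    # transient spike on gx, 5% above the required peak so noise cannot pull
    # the maximum back under fall_spike_factor * gyro_bound; rescaled so the
    # peak SAMPLE (not the continuous-time peak) reaches the target even when
    # the bump centre falls between samples
    spike_t0 <- 0.6 * p$duration
    spike <- raised_cosine(t, spike_t0, p$fall_spike_width, 1)
    if (max(spike) <= 0) {  # width below the sample spacing: one-sample spike
      spike[which.min(abs(t - (spike_t0 + p$fall_spike_width / 2)))] <- 1
    }
    spike <- spike * (1.05 * p$fall_spike_factor * p$gyro_bound / max(spike))
    chans$gx <- chans$gx + spike
  }

  signal_window(t, chans$ax, chans$ay, chans$az,
                chans$gx, chans$gy, chans$gz, rate = p$rate)
}

#' Generate a labelled corpus of motion recordings
#'
#' Produces `trials_per_class` recordings for each of the six classes, with
#' per-recording seeds derived deterministically from `params$seed`, so the
#' same call always yields the same corpus.
#'
#' @param trials_per_class recordings per class (the reference protocol uses
#'   40 trials per class).
#' @param params a [motion_model_params()] object.
#' @return A list of recordings, each a list with `id`, `window`, `label`;
#'   suitable for [write_motion_csv()].
#' @export
generate_corpus <- function(trials_per_class = 40,
                            params = motion_model_params()) {
  if (trials_per_class < 1) {
    fd_stop("trials_per_class must be >= 1", "falldetect_parameter_error")
  }
  out <- vector("list", 6L * trials_per_class)
  i <- 0L
  for (ci in seq_along(MOTION_CLASSES)) {
    cls <- MOTION_CLASSES[ci]
    for (trial in seq_len(trials_per_class)) {
      p <- params
      p$seed <- derive_seed(params$seed, ci, trial)
      i <- i + 1L
      out[[i]] <- list(id = sprintf("%s_%03d", cls, trial),
                       window = generate_motion(cls, p),
                       label = cls)
    }
  }
  out
}

#' Generate a synthetic grayscale frame sequence
#'
#' Emulates what the wearable camera sees: during ADLs the scene luminance
#' drifts gradually, keeping every consecutive-frame percentage difference
#' under the 7% fall threshold; during a fall one abrupt scene shift pushes at
#' least one consecutive difference well above it.
#'
#' @param is_fall logical; abrupt (fall) or gradual (non-fall) sequence.
#' @param n_frames number of frames, at least 2.
#' @param shape `c(rows, cols)` in pixels.
#' @param seed integer seed.
#' @return A [frame_sequence] of `n_frames` matrices with intensities in
#'   \[0, 255\].
#' @export
generate_frames <- function(is_fall, n_frames = 10, shape = c(32, 32),
                            seed = 0L) {
  if (n_frames < 2) {
    fd_stop("n_frames must be >= 2", "falldetect_parameter_error")
  }
  withr::local_seed(as.integer(seed))
  nr <- shape[1]; nc <- shape[2]
  # static scene: a smooth diagonal luminance gradient
  base <- outer(seq(60, 180, length.out = nr),
                seq(0, 40, length.out = nc), "+")
  drift_step <- 255 * 0.02        # ~2% gradual change per frame
  jump <- 255 * 0.25              # one abrupt ~25% scene shift on a fall
  jump_at <- max(2L, ceiling(n_frames / 2))
  frames <- vector("list", n_frames)
  offset <- 0
  for (i in seq_len(n_frames)) {
    if (i > 1) offset <- offset + drift_step * sample(c(-1, 1), 1)
    f <- base + offset
    if (is_fall && i >= jump_at) f <- f + jump
    f <- f + matrix(stats::rnorm(nr * nc, sd = 1), nr, nc)
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  frame_sequence(frames)
}
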