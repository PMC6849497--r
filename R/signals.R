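#' Motion classes
#'
#' The six motion classes the system distinguishes: five activities of daily
#' living (ADLs) and `fall`. `fall` is the only class mapping to the binary
#' fall indicator 1.
#'
#' @format Character vector of length six, in the fixed enumeration order used
#'   for deterministic tie-breaking throughout the package.
#' @export
MOTION_CLASSES <- c("still", "lying_down", "sitting_up", "standing_up",
                    "bending", "fall")

#' Validate a motion-class label
#'
#' @param x character scalar.
#' @return `x`, unchanged, if it is one of [MOTION_CLASSES].
#' @export
as_motion_class <- function(x) {
  if (!is.character(x) || length(x) != 1L || !(x %in% MOTION_CLASSES)) {
    fd_stop(sprintf("unknown motion class: %s", paste(format(x), collapse = ", ")),
            "falldetect_parameter_error")
  }
  x
}

# classed conditions so the CLI can map error kinds to exit codes
fd_stop <- function(message, class) {
  stop(structure(class = c(class, "falldetect_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Construct a signal window
#'
#' A signal window is one fixed-rate six-channel recording segment — three
#' accelerometer axes (m/s\eqn{^2}) and three gyroscope axes (rad/s) — and is
#' the unit of classification: a whole recording is classified at once.
#'
#' @param t sample times in seconds from recording start; strictly increasing,
#'   uniformly spaced at `1/rate` (tolerance 1e-6 s).
#' @param ax,ay,az accelerometer samples, m/s^2.
#' @param gx,gy,gz gyroscope samples, rad/s.
#' @param rate sampling rate in samples/second (default 10, the wearable
#'   unit's nominal rate).
#' @return An object of class `signal_window`: a list with the six channel
#'   vectors, `t`, and `rate`.
#' @examples
#' w <- signal_window(t = seq(0, 0.9, by = 0.1),
#'                    ax = rnorm(10), ay = rnorm(10), az = rnorm(10),
#'                    gx = rnorm(10), gy = rnorm(10), gz = rnorm(10))
#' @export
signal_window <- function(t, ax, ay, az, gx, gy, gz, rate = 10) {
  chans <- list(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  n <- length(t)
  if (n < 2L) {
    fd_stop("a signal window needs at least 2 samples", "falldetect_data_error")
  }
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n)) {
    fd_stop("all six channels must match the length of t", "falldetect_data_error")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    fd_stop("rate must be a positive scalar", "falldetect_parameter_error")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    fd_stop("timestamps must be strictly increasing", "falldetect_data_error")
  }
  if (any(abs(dt - 1 / rate) > 1e-6)) {
    fd_stop(sprintf("timestamps must be uniformly spaced at 1/%g s", rate),
            "falldetect_data_error")
  }
  structure(c(chans, list(rate = rate)), class = "signal_window")
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("<signal_window> %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$rate, length(x$t) / x$rate))
  cat(sprintf("  |accel| max %.3f m/s^2, |gyro| max %.3f rad/s\n",
              max(abs(c(x$ax, x$ay, x$az))), max(abs(c(x$gx, x$gy, x$gz)))))
  invisible(x)
}

#' @export
as.data.frame.signal_window <- function(x, ...) {
  data.frame(t = x$t, ax = x$ax, ay = x$ay, az = x$az,
             gx = x$gx, gy = x$gy, gz = x$gz)
}

MOTION_CSV_COLUMNS <- c("recording_id", "t", "ax", "ay", "az", "gx", "gy", "gz")

#' Read labelled motion recordings from CSV
#'
#' Reads a comma-separated motion file (columns
#' `recording_id,t,ax,ay,az,gx,gy,gz` plus an optional `label` column) holding
#' one or more recordings keyed by `recording_id`. Samples within a recording
#' are returned in time order.
#'
#' @param path path to the CSV file.
#' @return A list with one element per recording id (in order of first
#'   appearance), each a list with components `window` ([signal_window]),
#'   `label` (a motion class, or `NULL` when absent) and `id`.
#' @seealso [write_motion_csv()]
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path)) {
    fd_stop(sprintf("file not found: %s", path), "falldetect_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MOTION_CSV_COLUMNS, names(df))
  if (length(missing)) {
    fd_stop(sprintf("motion CSV is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            "falldetect_format_error")
  }
  has_label <- "label" %in% names(df)
  ids <- unique(df$recording_id)
  lapply(ids, function(id) {
    rec <- df[df$recording_id == id, , drop = FALSE]
    rec <- rec[order(rec$t), , drop = FALSE]
    if (any(diff(rec$t) <= 0)) {
      fd_stop(sprintf("non-monotone time in recording '%s'", id),
              "falldetect_data_error")
    }
    # sampling rate recovered from the median spacing of the stored timestamps
    rate <- 1 / stats::median(diff(rec$t))
    w <- signal_window(rec$t, rec$ax, rec$ay, rec$az,
                       rec$gx, rec$gy, rec$gz, rate = rate)
    label <- NULL
    if (has_label) {
      lab <- unique(rec$label[!is.na(rec$label) & rec$label != ""])
      if (length(lab) > 1L) {
        fd_stop(sprintf("conflicting labels in recording '%s'", id),
                "falldetect_data_error")
      }
      if (length(lab) == 1L) label <- as_motion_class(lab)
    }
    list(id = as.character(id), window = w, label = label)
  })
}

#' Write motion recordings to CSV
#'
#' Inverse of [read_motion_csv()]: values survive a round trip to well under
#' 1e-9 absolute error (15 significant digits are written).
#'
#' @param recordings non-empty list of recordings; each element a list with a
#'   `window` ([signal_window]), an optional `label`, and an optional `id`
#'   (defaults to `rec<index>`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(recordings, path) {
  if (!is.list(recordings) || length(recordings) == 0L) {
    fd_stop("recordings must be a non-empty list", "falldetect_parameter_error")
  }
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    w <- rec$window
    if (!inherits(w, "signal_window")) {
      fd_stop(sprintf("recording %d has no signal_window", i),
              "falldetect_parameter_error")
    }
    id <- if (!is.null(rec$id)) as.character(rec$id) else sprintf("rec%d", i)
    lab <- if (!is.null(rec$label)) as_motion_class(rec$label) else ""
    data.frame(recording_id = id,
               t = sprintf("%.15g", w$t),
               ax = sprintf("%.15g", w$ax), ay = sprintf("%.15g", w$ay),
               az = sprintf("%.15g", w$az), gx = sprintf("%.15g", w$gx),
               gy = sprintf("%.15g", w$gy), gz = sprintf("%.15g", w$gz),
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fd_stop(sprintf("cannot write to %s", path), "falldetect_io_error")
  invisible(path)
}
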