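I_MAX <- 255

#' Construct a frame sequence
#'
#' An ordered sequence of grayscale frames with a common shape, intensities
#' in \[0, 255\].
#'
#' @param frames list of numeric matrices (>= 2), all the same dimensions.
#' @return Object of class `frame_sequence` (the validated list).
#' @export
frame_sequence <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L) {
    fd_stop("a frame sequence needs at least 2 frames", "falldetect_parameter_error")
  }
  dims <- lapply(frames, dim)
  if (any(!vapply(frames, is.matrix, logical(1))) ||
      any(vapply(dims, is.null, logical(1)))) {
    fd_stop("frames must be numeric matrices", "falldetect_data_error")
  }
  ref <- dims[[1]]
  if (any(!vapply(dims, function(d) identical(d, ref), logical(1)))) {
    fd_stop("all frames must share one shape", "falldetect_data_error")
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > I_MAX) {
    fd_stop("frame intensities must lie in [0, 255]", "falldetect_data_error")
  }
  structure(frames, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d px\n", length(x), d[1], d[2]))
  invisible(x)
}

#' Percentage difference between two frames
#'
#' The visual classifier's statistic: the mean absolute pixel difference
#' normalised by the full intensity range, as a percent —
#' `100 * mean(|a - b|) / 255`. Bounded in \[0, 100\] and independent of the
#' frame shape, which keeps the 7% fall threshold meaningful for any
#' resolution.
#'
#' @param a,b grayscale frames (numeric matrices of the same shape),
#'   intensities in \[0, 255\].
#' @return Percent difference in \[0, 100\].
#' @export
frame_difference <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    fd_stop("frames differ in shape", "falldetect_data_error")
  }
  100 * mean(abs(a - b)) / I_MAX
}

#' Visual fall classification by frame differencing
#'
#' A fall shows as an abrupt change in the scene the wearable camera records,
#' while ADLs change it only gradually. The classifier flags a fall (returns
#' 1) iff any consecutive-frame [frame_difference()] strictly exceeds the
#' threshold.
#'
#' @param seq a [frame_sequence].
#' @param threshold_pct fall threshold in percent (default 7, the empirically
#'   determined value).
#' @return Integer flag: 1 for fall, 0 otherwise.
#' @export
visual_classify <- function(seq, threshold_pct = 7) {
  if (!inherits(seq, "frame_sequence")) seq <- frame_sequence(seq)
  for (i in seq_len(length(seq) - 1L)) {
    if (frame_difference(seq[[i]], seq[[i + 1L]]) > threshold_pct) return(1L)
  }
  0L
}

#' Camera-trigger thresholds
#'
#' The envelopes beyond which the camera wakes from idle and starts
#' recording: ADL motions stay within ±120 rad/s and ±1.5 m/s^2 on every
#' axis, so any sample outside either envelope signals a likely fall.
#'
#' @param gyro_limit rad/s (default 120).
#' @param accel_limit m/s^2 (default 1.5).
#' @return List of class `trigger_thresholds`.
#' @export
trigger_thresholds <- function(gyro_limit = 120, accel_limit = 1.5) {
  if (gyro_limit <= 0 || accel_limit <= 0) {
    fd_stop("trigger thresholds must be strictly positive",
            "falldetect_parameter_error")
  }
  structure(list(gyro_limit = gyro_limit, accel_limit = accel_limit),
            class = "trigger_thresholds")
}

#' Should the camera be recording?
#'
#' TRUE iff any gyroscope sample exceeds `gyro_limit` in magnitude or any
#' accelerometer sample exceeds `accel_limit` (strictly greater than).
#'
#' @param w a [signal_window].
#' @param th a [trigger_thresholds()] object.
#' @return Logical scalar.
#' @export
camera_trigger <- function(w, th = trigger_thresholds()) {
  max(abs(c(w$gx, w$gy, w$gz))) > th$gyro_limit ||
    max(abs(c(w$ax, w$ay, w$az))) > th$accel_limit
}

# ---- frame file I/O ---------------------------------------------------------

# plain (P2, ASCII) PGM: the text-friendly grayscale interchange format
read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2") {
    fd_stop(sprintf("not a plain (P2) PGM file: %s", path),
            "falldetect_format_error")
  }
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != nr * nc) {
    fd_stop(sprintf("PGM pixel count mismatch in %s", path),
            "falldetect_format_error")
  }
  matrix(px * (I_MAX / maxval), nrow = nr, ncol = nc, byrow = TRUE)
}

write_pgm <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(frame), nrow(frame)), "255"), con)
  apply_rows <- apply(round(frame), 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

# Rec. 601 luma weights for colour -> grayscale
LUMA <- c(0.299, 0.587, 0.114)

read_frame_file <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      img <- LUMA[1] * img[, , 1] + LUMA[2] * img[, , 2] + LUMA[3] * img[, , 3]
    }
    return(img * I_MAX)
  }
  fd_stop(sprintf("unsupported frame format: %s", path),
          "falldetect_format_error")
}

#' Read a frame sequence from a directory
#'
#' Loads all `.png` and `.pgm` files in `dir` in lexicographic order. Colour
#' PNGs are converted to grayscale by standard luma weighting; intensities
#' are scaled to \[0, 255\].
#'
#' @param dir directory containing the frames.
#' @return A [frame_sequence].
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|pgm)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) < 2L) {
    fd_stop(sprintf("need at least 2 frame files in %s", dir),
            "falldetect_data_error")
  }
  frame_sequence(lapply(files, read_frame_file))
}

#' Write a frame sequence as plain PGM files
#'
#' @param seq a [frame_sequence].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_frames <- function(seq, dir) {
  if (!inherits(seq, "frame_sequence")) seq <- frame_sequence(seq)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq)) {
    write_pgm(seq[[i]], file.path(dir, sprintf("frame_%04d.pgm", i)))
  }
  invisible(dir)
}
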