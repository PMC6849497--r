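FEATURE_NAMES <- c("p_ax", "p_ay", "p_az", "p_gx", "p_gy", "p_gz")

#' Extract the 6-D signal-power feature vector
#'
#' The feature of each channel is its signal power over the whole window: the
#' mean of the squared samples. Mean-square (rather than sum-of-squares) makes
#' the feature invariant to window length, so recordings of different
#' durations live in the same 6-D feature space. No detrending or gravity
#' removal is applied.
#'
#' @param w a [signal_window].
#' @return Named numeric vector `p_ax, p_ay, p_az` ((m/s^2)^2) and
#'   `p_gx, p_gy, p_gz` ((rad/s)^2); all entries non-negative.
#' @examples
#' w <- generate_motion("sitting_up", motion_model_params(seed = 3))
#' extract_features(w)
#' @export
extract_features <- function(w) {
  if (!inherits(w, "signal_window")) {
    fd_stop("extract_features expects a signal_window", "falldetect_parameter_error")
  }
  chans <- list(w$ax, w$ay, w$az, w$gx, w$gy, w$gz)
  if (any(vapply(chans, length, integer(1)) == 0L)) {
    fd_stop("empty channel in signal window", "falldetect_data_error")
  }
  stats::setNames(vapply(chans, function(x) mean(x^2), numeric(1)),
                  FEATURE_NAMES)
}

#' Feature table for a labelled corpus
#'
#' Applies [extract_features()] to every recording, giving the table that
#' both classifiers train on.
#'
#' @param corpus list of recordings (`id`, `window`, optional `label`), as
#'   returned by [generate_corpus()] or [read_motion_csv()].
#' @return A data frame with `recording_id`, the six power features, and a
#'   `label` column (`NA` where a recording is unlabelled).
#' @export
corpus_features <- function(corpus) {
  feats <- t(vapply(corpus, function(r) extract_features(r$window),
                    numeric(6)))
  labels <- vapply(corpus, function(r) {
    if (is.null(r$label)) NA_character_ else r$label
  }, character(1))
  ids <- vapply(seq_along(corpus), function(i) {
    if (is.null(corpus[[i]]$id)) sprintf("rec%d", i) else corpus[[i]]$id
  }, character(1))
  out <- data.frame(recording_id = ids, feats, label = labels,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
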