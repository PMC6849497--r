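#' Binary fall indicator of a motion class
#'
#' @param cls a motion class.
#' @return 1L iff `cls` is `"fall"`, else 0L.
#' @export
to_fall_flag <- function(cls) {
  as.integer(as_motion_class(cls) == "fall")
}

#' Three-input majority gate
#'
#' The fusion rule combining the k-NN, naive Bayes and visual votes: the
#' system declares a fall iff at least two of the three binary flags are 1.
#'
#' @param knn_flag,nb_flag,visual_flag binary flags (0 or 1).
#' @return 1L or 0L.
#' @export
fuse <- function(knn_flag, nb_flag, visual_flag) {
  flags <- c(knn_flag, nb_flag, visual_flag)
  if (!all(flags %in% c(0L, 1L))) {
    fd_stop("fuse expects binary flags", "falldetect_parameter_error")
  }
  as.integer(sum(flags) >= 2L)
}

#' Run the full detection pipeline on one recording
#'
#' Extracts the 6-D power features, runs both sensor classifiers, checks the
#' camera trigger, runs the visual classifier when the camera was triggered
#' and frames are available, and fuses the three binary votes through the
#' majority gate. When the camera stays idle (or frames are missing despite a
#' trigger, which logs a warning) the visual vote is fixed at 0, so a fall
#' verdict then needs both sensor classifiers to agree.
#'
#' @param w a [signal_window].
#' @param knn_model list with `train` (a [training_set]) and `k`, e.g. from
#'   [train_models()].
#' @param nb_model a `class_stats` object from [fit_gaussian_nb()].
#' @param frames optional [frame_sequence] recorded alongside `w`.
#' @param thresholds a [trigger_thresholds()] object.
#' @param visual_threshold percent threshold of the visual classifier.
#' @return Object of class `detection_result`: list with the predicted
#'   classes, the three flags, `camera_was_triggered`, and the `fused`
#'   verdict.
#' @export
detect <- function(w, knn_model, nb_model, frames = NULL,
                   thresholds = trigger_thresholds(), visual_threshold = 7) {
  f <- extract_features(w)
  knn_class <- knn_classify(knn_model$train, f, knn_model$k)
  nb_class <- nb_classify(f, nb_model)
  knn_flag <- to_fall_flag(knn_class)
  nb_flag <- to_fall_flag(nb_class)
  triggered <- camera_trigger(w, thresholds)
  visual_flag <- 0L
  if (triggered) {
    if (is.null(frames)) {
      warning("camera triggered but no frames available; ",
              "visual vote fixed at 0 (degraded two-classifier mode)",
              call. = FALSE)
    } else {
      visual_flag <- visual_classify(frames, visual_threshold)
    }
  }
  structure(list(knn_class = knn_class, nb_class = nb_class,
                 knn_flag = knn_flag, nb_flag = nb_flag,
                 visual_flag = visual_flag,
                 camera_was_triggered = triggered,
                 fused = fuse(knn_flag, nb_flag, visual_flag)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> fused=%d (knn=%d nb=%d visual=%d, camera %s)\n",
              x$fused, x$knn_flag, x$nb_flag, x$visual_flag,
              if (x$camera_was_triggered) "triggered" else "idle"))
  invisible(x)
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative trial counts: true/false
#'   positives/negatives, where positive means a fall was declared.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    fd_stop("confusion counts must be non-negative integers",
            "falldetect_parameter_error")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Tally fused verdicts against ground truth
#'
#' @param results list of `detection_result` objects, or an integer vector of
#'   fused 0/1 verdicts.
#' @param truth binary vector (1 = fall) of the same length.
#' @return A [confusion_counts()] object; counts always total
#'   `length(truth)`.
#' @export
evaluate <- function(results, truth) {
  pred <- if (is.list(results)) {
    vapply(results, function(r) r$fused, integer(1))
  } else {
    as.integer(results)
  }
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    fd_stop("predictions and truth differ in length", "falldetect_data_error")
  }
  confusion_counts(tp = sum(pred == 1L & truth == 1L),
                   tn = sum(pred == 0L & truth == 0L),
                   fp = sum(pred == 1L & truth == 0L),
                   fn = sum(pred == 0L & truth == 1L))
}

#' Sensitivity (true-positive rate)
#'
#' `100 * TP / (TP + FN)`: the ability to detect a fall when one occurred.
#'
#' @param c a [confusion_counts()] object.
#' @return Percent in \[0, 100\] (unrounded).
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) {
    fd_stop("sensitivity undefined: no positive trials", "falldetect_metric_error")
  }
  100 * c$tp / (c$tp + c$fn)
}

#' Specificity (true-negative rate)
#'
#' `100 * TN / (TN + FP)`: the ability to stay silent when no fall occurred.
#'
#' @param c a [confusion_counts()] object.
#' @return Percent in \[0, 100\] (unrounded).
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) {
    fd_stop("specificity undefined: no negative trials", "falldetect_metric_error")
  }
  100 * c$tn / (c$tn + c$fp)
}

#' Overall accuracy
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c a [confusion_counts()] object.
#' @return Percent in \[0, 100\] (unrounded).
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) {
    fd_stop("accuracy undefined: no trials", "falldetect_metric_error")
  }
  100 * (c$tp + c$tn) / total
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Metric summary of a confusion table
#'
#' Reports raw counts, exact fractions, and the one-decimal rounded percents
#' used for human-readable reporting.
#'
#' @param c a [confusion_counts()] object.
#' @return List with `counts`, `sensitivity`, `specificity`, `accuracy`
#'   (exact percents) and `rounded` (one-decimal versions).
#' @export
metric_report <- function(c) {
  m <- list(sensitivity = sensitivity(c), specificity = specificity(c),
            accuracy = accuracy(c))
  list(counts = c[c("tp", "tn", "fp", "fn")],
       sensitivity = m$sensitivity, specificity = m$specificity,
       accuracy = m$accuracy,
       rounded = lapply(m, round, digits = 1))
}
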