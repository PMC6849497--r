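#' Construct a training set
#'
#' Pairs feature vectors with their motion-class labels. Both classifiers
#' train from the same set.
#'
#' @param x numeric matrix (or data frame) with one row per training point
#'   and the six power-feature columns.
#' @param y character vector of motion-class labels, one per row of `x`.
#' @return An object of class `training_set`: list with matrix `x` and
#'   labels `y`.
#' @export
training_set <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) {
    fd_stop("training set must be non-empty", "falldetect_parameter_error")
  }
  if (ncol(x) != 6L) {
    fd_stop("training features must have exactly 6 columns",
            "falldetect_parameter_error")
  }
  if (length(y) != nrow(x)) {
    fd_stop("one label per training point required", "falldetect_parameter_error")
  }
  vapply(y, as_motion_class, character(1))
  colnames(x) <- FEATURE_NAMES
  structure(list(x = x, y = as.character(y)), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d points, classes: %s\n", nrow(x$x),
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)),
                    collapse = " ")))
  invisible(x)
}

#' Euclidean distance between two feature vectors
#'
#' The distance underlying the k-NN classifier:
#' \eqn{\sqrt{\sum_{i=1}^{6}(x_i - y_i)^2}}.
#'
#' @param x,y numeric vectors of length 6.
#' @return Non-negative scalar; zero iff `x == y`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != 6L || length(y) != 6L) {
    fd_stop("feature vectors must have dimension 6", "falldetect_parameter_error")
  }
  sqrt(sum((x - y)^2))
}

# distances from query x to every row of matrix m (vectorised)
row_distances <- function(m, x) {
  sqrt(colSums((t(m) - x)^2))
}

#' k-nearest-neighbour classification
#'
#' Assigns the modal class among the `k` training points nearest to `x` under
#' Euclidean distance. Ties are resolved deterministically: all points whose
#' distance equals the k-th smallest vote (distance-tie expansion); a vote tie
#' between classes goes to the class with the smaller summed distance over its
#' voters, then to the class earlier in the [MOTION_CLASSES] enumeration.
#'
#' @param train a [training_set].
#' @param x feature vector of length 6.
#' @param k number of neighbours, `1 <= k <= nrow(train$x)`.
#' @return The predicted class label (character scalar).
#' @export
knn_classify <- function(train, x, k) {
  if (!inherits(train, "training_set")) {
    fd_stop("train must be a training_set", "falldetect_parameter_error")
  }
  n <- nrow(train$x)
  if (k < 1 || k > n) {
    fd_stop(sprintf("k must be in [1, %d]", n), "falldetect_parameter_error")
  }
  d <- row_distances(train$x, x)
  kth <- sort(d, partial = k)[k]
  voters <- which(d <= kth)
  votes <- table(factor(train$y[voters], levels = MOTION_CLASSES))
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(d[voters][train$y[voters] == cl]),
                   numeric(1))
    top <- top[sums == min(sums)]  # still ties -> enumeration order (first)
  }
  top[1L]
}

#' Choose k by n-fold cross-validation
#'
#' Splits the training set into `n_folds` stratified folds (seeded), uses
#' each fold once as the held-out test set, and for every candidate `k`
#' records the mean misclassification fraction over folds. The candidate with
#' the lowest error wins; at equal error the smallest `k` is preferred (the
#' less complex model).
#'
#' @param train a [training_set].
#' @param n_folds number of folds (>= 2).
#' @param candidates candidate values of `k`; every candidate must be at most
#'   the smallest per-fold training size. Default: odd 1 to 15.
#' @param seed seed for the stratified fold assignment.
#' @return List with `k` (the chosen value) and `cv_error` (named numeric
#'   vector of the per-candidate mean misclassification fractions).
#' @export
select_k <- function(train, n_folds = 5, candidates = seq(1, 15, by = 2),
                     seed = 1L) {
  if (!inherits(train, "training_set")) {
    fd_stop("train must be a training_set", "falldetect_parameter_error")
  }
  n <- nrow(train$x)
  if (length(candidates) == 0L || any(candidates < 1)) {
    fd_stop("candidates must be positive integers", "falldetect_parameter_error")
  }
  if (n_folds < 2 || n_folds > n) {
    fd_stop("n_folds must be between 2 and the training size",
            "falldetect_parameter_error")
  }
  withr::local_seed(as.integer(seed))
  # stratified: shuffle within class, deal fold ids round-robin
  fold <- integer(n)
  for (cl in unique(train$y)) {
    idx <- which(train$y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  min_train <- min(vapply(seq_len(n_folds), function(f) sum(fold != f),
                          integer(1)))
  if (max(candidates) > min_train) {
    fd_stop(sprintf("candidate k=%d exceeds smallest training-fold size %d",
                    max(candidates), min_train),
            "falldetect_parameter_error")
  }
  errs <- matrix(NA_real_, nrow = n_folds, ncol = length(candidates))
  for (f in seq_len(n_folds)) {
    tr <- training_set(train$x[fold != f, , drop = FALSE], train$y[fold != f])
    te_x <- train$x[fold == f, , drop = FALSE]
    te_y <- train$y[fold == f]
    for (j in seq_along(candidates)) {
      pred <- vapply(seq_len(nrow(te_x)),
                     function(i) knn_classify(tr, te_x[i, ], candidates[j]),
                     character(1))
      errs[f, j] <- mean(pred != te_y)
    }
  }
  cv_error <- stats::setNames(colMeans(errs), as.character(candidates))
  best <- candidates[cv_error == min(cv_error)]
  list(k = min(best), cv_error = cv_error)
}
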