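#' Fit per-class Gaussian statistics for naive Bayes
#'
#' For every class present in the training set, computes the per-feature
#' sample mean and sample standard deviation (denominator n-1) and the
#' empirical class prior (class frequency). A variance floor replaces each
#' standard deviation by `max(sigma, 1e-6 * global feature SD, 1e-12)` so
#' constant features cannot produce degenerate densities.
#'
#' @param train a [training_set]; every class in it needs at least 2 points.
#' @return An object of class `class_stats`: list with `classes`, `prior`
#'   (named, sums to 1), `mu` and `sigma` (class-by-feature matrices), and
#'   `floor` (the per-feature floor actually applied).
#' @export
fit_gaussian_nb <- function(train) {
  if (!inherits(train, "training_set")) {
    fd_stop("train must be a training_set", "falldetect_parameter_error")
  }
  classes <- MOTION_CLASSES[MOTION_CLASSES %in% unique(train$y)]
  counts <- vapply(classes, function(cl) sum(train$y == cl), integer(1))
  if (any(counts < 2L)) {
    fd_stop(sprintf("class '%s' has fewer than 2 training points",
                    classes[which(counts < 2L)[1]]),
            "falldetect_fit_error")
  }
  global_sd <- apply(train$x, 2, stats::sd)
  floor_sd <- pmax(1e-6 * global_sd, 1e-12)
  mu <- t(vapply(classes,
                 function(cl) colMeans(train$x[train$y == cl, , drop = FALSE]),
                 numeric(6)))
  sigma <- t(vapply(classes,
                    function(cl) apply(train$x[train$y == cl, , drop = FALSE],
                                       2, stats::sd),
                    numeric(6)))
  sigma <- pmax(sigma, matrix(floor_sd, nrow(sigma), 6, byrow = TRUE))
  prior <- counts / sum(counts)
  structure(list(classes = classes,
                 prior = stats::setNames(as.numeric(prior), classes),
                 mu = mu, sigma = sigma, floor = floor_sd),
            class = "class_stats")
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("<class_stats> %d classes: %s\n", length(x$classes),
              paste(sprintf("%s (prior %.3f)", x$classes, x$prior),
                    collapse = ", ")))
  invisible(x)
}

#' Gaussian likelihood of a feature value
#'
#' The class-conditional density of a single feature under the Gaussian
#' assumption:
#' \eqn{p(F = x \mid C) = \frac{1}{\sigma\sqrt{2\pi}}
#'   e^{-\frac{1}{2}\left(\frac{x-\mu}{\sigma}\right)^2}}.
#'
#' @param x observed feature value.
#' @param mu class mean of the feature.
#' @param sigma class standard deviation of the feature; must be positive.
#' @return The density value.
#' @export
gaussian_likelihood <- function(x, mu, sigma) {
  if (any(sigma <= 0)) {
    fd_stop("sigma must be positive", "falldetect_parameter_error")
  }
  stats::dnorm(x, mean = mu, sd = sigma)
}

# per-class log prior + log joint likelihood of the six features
nb_log_joint <- function(f, stats_obj) {
  if (length(f) != 6L) {
    fd_stop("feature vector must have dimension 6", "falldetect_parameter_error")
  }
  vapply(seq_along(stats_obj$classes), function(k) {
    log(stats_obj$prior[[k]]) +
      sum(stats::dnorm(f, mean = stats_obj$mu[k, ], sd = stats_obj$sigma[k, ],
                       log = TRUE))
  }, numeric(1))
}

#' Evidence (total probability) of a feature vector
#'
#' The normalising denominator of Bayes' theorem: the prior-weighted sum over
#' classes of the joint likelihood of all six features,
#' \eqn{\sum_k p(C_k)\,\prod_{i=1}^{6} p(F_i = f_i \mid C_k)}.
#' Computed via log-sum-exp for numerical robustness; the returned value is
#' on the linear scale.
#'
#' @param f feature vector of length 6.
#' @param stats a `class_stats` object from [fit_gaussian_nb()].
#' @return Strictly positive scalar (may underflow to the smallest
#'   representable double for extremely unlikely inputs).
#' @export
evidence <- function(f, stats) {
  lj <- nb_log_joint(f, stats)
  m <- max(lj)
  exp(m) * sum(exp(lj - m))
}

#' Posterior class probabilities
#'
#' Bayes' rule for each class: prior times joint likelihood over evidence,
#' \eqn{p(C_k \mid F) = p(C_k)\,p(F \mid C_k) / p(F)}. Evaluated in log space
#' and normalised with log-sum-exp, which is exactly equivalent to the direct
#' ratio but immune to the underflow a six-feature density product invites.
#'
#' @param f feature vector of length 6.
#' @param stats a `class_stats` object.
#' @return Named numeric vector of per-class probabilities in \[0, 1\],
#'   summing to 1.
#' @export
posterior <- function(f, stats) {
  lj <- nb_log_joint(f, stats)
  m <- max(lj)
  p <- exp(lj - m)
  stats::setNames(p / sum(p), stats$classes)
}

#' Naive Bayes classification
#'
#' Returns the class with the highest posterior probability; exact ties go to
#' the class earlier in the [MOTION_CLASSES] enumeration.
#'
#' @param f feature vector of length 6.
#' @param stats a `class_stats` object.
#' @return The predicted class label (character scalar).
#' @export
nb_classify <- function(f, stats) {
  post <- posterior(f, stats)
  names(post)[which.max(post)]
}
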