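# direct linear-scale Bayes pipeline used as the reference: raw density
# products, no log-space tricks
oracle_posterior <- function(f, stats) {
  joint <- sapply(seq_along(stats$classes), function(k) {
    stats$prior[[k]] * prod(dnorm(f, stats$mu[k, ], stats$sigma[k, ]))
  })
  joint / sum(joint)
}

test_that("fitting recovers per-class means, SDs and frequency priors", {
  set.seed(41)
  x <- matrix(runif(60 * 6, 0, 5), ncol = 6)
  y <- rep(c("still", "fall", "bending"), each = 20)
  stats <- fit_gaussian_nb(training_set(x, y))
  expect_equal(sum(stats$prior), 1, tolerance = 1e-9)
  expect_equal(unname(stats$prior), rep(1 / 3, 3))
  for (cl in c("still", "bending", "fall")) {
    k <- match(cl, stats$classes)
    expect_equal(unname(stats$mu[k, ]), unname(colMeans(x[y == cl, ])),
                 tolerance = 1e-10)
    expect_equal(unname(stats$sigma[k, ]), unname(apply(x[y == cl, ], 2, sd)),
                 tolerance = 1e-10)
  }
  expect_true(all(stats$sigma > 0))
})

test_that("degenerate classes hit the variance floor or error out", {
  # identical feature values in a class: sd would be 0, floor applies
  x <- rbind(matrix(1, 2, 6), matrix(c(2, 4), 2, 6))
  stats <- fit_gaussian_nb(training_set(x, c("still", "still", "fall", "fall")))
  expect_true(all(stats$sigma > 0))
  expect_equal(unname(stats$mu[1, ]), rep(1, 6))
  # a class with a single point cannot be fitted
  expect_error(fit_gaussian_nb(training_set(rbind(x, 0), c(
    "still", "still", "fall", "fall", "bending"))),
    "bending", class = "falldetect_fit_error")
})

test_that("gaussian likelihood matches the closed form", {
  expect_equal(gaussian_likelihood(0, 0, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_likelihood(1, 0, 1), exp(-0.5) / sqrt(2 * pi),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    x <- rnorm(1); mu <- rnorm(1); sigma <- runif(1, 0.1, 3)
    expect_equal(gaussian_likelihood(x, mu, sigma),
                 exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi)),
                 tolerance = 1e-12)
  }
  expect_error(gaussian_likelihood(0, 0, 0),
               class = "falldetect_parameter_error")
})

test_that("evidence is the prior-weighted sum of joint likelihoods", {
  set.seed(43)
  x <- matrix(rnorm(40 * 6, mean = 3), ncol = 6)
  y <- rep(c("still", "fall"), each = 20)
  stats <- fit_gaussian_nb(training_set(abs(x), y))
  for (i in 1:20) {
    f <- runif(6, 0, 5)
    direct <- sum(sapply(seq_along(stats$classes), function(k) {
      stats$prior[[k]] * prod(dnorm(f, stats$mu[k, ], stats$sigma[k, ]))
    }))
    expect_equal(evidence(f, stats), direct, tolerance = 1e-9)
    expect_gt(evidence(f, stats), 0)
  }
  # single class: evidence = prior x joint likelihood
  one <- fit_gaussian_nb(training_set(abs(x[1:20, ]), rep("still", 20)))
  f <- runif(6, 0, 5)
  expect_equal(evidence(f, one), prod(dnorm(f, one$mu[1, ], one$sigma[1, ])))
})

test_that("posterior matches the direct Bayes computation and sums to 1", {
  set.seed(44)
  x <- abs(matrix(rnorm(60 * 6, mean = 4, sd = 2), ncol = 6))
  y <- rep(c("still", "sitting_up", "fall"), each = 20)
  stats <- fit_gaussian_nb(training_set(x, y))
  for (i in 1:50) {
    f <- runif(6, 0, 8)
    post <- posterior(f, stats)
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_true(all(post >= 0 & post <= 1))
    expect_equal(unname(post), oracle_posterior(f, stats), tolerance = 1e-9)
    expect_identical(nb_classify(f, stats),
                     stats$classes[which.max(oracle_posterior(f, stats))])
  }
})

test_that("two symmetric classes give a (1/2, 1/2) posterior", {
  x <- rbind(matrix(c(0, 2), 4, 6), matrix(c(0, 2), 4, 6))
  stats <- fit_gaussian_nb(training_set(x, rep(c("still", "fall"), each = 4)))
  post <- posterior(runif(6), stats)
  expect_equal(unname(post), c(0.5, 0.5))
  # symmetric tie resolves to the class earlier in the enumeration
  expect_identical(nb_classify(runif(6), stats), "still")
})

test_that("hand-computed two-Gaussian posterior is reproduced", {
  # single informative feature: mu 0 vs 2, sigma 1, equal priors, x = 0
  # closed form: p(class1 | x) = 1 / (1 + exp(-2))
  stats <- structure(list(
    classes = c("still", "fall"),
    prior = c(still = 0.5, fall = 0.5),
    mu = rbind(rep(0, 6), c(2, rep(0, 5))),
    sigma = matrix(1, 2, 6),
    floor = rep(1e-12, 6)), class = "class_stats")
  post <- posterior(rep(0, 6), stats)
  expect_equal(unname(post[["still"]]), 1 / (1 + exp(-2)), tolerance = 1e-12)
})

test_that("posteriors are invariant to a common likelihood scaling", {
  # multiplying every sigma row-pair structure by the same constant rescales
  # all densities by a common factor; the posterior must not move
  stats <- structure(list(
    classes = c("still", "fall"),
    prior = c(still = 0.3, fall = 0.7),
    mu = rbind(rep(1, 6), rep(3, 6)),
    sigma = matrix(2, 2, 6),
    floor = rep(1e-12, 6)), class = "class_stats")
  scaled <- stats
  scaled$sigma <- stats$sigma * 5  # common factor on every density
  f <- rep(2, 6)  # equidistant from both means: likelihood ratio stays 1
  expect_equal(posterior(f, stats), posterior(f, scaled), tolerance = 1e-12)
})

test_that("with identical class stats the argmax follows the prior", {
  stats <- structure(list(
    classes = c("still", "fall"),
    prior = c(still = 0.2, fall = 0.8),
    mu = matrix(1, 2, 6), sigma = matrix(1, 2, 6),
    floor = rep(1e-12, 6)), class = "class_stats")
  expect_identical(nb_classify(rnorm(6), stats), "fall")
  stats$prior <- c(still = 0.8, fall = 0.2)
  expect_identical(nb_classify(rnorm(6), stats), "still")
})

test_that("log-space posterior survives inputs that underflow linearly", {
  stats <- structure(list(
    classes = c("still", "fall"),
    prior = c(still = 0.5, fall = 0.5),
    mu = rbind(rep(0, 6), rep(1000, 6)),
    sigma = matrix(0.1, 2, 6),
    floor = rep(1e-12, 6)), class = "class_stats")
  post <- posterior(rep(500, 6), stats)  # both joints underflow to 0 linearly
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_false(anyNA(post))
})

test_that("fit-then-classify separates fall from ADLs on a default corpus", {
  corpus <- generate_corpus(20, motion_model_params(seed = 3))
  feats <- corpus_features(corpus)
  tr <- training_set(as.matrix(feats[falldetect:::FEATURE_NAMES]), feats$label)
  stats <- fit_gaussian_nb(tr)
  pred <- vapply(seq_len(nrow(tr$x)),
                 function(i) to_fall_flag(nb_classify(tr$x[i, ], stats)),
                 integer(1))
  truth <- vapply(feats$label, to_fall_flag, integer(1))
  expect_gte(100 * mean(pred == truth), 95)
})
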