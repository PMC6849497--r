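# shared fixture builders

# a signal window from raw channel values (constant-rate grid)
make_window <- function(ax = 0, ay = 0, az = 0, gx = 0, gy = 0, gz = 0,
                        n = 10, rate = 10) {
  rep_ch <- function(x) if (length(x) == 1L) rep(x, n) else x
  signal_window(t = seq(0, by = 1 / rate, length.out = n),
                ax = rep_ch(ax), ay = rep_ch(ay), az = rep_ch(az),
                gx = rep_ch(gx), gy = rep_ch(gy), gz = rep_ch(gz),
                rate = rate)
}

random_features <- function(n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * 6, 0, 10), ncol = 6,
                                dimnames = list(NULL, falldetect:::FEATURE_NAMES)))
}

# small labelled training set over two well-separated classes
two_class_train <- function(n_per = 15, seed = 4) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n_per * 6, mean = 0, sd = 1), ncol = 6)
    b <- matrix(stats::rnorm(n_per * 6, mean = 6, sd = 1), ncol = 6)
    training_set(abs(rbind(a, b)),
                 rep(c("still", "fall"), each = n_per))
  })
}
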