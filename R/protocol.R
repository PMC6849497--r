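#' Replicate the ten-scenario trial protocol on synthetic data
#'
#' Runs the full pipeline end to end under the reference evaluation protocol:
#' a training corpus of `trials_per_class` recordings per class; both sensor
#' classifiers trained (k chosen by stratified cross-validation unless fixed);
#' then ten test scenarios — the five ADLs plus five fall variants (falls
#' initiated from still, lying down, sitting up, standing up and bending,
#' which share the fall signal model) — with `trials_per_scenario` fresh
#' recordings each, every one paired with a simulated frame sequence, pushed
#' through [detect()] and tallied against ground truth.
#'
#' @param train_seed,test_seed base seeds for the training corpus and the
#'   (disjoint) test recordings.
#' @param trials_per_class training recordings per class.
#' @param trials_per_scenario test recordings per scenario.
#' @param params simulator parameters (the seed field is overridden by the
#'   two seeds above).
#' @param k fixed k, or `NULL` for [select_k()] with `n_folds` folds and odd
#'   candidates 1-15.
#' @param n_folds cross-validation folds.
#' @return List with `counts` (a [confusion_counts()]), `accuracy`,
#'   `sensitivity`, `specificity` (unrounded percents), the chosen `k`, and
#'   `n` (number of test trials).
#' @export
run_trial_protocol <- function(train_seed = 0, test_seed = 1,
                               trials_per_class = 40,
                               trials_per_scenario = 100,
                               params = motion_model_params(),
                               k = NULL, n_folds = 5) {
  tp <- params
  tp$seed <- as.integer(train_seed)
  corpus <- generate_corpus(trials_per_class, tp)
  models <- train_models(corpus, k = k, n_folds = n_folds,
                         seed = as.integer(train_seed) + 1L)

  scenarios <- c(setdiff(MOTION_CLASSES, "fall"), rep("fall", 5))
  pred <- integer(0)
  truth <- integer(0)
  for (si in seq_along(scenarios)) {
    cls <- scenarios[si]
    for (trial in seq_len(trials_per_scenario)) {
      sp <- params
      sp$seed <- derive_seed(test_seed, si + 100L, trial)
      w <- generate_motion(cls, sp)
      frames <- generate_frames(cls == "fall",
                                seed = derive_seed(test_seed, si + 200L, trial))
      res <- detect(w, models$knn, models$nb, frames = frames)
      pred <- c(pred, res$fused)
      truth <- c(truth, to_fall_flag(cls))
    }
  }
  cc <- evaluate(pred, truth)
  list(counts = cc, accuracy = accuracy(cc), sensitivity = sensitivity(cc),
       specificity = specificity(cc), k = models$knn$k, n = length(truth))
}
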