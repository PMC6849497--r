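test_that("fall flag maps only the fall class to 1", {
  expect_identical(to_fall_flag("fall"), 1L)
  expect_identical(to_fall_flag("still"), 0L)
  expect_identical(to_fall_flag("bending"), 0L)
})

test_that("fuse reproduces the 3-input majority truth table exactly", {
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    expect_identical(fuse(a, b, c), as.integer(a + b + c >= 2))
  }
  expect_error(fuse(2, 0, 0), class = "falldetect_parameter_error")
})

test_that("evaluate tallies outcomes into the right confusion cells", {
  cc <- evaluate(c(rep(1, 10), rep(0, 10)), c(rep(1, 10), rep(0, 10)))
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                   c(tp = 10L, tn = 10L, fp = 0L, fn = 0L))
  cc2 <- evaluate(rep(0, 5), rep(1, 5))
  expect_identical(cc2$fn, 5L)
  expect_identical(cc2$tp + cc2$tn + cc2$fp, 0L)
  expect_error(evaluate(c(1, 0), c(1, 0, 1)), class = "falldetect_data_error")
})

test_that("evaluate matches a per-pair case analysis on random instances", {
  set.seed(61)
  pred <- sample(0:1, 50, replace = TRUE)
  truth <- sample(0:1, 50, replace = TRUE)
  cc <- evaluate(pred, truth)
  ref <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in 1:50) {
    cell <- if (truth[i] == 1) (if (pred[i] == 1) "tp" else "fn")
            else (if (pred[i] == 1) "fp" else "tn")
    ref[cell] <- ref[cell] + 1L
  }
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]), ref)
  expect_identical(sum(ref), 50L)  # counts conserved
})

test_that("metrics reproduce the reference confusion-table percentages", {
  cc <- confusion_counts(tp = 481, tn = 472, fp = 28, fn = 19)
  expect_equal(round(sensitivity(cc), 1), 96.2)
  expect_equal(round(specificity(cc), 1), 94.4)
  expect_equal(round(accuracy(cc), 1), 95.3)
  # accuracy lies between the two rate metrics when arms are equal-sized
  expect_gte(accuracy(cc), min(sensitivity(cc), specificity(cc)))
  expect_lte(accuracy(cc), max(sensitivity(cc), specificity(cc)))
})

test_that("metric edge cases and undefined-metric errors behave", {
  expect_equal(sensitivity(confusion_counts(0, 0, 0, 10)), 0)
  expect_equal(sensitivity(confusion_counts(50, 0, 0, 0)), 100)
  expect_equal(specificity(confusion_counts(0, 100, 0, 0)), 100)
  expect_equal(specificity(confusion_counts(0, 0, 5, 0)), 0)
  expect_equal(accuracy(confusion_counts(25, 25, 25, 25)), 50)
  expect_error(sensitivity(confusion_counts(0, 5, 5, 0)),
               class = "falldetect_metric_error")
  expect_error(specificity(confusion_counts(5, 0, 0, 5)),
               class = "falldetect_metric_error")
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)),
               class = "falldetect_metric_error")
})

test_that("per-scenario confusion rows pool to the reference totals", {
  # the ten-scenario trial protocol: five ADL rows (negative) and five fall
  # rows (positive), 100 trials each; per-row counts below
  tn_rows <- c(100, 97, 96, 93, 86)
  fp_rows <- c(0, 3, 4, 7, 14)
  tp_rows <- c(100, 98, 100, 93, 90)
  fn_rows <- c(0, 2, 0, 7, 10)
  cc <- confusion_counts(tp = sum(tp_rows), tn = sum(tn_rows),
                         fp = sum(fp_rows), fn = sum(fn_rows))
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(481, 472, 28, 19))
  expect_equal(round(sensitivity(cc), 1), 96.2)
  expect_equal(round(specificity(cc), 1), 94.4)
  expect_equal(round(accuracy(cc), 1), 95.3)
})

make_pipeline_models <- function() {
  corpus <- generate_corpus(15, motion_model_params(seed = 2))
  train_models(corpus, k = 3)
}

test_that("detect runs the full pipeline on seeded recordings", {
  models <- make_pipeline_models()
  p <- motion_model_params(seed = 77)

  still <- generate_motion("still", p)
  res <- detect(still, models$knn, models$nb)
  expect_identical(res$fused, 0L)
  expect_false(res$camera_was_triggered)
  expect_identical(res$visual_flag, 0L)

  fall <- generate_motion("fall", p)
  frames <- generate_frames(TRUE, 10, seed = 77)
  res_f <- detect(fall, models$knn, models$nb, frames = frames)
  expect_true(res_f$camera_was_triggered)
  expect_identical(res_f$visual_flag, 1L)
  expect_identical(res_f$fused, 1L)
})

test_that("missing frames degrade to two-classifier agreement with a warning", {
  models <- make_pipeline_models()
  fall <- generate_motion("fall", motion_model_params(seed = 78))
  expect_warning(res <- detect(fall, models$knn, models$nb, frames = NULL),
                 "degraded")
  expect_identical(res$visual_flag, 0L)
  expect_identical(res$fused, as.integer(res$knn_flag & res$nb_flag))
})
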