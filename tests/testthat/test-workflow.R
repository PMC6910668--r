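test_that("recordings, labels and predictions round-trip through text files", {
  sub <- synth_subject(subject_spec(duration = 30, seed = 2,
                                    subject_id = "m7"))
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_recording(sub$recording, p1)
  rec2 <- read_recording(p1)
  expect_equal(rec2$fs, 128)
  expect_equal(rec2$subject_id, "m7")
  expect_equal(rec2$eeg, sub$recording$eeg, tolerance = 1e-6)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_labels(sub$labels, p2)
  lab2 <- read_labels(p2)
  expect_identical(unclass(lab2), unclass(sub$labels))
  expect_equal(attr(lab2, "epoch_len"), 2.5)

  pred <- tibble::tibble(epoch = 1:3, stage = c(1L, 2L, 3L),
                         p_rem = c(0.8, 0.1, 0.1), p_wake = c(0.1, 0.8, 0.1),
                         p_nrem = c(0.1, 0.1, 0.8))
  class(pred) <- c("stage_prediction", class(pred))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_predictions(pred, p3)
  expect_equal(as.data.frame(read_predictions(p3)), as.data.frame(pred))
})

test_that("subject calibration demands every stage and is deterministic", {
  sub <- synth_subject(subject_spec(duration = 900, seed = 3))
  feats <- preprocess_recording(sub$recording)
  lab <- as.integer(sub$labels)[seq_len(ncol(feats))]

  sparse <- tibble::tibble(epoch = seq_along(lab), stage = lab)
  two_stages <- sparse[sparse$stage != 1L, ]
  expect_error(calibrate_subject(sub$recording, two_stages, features = feats),
               "REM")

  p1 <- calibrate_subject(sub$recording, sparse, features = feats)
  p2 <- calibrate_subject(sub$recording, sparse, features = feats)
  expect_equal(p1$offset, p2$offset, tolerance = 1e-15)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_calibration(p1, f1); write_calibration(p2, f2)
  expect_identical(sub("created.*", "", paste(readLines(f1), collapse = "")),
                   sub("created.*", "", paste(readLines(f2), collapse = "")))
})

test_that("scored recordings match generator truth on held-out subjects", {
  h <- heavy_fixture()
  sp <- subject_spec(duration = 1200, seed = 777)
  held <- synth_subject(sp)
  feats <- preprocess_recording(held$recording)
  params <- calibrate_subject(held$recording,
                              held$labels[seq_len(ncol(feats))],
                              w = h$w, features = feats)
  pr <- score_recording(held$recording, params, h$model_mix, features = feats)
  truth <- as.integer(held$labels)[seq_len(nrow(pr))]
  expect_gt(mean(pr$stage == truth), 0.90)

  pr2 <- score_recording(held$recording, params, h$model_mix, features = feats)
  expect_identical(pr$stage, pr2$stage)

  bad <- params
  bad$layout <- "other-10"
  expect_error(score_recording(held$recording, bad, h$model_mix), "layout")
})

test_that("mismatched subject calibration degrades scoring accuracy", {
  h <- heavy_fixture()
  sub <- h$subjects[[1]]
  feats <- preprocess_recording(sub$recording)
  truth <- as.integer(sub$labels)[seq_len(ncol(feats))]
  pr_match <- score_recording(sub$recording, sub$params, h$model_mix,
                              features = feats)
  # calibration from a subject with a very different gain
  other <- calibrate_subject(
    h$cohort[[3]]$recording,
    h$cohort[[3]]$labels[seq_len(ncol(h$feats[[3]]))],
    w = h$w, features = h$feats[[3]])
  pr_other <- score_recording(sub$recording, other, h$model_mix,
                              features = feats)
  acc_match <- mean(pr_match$stage == truth)
  acc_other <- mean(pr_other$stage == truth)
  expect_gt(acc_match, acc_other)
})

test_that("the budget sweep plateaus and repeats under a fixed seed", {
  h <- heavy_fixture()
  sp <- h$subjects[[2]]$spec
  sp$duration <- 2700
  sp$seed <- sp$seed + 19L
  sub <- synth_subject(sp)
  sw <- suppressMessages(
    label_budget_sweep(sub$recording, sub$labels, h$model_mix,
                       budgets_min = c(1, 5), w = h$w, repeats = 2,
                       seed = 23))
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$accuracy > 0.8))
  sw2 <- suppressMessages(
    label_budget_sweep(sub$recording, sub$labels, h$model_mix,
                       budgets_min = c(1, 5), w = h$w, repeats = 2,
                       seed = 23))
  expect_equal(sw$accuracy, sw2$accuracy)
  expect_error(label_budget_sweep(sub$recording, sub$labels, h$model_mix,
                                  budgets_min = 1e5), "exceeds")
})

test_that("the experiment dispatcher runs selectors and stamps provenance", {
  rep <- run_experiment(list(experiment = "simulate", seed = 5))
  expect_equal(rep$experiment, "simulate")
  expect_match(rep$config_hash, "^[0-9a-f]{8}$")
  expect_true(rep$report$summary$mixture_true_positive)

  dir <- withr::local_tempdir()
  synth_rep <- run_experiment(list(
    experiment = "synth", seed = 4, duration = 60,
    out_signals = file.path(dir, "sig.txt"),
    out_labels = file.path(dir, "lab.csv")))
  expect_equal(synth_rep$report$n_epochs, 24)
  expect_true(file.exists(file.path(dir, "sig.txt")))

  pre <- run_experiment(list(experiment = "preprocess", seed = 1,
                             signals = file.path(dir, "sig.txt")))
  expect_equal(pre$report$n_features, 185L)
  expect_equal(pre$report$n_epochs, 24L)

  rep2 <- run_experiment(list(experiment = "simulate", seed = 5))
  expect_equal(rep2$report$report$estimate, rep$report$report$estimate)

  expect_error(run_experiment(list(experiment = "nope")), "unknown")
})

test_that("feature matrices round-trip with their layout header", {
  z <- standard_zscore(matrix(rnorm(20), 4))$features
  p <- withr::local_tempfile(fileext = ".tsv")
  write_features(z, p)
  z2 <- read_features(p)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12)
  expect_true(attr(z2, "standardized"))
  expect_equal(attr(z2, "layout"), attr(z, "layout"))
})
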