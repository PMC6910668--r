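# Shared fixtures, built once per test run and memoized. The heavy bundle
# (synthetic cohort, per-subject calibrations, and the two SS-ANN arms) is
# used by the workflow, sweep and acceptance tests; problem sizes are the
# package's documented desk-scale defaults.

.fixture_env <- new.env(parent = emptyenv())

#  3 training subjects x 1800 s plus per-subject 5400 s evaluation
#  recordings sharing each subject's nuisance
heavy_fixture <- function() {
  if (!is.null(.fixture_env$heavy)) return(.fixture_env$heavy)
  cohort <- make_cohort(3, subject_spec(duration = 1800), seed = 101)
  feats <- lapply(cohort, function(s) preprocess_recording(s$recording))
  labs <- lapply(seq_along(cohort), function(i)
    as.integer(cohort[[i]]$labels)[seq_len(ncol(feats[[i]]))])
  train_bal <- as.numeric(table(factor(unlist(labs), 1:3)) / length(unlist(labs)))
  w <- c(REM = train_bal[1], Wake = train_bal[2], NREM = train_bal[3])
  params <- lapply(seq_along(cohort), function(i)
    calibrate_subject(cohort[[i]]$recording,
                      cohort[[i]]$labels[seq_len(ncol(feats[[i]]))],
                      w = w, features = feats[[i]]))
  stack_images <- function(zs) {
    imgs <- lapply(zs, make_epoch_images)
    n <- sum(vapply(imgs, function(x) dim(x)[3], numeric(1)))
    all <- array(unlist(imgs), c(185, 13, n))
    attr(all, "layout") <- "ssann-185"
    class(all) <- "epoch_images"
    all
  }
  train_arm <- function(zs) {
    ov <- oversample_balance(stack_images(zs), unlist(labs), seed = 5)
    train_ssann(build_model(seed = 7), ov$images, ov$labels,
                train_config(seed = 9))
  }
  model_std <- train_arm(lapply(feats, function(f) standard_zscore(f)$features))
  model_mix <- train_arm(lapply(seq_along(feats), function(i)
    apply_standardization(feats[[i]], params[[i]])))
  subjects <- lapply(seq_along(cohort), function(i) {
    sp <- cohort[[i]]$spec
    sp$duration <- 5400
    sp$seed <- sp$seed + 7L
    b <- synth_subject(sp)
    list(recording = b$recording, labels = b$labels, params = params[[i]],
         spec = sp)
  })
  .fixture_env$heavy <- list(
    cohort = cohort, feats = feats, labs = labs, params = params,
    w = w, train_bal = c(Wake = train_bal[2], NREM = train_bal[3],
                         REM = train_bal[1]),
    model_std = model_std, model_mix = model_mix, subjects = subjects)
  .fixture_env$heavy
}

balance_grid_12 <- function() {
  g <- tibble::tibble(
    Wake = c(0.20, 0.40, 0.60, 0.80, 0.20, 0.45, 0.70, 0.30, 0.45,
             0.25, 0.65, 0.35),
    REM = c(0.05, 0.05, 0.05, 0.05, 0.10, 0.10, 0.10, 0.15, 0.15,
            0.00, 0.00, 0.20))
  g$NREM <- 1 - g$Wake - g$REM
  g
}

bias_fixture <- function() {
  if (!is.null(.fixture_env$bias)) return(.fixture_env$bias)
  h <- heavy_fixture()
  .fixture_env$bias <- bias_experiment(h$model_std, h$model_mix, h$subjects,
                                       balance_grid_12(),
                                       train_balance = h$train_bal, seed = 13)
  .fixture_env$bias
}

# a small random standardized image stack for classifier unit tests
random_images <- function(n, h = 24L, w = 13L, seed = 1L) {
  set.seed(seed)
  img <- array(rnorm(h * w * n), c(h, w, n))
  attr(img, "layout") <- "ssann-185"
  class(img) <- "epoch_images"
  img
}
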