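test_that("the default architecture hits the documented parameter budget", {
  m <- build_model()
  n <- count_parameters(m)
  # conv 80 + 1168 + 4640, batchnorm 112, head 736 * 3 + 3
  expect_equal(n, 80L + 1168L + 4640L + 112L + 2211L)
  expect_lt(n, 20000L)
  expect_gt(6.8e6 / n, 300)

  # only the head changes with the class count
  m2 <- build_model(ssann_config(n_classes = 2L))
  expect_equal(count_parameters(m) - count_parameters(m2), 2211L - (736L * 2L + 2L))

  # a single 3x3 conv block with bias on 1 channel contributes 80 + bn
  expect_equal(length(m$params$conv1$W) + length(m$params$conv1$b), 80L)

  expect_error(build_model(ssann_config(input_shape = c(4L, 4L, 1L))),
               "architecture")
})

test_that("oversampling tops every class up to the largest class", {
  imgs <- random_images(160, seed = 2)
  labels <- rep(c(1L, 2L, 3L), c(100, 50, 10))
  ov <- oversample_balance(imgs, labels, seed = 3)
  expect_equal(unname(table(ov$labels)), rep(100L, 3), ignore_attr = TRUE)
  # originals retained, extras drawn from the right class
  expect_equal(ov$index[1:160], 1:160)
  expect_true(all(labels[ov$index[-(1:160)]] == ov$labels[-(1:160)]))

  bal <- oversample_balance(imgs[, , 1:90], rep(1:3, each = 30), seed = 1)
  expect_equal(bal$index, 1:90)

  ov2 <- oversample_balance(imgs, labels, seed = 3)
  expect_identical(ov$index, ov2$index)
})

test_that("training reduces the loss and follows the learning-rate schedule", {
  set.seed(6)
  n <- 360
  imgs <- random_images(n, h = 24L, seed = 7)
  labels <- sample(1:3, n, replace = TRUE)
  # plant a strong class signal
  for (i in seq_len(n)) imgs[labels[i] * 4, , i] <- imgs[labels[i] * 4, , i] + 4
  cfg <- ssann_config(input_shape = c(24L, 13L, 1L))
  m <- train_ssann(build_model(cfg, seed = 2), imgs, labels,
                   train_config(batch_size = 120L, seed = 3))
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
  expect_equal(m$lr_trace, 0.015 * 0.85^(0:9))

  test_imgs <- random_images(300, h = 24L, seed = 8)
  test_lab <- sample(1:3, 300, replace = TRUE)
  for (i in 1:300) test_imgs[test_lab[i] * 4, , i] <- test_imgs[test_lab[i] * 4, , i] + 4
  pr <- predict(m, test_imgs)
  expect_gt(mean(pr$stage == test_lab), 0.9)

  # shuffled labels: held-out accuracy collapses to chance
  m0 <- train_ssann(build_model(cfg, seed = 2), imgs, sample(labels),
                    train_config(batch_size = 120L, seed = 3))
  pr0 <- predict(m0, test_imgs)
  expect_lt(abs(mean(pr0$stage == test_lab) - 1 / 3), 0.07)
})

test_that("predictions are proper softmax outputs and deterministic", {
  m <- build_model(ssann_config(input_shape = c(24L, 13L, 1L)), seed = 4)
  imgs <- random_images(20, h = 24L, seed = 5)
  pr <- predict(m, imgs)
  expect_equal(pr$p_rem + pr$p_wake + pr$p_nrem, rep(1, 20), tolerance = 1e-6)
  expect_equal(pr$stage,
               apply(rbind(pr$p_rem, pr$p_wake, pr$p_nrem), 2, which.max))

  # duplicated image gives an identical prediction
  imgs2 <- imgs
  imgs2[, , 2] <- imgs2[, , 1]
  pr2 <- predict(m, imgs2)
  expect_equal(pr2[2, -1], pr2[1, -1], ignore_attr = TRUE)

  bad <- random_images(4, h = 30L, seed = 6)
  expect_error(predict(m, bad), "shape")
})

test_that("equal logits give uniform class probabilities", {
  z <- matrix(0.7, 3, 5)
  expect_equal(somnoshift:::softmax_cols(z), matrix(1 / 3, 3, 5))
})

test_that("sub-5-second bouts merge into their surroundings idempotently", {
  W <- 2L; R <- 1L; N <- 3L
  expect_equal(as.integer(refine_bouts(c(W, W, R, W, W))), rep(W, 5))
  expect_equal(as.integer(refine_bouts(c(W, W, R, R, W))), c(W, W, R, R, W))
  expect_equal(as.integer(refine_bouts(rep(N, 6))), rep(N, 6))
  # record-edge runs are truncated bouts and stay as observed
  expect_equal(as.integer(refine_bouts(c(R, W, W, W))), c(R, W, W, W))
  # neighbors disagreeing: the preceding stage wins
  expect_equal(as.integer(refine_bouts(c(W, W, R, N, N))), c(W, W, W, N, N))

  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:3, 40, replace = TRUE)
    once <- refine_bouts(x)
    expect_identical(unclass(refine_bouts(once)), unclass(once))
    r <- rle(as.integer(once))
    nr <- length(r$lengths)
    if (nr > 2) expect_true(all(r$lengths[2:(nr - 1)] >= 2))
  }
})

test_that("evaluation reports confusion, accuracy and ROC significance", {
  truth <- c(1L, 1L, 2L, 3L)
  ev <- evaluate_predictions(c(1L, 2L, 2L, 3L), truth)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 1)

  # perfect predictions with confident probabilities
  set.seed(10)
  n <- 120
  tr <- sample(1:3, n, replace = TRUE)
  probs <- matrix(0.05, 3, n)
  probs[cbind(tr, 1:n)] <- 0.9
  pred <- tibble::tibble(epoch = 1:n, stage = tr, p_rem = probs[1, ],
                         p_wake = probs[2, ], p_nrem = probs[3, ])
  class(pred) <- c("stage_prediction", class(pred))
  ev2 <- evaluate_predictions(pred, tr, n_perm = 100, seed = 2)
  expect_equal(ev2$accuracy, 1)
  expect_true(all(vapply(ev2$roc, `[[`, numeric(1), "auc") == 1))
  expect_true(all(vapply(ev2$roc, `[[`, numeric(1), "p_value") < 0.05))

  # random probabilities: chance-level AUC
  rnd <- tibble::tibble(epoch = 1:n, stage = sample(1:3, n, replace = TRUE),
                        p_rem = runif(n), p_wake = runif(n), p_nrem = runif(n))
  class(rnd) <- c("stage_prediction", class(rnd))
  ev3 <- evaluate_predictions(rnd, tr, n_perm = 50, seed = 3)
  for (r in ev3$roc) expect_lt(abs(r$auc - 0.5), 0.15)

  expect_error(evaluate_predictions(c(1L, 2L), c(1L, 2L, 3L)), "length")
})

test_that("checkpoints round-trip through the JSON format", {
  m <- build_model(ssann_config(input_shape = c(24L, 13L, 1L)), seed = 11)
  imgs <- random_images(30, h = 24L, seed = 12)
  labels <- sample(1:3, 30, replace = TRUE)
  m <- train_ssann(m, imgs, labels, train_config(epochs = 2L, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  save_ssann(m, path)
  m2 <- load_ssann(path)
  expect_equal(predict(m2, imgs), predict(m, imgs), tolerance = 1e-12)
  expect_equal(m2$loss_trace, m$loss_trace, tolerance = 1e-12)
})
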