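make_sine_rec <- function(freq, fs, dur, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)[-1]
  recording(amp * sin(2 * pi * freq * t), amp * sin(2 * pi * freq * t), fs)
}

test_that("resampling preserves duration and spectral content", {
  rec <- make_sine_rec(10, 1000, 60)
  out <- resample_to_128(rec)
  expect_equal(out$fs, 128)
  expect_equal(length(out$eeg), 7680, tolerance = 1)

  rec128 <- make_sine_rec(10, 128, 10)
  expect_identical(resample_to_128(rec128), rec128)

  sp <- Mod(stats::fft(out$eeg[1:2048]))[1:1024]
  peak <- (which.max(sp) - 1) * 128 / 2048
  expect_lt(abs(peak - 10), 0.2)

  expect_error(resample_to_128(make_sine_rec(5, 100, 10)), "unsupported")
})

test_that("multitaper spectrogram has the stated grid and peak behavior", {
  t <- seq(0, 60, by = 1 / 128)[-1]
  sp <- multitaper_spectrogram(sin(2 * pi * 10 * t))
  expect_equal(dim(sp), c(251L, 24L))
  expect_true(all(sp >= 0))
  expect_equal(rownames(sp)[1], "0.0")
  expect_equal(rownames(sp)[251], "50.0")
  # column-wise argmax at the 10 Hz bin
  expect_true(all(apply(sp, 2, which.max) == 51L))

  # white noise: approximately flat mean spectrum
  set.seed(2)
  spw <- multitaper_spectrogram(rnorm(128 * 300))
  m <- rowMeans(spw)[2:250]  # interior bins
  expect_lt(sd(m) / mean(m), 0.2)

  expect_error(multitaper_spectrogram(rnorm(100)), "too short")
})

test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  v <- somnoshift:::dpss_tapers(640, 3, 5)
  expect_equal(crossprod(v), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # concentration of the leading taper within +/- W = 3/640 cycles/sample
  h <- abs(stats::fft(c(v[, 1], rep(0, 640 * 7))))^2
  in_band <- sum(h[1:(3 * 8 + 1)]) + sum(h[(5120 - 3 * 8 + 1):5120])
  expect_gt(in_band / sum(h), 0.999)
})

test_that("high-band reduction keeps 101 bins and pair-averages the rest", {
  x <- matrix(1, 251, 4)
  r <- reduce_frequencies(x)
  expect_equal(nrow(r), 176L)
  expect_true(all(r == 1))

  x2 <- matrix(0, 251, 1)
  x2[102] <- 2; x2[103] <- 4  # the 20.2 and 20.4 Hz bins
  r2 <- reduce_frequencies(x2)
  expect_equal(r2[102, 1], 3)

  x3 <- matrix(rnorm(251 * 3), 251, 3)
  expect_equal(reduce_frequencies(x3)[1:101, ], x3[1:101, ])
  expect_error(reduce_frequencies(matrix(0, 250, 2)), "251")
})

test_that("EMG activity is a band-passed per-epoch RMS", {
  t <- seq(0, 60, by = 1 / 128)[-1]
  a <- 2
  rms35 <- suppressMessages(emg_activity(a * sin(2 * pi * 35 * t), 128))
  expect_equal(length(rms35), 24L)
  expect_true(all(abs(rms35 - a / sqrt(2)) / (a / sqrt(2)) < 0.10))

  rms5 <- suppressMessages(emg_activity(a * sin(2 * pi * 5 * t), 128))
  expect_true(all(rms35 / rms5 > 10))

  expect_equal(suppressMessages(emg_activity(rep(0, 128 * 10), 128)),
               rep(0, 4))
})

test_that("feature matrix assembly stacks log spectra over replicated EMG", {
  set.seed(5)
  spec <- matrix(rexp(176 * 10), 176)
  emg <- rexp(10)
  fm <- build_feature_matrix(spec, emg)
  expect_equal(nrow(fm), 185L)
  expect_false(attr(fm, "standardized"))
  for (r in 178:185) expect_equal(fm[r, ], fm[177, ], ignore_attr = TRUE)

  fm2 <- build_feature_matrix(spec, 2 * emg)
  expect_equal(fm2[177, ] - fm[177, ], rep(log(2), 10),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(build_feature_matrix(spec, rexp(9)), "mismatch")
})

test_that("context images center each epoch and replicate the boundary", {
  z <- standard_zscore(matrix(rnorm(185 * 24), 185))$features
  imgs <- make_epoch_images(z)
  expect_equal(dim(imgs), c(185L, 13L, 24L))
  expect_equal(imgs[, 7, 10], z[, 10], ignore_attr = TRUE)
  for (k in 1:6) expect_equal(imgs[, k, 1], z[, 1], ignore_attr = TRUE)
  expect_error(make_epoch_images(z, context = 12), "odd")
  expect_error(make_epoch_images(matrix(rnorm(10), 2), context = 13),
               "standardized")
})

test_that("a d-second recording yields floor(d / 2.5) epochs end to end", {
  for (d in c(60, 123)) {
    sub <- synth_subject(subject_spec(duration = d, seed = 3))
    fm <- preprocess_recording(sub$recording)
    expect_equal(ncol(fm), floor(d / 2.5))
    expect_equal(nrow(fm), 185L)
    expect_equal(dim(make_epoch_images(standard_zscore(fm)$features))[3],
                 floor(d / 2.5))
  }
})

test_that("a raw EEG gain shifts every spectral log-feature by 2 log g", {
  sub <- synth_subject(subject_spec(duration = 120, seed = 6))
  g <- 3.7
  rec2 <- recording(g * sub$recording$eeg, sub$recording$emg, 128)
  f1 <- preprocess_recording(sub$recording)
  f2 <- preprocess_recording(rec2)
  d <- as.matrix(f2)[1:176, ] - as.matrix(f1)[1:176, ]
  expect_equal(max(abs(d - 2 * log(g))), 0, tolerance = 1e-6)
})
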