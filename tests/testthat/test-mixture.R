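test_that("class-conditional statistics use per-class MLE denominators", {
  st <- estimate_class_stats(matrix(c(0, 1, 2, 3), 1), c(1, 1, 2, 2))
  expect_equal(as.numeric(st$mu_hat), c(0.5, 2.5))
  expect_equal(as.numeric(st$sigma2_hat), c(0.25, 0.25))
  expect_equal(unname(st$n_per_class), c(2L, 2L))

  # constant single-class input is degenerate but estimable
  st2 <- estimate_class_stats(matrix(rep(3, 4), 1), rep("a", 4))
  expect_equal(as.numeric(st2$mu_hat), 3)
  expect_equal(as.numeric(st2$sigma2_hat), 0)

  # perfectly separated indicator feature
  st3 <- estimate_class_stats(matrix(c(0, 0, 1, 1), 1), c(0, 0, 1, 1))
  expect_equal(as.numeric(st3$mu_hat), c(0, 1))
  expect_equal(as.numeric(st3$sigma2_hat), c(0, 0))
})

test_that("insufficient or malformed calibration input is rejected", {
  expect_error(estimate_class_stats(matrix(1:4, 1), c(1, 1, 1, 2)),
               "calibration insufficient.*2")
  expect_error(estimate_class_stats(matrix(1:4, 1), c(1, 1, 2)),
               "length")
})

test_that("mixture parameters combine class stats under the weights", {
  st <- estimate_class_stats(matrix(c(0, 1, 2, 3), 1), c(1, 1, 2, 2))
  p <- compute_mixture_params(st, c(0.5, 0.5))
  expect_equal(p$offset, 1.5)
  expect_equal(p$scale, sqrt(1.25), tolerance = 1e-12)

  p2 <- compute_mixture_params(st, c(0.8, 0.2))
  expect_equal(p2$offset, 0.9)
  expect_equal(p2$scale, sqrt(0.8 * 0.41 + 0.2 * 2.81), tolerance = 1e-12)

  # single-class reduction: plain z-score parameters
  st1 <- estimate_class_stats(matrix(c(0, 1, 2, 3), 1), rep(1, 4))
  p1 <- compute_mixture_params(st1, 1)
  expect_equal(p1$offset, 1.5)
  expect_equal(p1$scale, sqrt(1.25))

  expect_error(compute_mixture_params(st, c(0.5, 0.6)), "sum")
  stz <- estimate_class_stats(matrix(rep(2, 4), 1), c(1, 1, 2, 2))
  expect_error(compute_mixture_params(stz, c(0.5, 0.5)), "degenerate")
})

test_that("applying standardization centers and scales per feature", {
  st <- estimate_class_stats(matrix(c(0, 1, 2, 3), 1), c(1, 1, 2, 2))
  p <- compute_mixture_params(st, c(0.5, 0.5))
  z <- apply_standardization(matrix(c(0, 1, 2, 3), 1), p)
  expect_equal(as.numeric(z), c(-1.3416, -0.4472, 0.4472, 1.3416),
               tolerance = 1e-4)
  expect_true(attr(z, "standardized"))

  p2 <- compute_mixture_params(st, c(0.8, 0.2))
  expect_equal(as.numeric(apply_standardization(matrix(0, 1), p2)),
               -0.9540, tolerance = 1e-4)

  # centering identity
  z0 <- apply_standardization(matrix(rep(p$offset, 5), 1), p)
  expect_equal(as.numeric(z0), rep(0, 5))

  expect_error(apply_standardization(matrix(1:6, 2), p), "feature count")
})

test_that("standard z-scoring matches its closed form and is idempotent", {
  z <- standard_zscore(matrix(c(0, 1, 2, 3), 1))
  expect_equal(as.numeric(z$features), c(-1.3416, -0.4472, 0.4472, 1.3416),
               tolerance = 1e-4)
  expect_equal(z$params$mu, 1.5)
  expect_equal(z$params$sigma, sqrt(1.25))

  z2 <- standard_zscore(z$features)
  expect_equal(as.matrix(z2$features), as.matrix(z$features),
               tolerance = 1e-12, ignore_attr = TRUE)

  # affine invariance of the marginal z-score
  x <- matrix(rnorm(50), 1)
  expect_equal(as.matrix(standard_zscore(3 * x + 2)$features),
               as.matrix(standard_zscore(x)$features), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(standard_zscore(matrix(rep(1, 5), 1)), "degenerate")
})

test_that("offset and scale agree with naive summation on random instances", {
  # brute-force oracle: direct per-class loops over observations
  naive <- function(x, lab, w) {
    classes <- sort(unique(lab))
    F_ <- nrow(x)
    offset <- numeric(F_); scale2 <- numeric(F_)
    for (f in seq_len(F_)) {
      mus <- sapply(classes, function(cl) mean(x[f, lab == cl]))
      v <- sapply(classes, function(cl) {
        xi <- x[f, lab == cl]; sum((xi - mean(xi))^2) / length(xi)
      })
      offset[f] <- sum(w * mus)
      scale2[f] <- sum(w * (v + (mus - offset[f])^2))
    }
    list(offset = offset, scale = sqrt(scale2))
  }
  set.seed(42)
  for (i in 1:15) {
    C <- sample(1:3, 1); F_ <- sample(1:4, 1); n <- sample(8:50, 1)
    lab <- sample(seq_len(C), n, replace = TRUE)
    while (any(table(factor(lab, seq_len(C))) < 2)) {
      lab <- sample(seq_len(C), n, replace = TRUE)
    }
    x <- matrix(rnorm(F_ * n, sd = 2), F_)
    w <- as.numeric(rexp(C)); w <- w / sum(w)
    st <- estimate_class_stats(x, lab, classes = seq_len(C))
    p <- compute_mixture_params(st, w)
    o <- naive(x, lab, w)
    expect_equal(p$offset, o$offset, tolerance = 1e-10)
    expect_equal(p$scale, o$scale, tolerance = 1e-10)
  }
})

test_that("mixture z-scoring is affine invariant and reduces to standard z", {
  set.seed(7)
  for (i in 1:10) {
    n <- 60; F_ <- 3
    lab <- sample(1:3, n, replace = TRUE)
    x <- matrix(rnorm(F_ * n), F_)
    w <- as.numeric(rexp(3)); w <- w / sum(w)
    a <- runif(1, 0.5, 4); b <- runif(1, -5, 5)
    z1 <- apply_standardization(x, compute_mixture_params(
      estimate_class_stats(x, lab), w))
    z2 <- apply_standardization(a * x + b, compute_mixture_params(
      estimate_class_stats(a * x + b, lab), w))
    expect_equal(as.matrix(z1), as.matrix(z2), tolerance = 1e-9)

    w_emp <- as.numeric(table(factor(lab, 1:3)) / n)
    zm <- apply_standardization(x, compute_mixture_params(
      estimate_class_stats(x, lab), w_emp))
    expect_equal(as.matrix(zm), as.matrix(standard_zscore(x)$features),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("output under label shift is non-unit but class-conditionally aligned", {
  set.seed(11)
  mu_cl <- c(-2, 0, 3)
  gen <- function(props, n) {
    lab <- sample(1:3, n, replace = TRUE, prob = props)
    list(x = matrix(rnorm(n, mean = mu_cl[lab]), 1), lab = lab)
  }
  ref <- gen(c(0.2, 0.3, 0.5), 4000)   # balance equal to w
  shift <- gen(c(0.5, 0.3, 0.2), 4000) # label-shifted
  w <- c(0.2, 0.3, 0.5)
  zs <- function(d) {
    z <- apply_standardization(d$x, compute_mixture_params(
      estimate_class_stats(d$x, d$lab), w))
    as.numeric(z)
  }
  z_ref <- zs(ref); z_shift <- zs(shift)
  # marginal moments deliberately differ from 0/1 under label shift
  expect_gt(abs(mean(z_shift)), 0.05)
  # class-conditional means align with the reference-balance dataset
  for (cl in 1:3) {
    m1 <- mean(z_ref[ref$lab == cl]); m2 <- mean(z_shift[shift$lab == cl])
    se <- sqrt(var(z_ref[ref$lab == cl]) / sum(ref$lab == cl) +
               var(z_shift[shift$lab == cl]) / sum(shift$lab == cl))
    expect_lt(abs(m1 - m2), 3 * se)
  }
})

test_that("calibration files round-trip through JSON", {
  set.seed(3)
  x <- matrix(rnorm(5 * 40), 5)
  lab <- rep(1:2, each = 20)
  p <- compute_mixture_params(estimate_class_stats(x, lab), c(0.3, 0.7),
                              subject = "m1", layout = "generic-5")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(p, path)
  p2 <- read_calibration(path)
  expect_equal(p2$offset, p$offset, tolerance = 1e-12)
  expect_equal(p2$scale, p$scale, tolerance = 1e-12)
  expect_equal(p2$subject, "m1")
  expect_equal(unname(p2$w), c(0.3, 0.7))
  expect_equal(glance(p2)$n_calibration, 40L)
})
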