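#' Feature matrix container
#'
#' A feature matrix holds F features (rows) by n observations (columns):
#' log-scaled spectral power and log EMG activity before standardization,
#' dimensionless values after. All entries must be finite.
#'
#' @param values numeric matrix, features x observations.
#' @param standardized logical flag; `TRUE` once a standardization has been
#'   applied.
#' @param layout character tag describing the feature layout (used to guard
#'   against applying calibration parameters to mismatched features).
#' @return a `feature_matrix` object (a matrix with attributes).
#' @export
feature_matrix <- function(values, standardized = FALSE, layout = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must be a numeric matrix with at least one row and column",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("feature matrix contains non-finite entries", call. = FALSE)
  }
  structure(values,
            standardized = isTRUE(standardized),
            layout = layout %||% sprintf("generic-%d", nrow(values)),
            class = c("feature_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_standardized <- function(x) isTRUE(attr(x, "standardized"))

feature_layout <- function(x) attr(x, "layout")

#' Estimate class-conditional feature statistics
#'
#' Computes, per class and per feature, the sample mean and the
#' maximum-likelihood variance (denominator n_l, no Bessel correction) over
#' the observations carrying that class label. The MLE convention is what
#' makes mixture z-scoring collapse exactly to standard z-scoring when the
#' weights equal the empirical class proportions (law of total variance).
#'
#' @param features a [feature_matrix()] or numeric matrix, F x n.
#' @param labels class label per observation (length n).
#' @param classes ordered set of class labels; every class must appear at
#'   least twice in `labels`.
#' @return a `class_stats` object: list with `classes`, `mu_hat` (C x F),
#'   `sigma2_hat` (C x F), `n_per_class`.
#' @export
estimate_class_stats <- function(features, labels,
                                 classes = sort(unique(labels))) {
  x <- as.matrix(features)
  n <- ncol(x)
  if (length(labels) != n) {
    stop(sprintf("label vector length (%d) does not match observation count (%d)",
                 length(labels), n), call. = FALSE)
  }
  classes <- as.character(classes)
  labels <- as.character(labels)
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2L)) {
    bad <- classes[counts < 2L]
    stop(sprintf("calibration insufficient: class(es) %s have fewer than 2 labeled observations",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  C <- length(classes); F_ <- nrow(x)
  mu <- matrix(NA_real_, C, F_, dimnames = list(classes, rownames(x)))
  s2 <- mu
  for (i in seq_len(C)) {
    xi <- x[, labels == classes[i], drop = FALSE]
    m <- rowMeans(xi)
    mu[i, ] <- m
    s2[i, ] <- rowMeans((xi - m)^2)
  }
  structure(list(classes = classes, mu_hat = mu, sigma2_hat = s2,
                 n_per_class = setNames(counts, classes)),
            class = "class_stats")
}

#' Derive mixture z-scoring parameters
#'
#' Combines class-conditional statistics under fixed baseline weights `w`
#' into a per-feature offset and scale:
#' offset_f = sum_l w_l mu_hat\[l,f\],
#' scale_f = sqrt(sum_l w_l (sigma2_hat\[l,f\] + s\[l,f\])) with
#' s\[l,f\] = (mu_hat\[l,f\] - offset_f)^2, the between-class squared
#' deviation. `w` plays the role of the reference class balance: the
#' parameters equal what plain z-score parameters would have been had the
#' data's class balance been `w`.
#'
#' @param stats a `class_stats` object from [estimate_class_stats()].
#' @param w baseline mixture weights, length C, nonnegative, summing to 1.
#' @param subject optional subject identifier stored in the parameters.
#' @param layout optional feature-layout tag; defaults to a generic tag for
#'   the feature count.
#' @return a `mixture_params` object.
#' @export
compute_mixture_params <- function(stats, w, subject = NULL, layout = NULL) {
  stopifnot(inherits(stats, "class_stats"))
  C <- length(stats$classes)
  w <- as.numeric(w)
  if (length(w) != C || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("`w` must be a length-C nonnegative weight vector summing to 1",
         call. = FALSE)
  }
  offset <- as.numeric(crossprod(w, stats$mu_hat))          # w' mu_hat
  s <- sweep(stats$mu_hat, 2, offset)^2                     # (mu - w'mu)^2
  scale2 <- as.numeric(crossprod(w, stats$sigma2_hat + s))  # w'(sigma2 + s)
  if (any(scale2 <= 0)) {
    bad <- which(scale2 <= 0)
    stop(sprintf("degenerate feature(s) with zero mixture scale: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(w = setNames(w, stats$classes),
                 offset = offset, scale = sqrt(scale2), s = s,
                 class_stats = stats,
                 subject = subject %||% "unknown",
                 layout = layout %||% sprintf("generic-%d", ncol(stats$mu_hat)),
                 created = format(Sys.time(), "%Y-%m-%d")),
            class = "mixture_params")
}

#' Apply mixture standardization to a feature matrix
#'
#' Per feature f and observation i, Z_M\[f,i\] = (x\[f,i\] - offset_f) /
#' scale_f. The output marginal mean/sd are 0/1 only when the data's class
#' balance equals the baseline weights; under label shift they deliberately
#' differ, which is the point of the method.
#'
#' @param features a [feature_matrix()] (or numeric matrix), F x n.
#' @param params a `mixture_params` object with matching feature count and
#'   layout.
#' @return a standardized [feature_matrix()].
#' @export
apply_standardization <- function(features, params) {
  stopifnot(inherits(params, "mixture_params"))
  x <- as.matrix(features)
  if (nrow(x) != length(params$offset)) {
    stop(sprintf("feature count (%d) does not match parameters (%d features)",
                 nrow(x), length(params$offset)), call. = FALSE)
  }
  lay <- attr(features, "layout")
  if (!is.null(lay) && !identical(lay, params$layout)) {
    stop(sprintf("feature layout mismatch: data '%s' vs parameters '%s'",
                 lay, params$layout), call. = FALSE)
  }
  z <- (x - params$offset) / params$scale
  feature_matrix(z, standardized = TRUE, layout = params$layout)
}

#' Standard (marginal) z-scoring
#'
#' Per-feature centering by the marginal mean and scaling by the marginal
#' MLE standard deviation, so each output feature has mean 0 and sd 1.
#'
#' @param features a [feature_matrix()] or numeric matrix, F x n.
#' @return list with `features` (standardized [feature_matrix()]) and
#'   `params` (a `zscore_params` object with `mu`, `sigma`).
#' @export
standard_zscore <- function(features) {
  x <- as.matrix(features)
  mu <- rowMeans(x)
  sigma <- sqrt(rowMeans((x - mu)^2))
  if (any(sigma <= 0)) {
    stop(sprintf("degenerate feature(s) with zero variance: %s",
                 paste(which(sigma <= 0), collapse = ", ")), call. = FALSE)
  }
  z <- (x - mu) / sigma
  list(features = feature_matrix(z, standardized = TRUE,
                                 layout = attr(features, "layout")),
       params = structure(list(mu = mu, sigma = sigma),
                          class = "zscore_params"))
}

#' Write / read a calibration file
#'
#' Mixture z-scoring parameters serialize to a human-readable JSON file so
#' that a subject's calibration, estimated once from a small labeled sample,
#' can be reused to score other recordings from the same subject.
#'
#' @param params a `mixture_params` object.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `mixture_params` object.
#' @export
write_calibration <- function(params, path) {
  stopifnot(inherits(params, "mixture_params"))
  st <- params$class_stats
  obj <- list(version = "1",
              subject = params$subject,
              classes = st$classes,
              w = unname(params$w),
              mu_hat = st$mu_hat,
              sigma2_hat = st$sigma2_hat,
              n_per_class = unname(st$n_per_class),
              feature_layout = params$layout,
              created = params$created)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- structure(list(classes = obj$classes,
                       mu_hat = matrix(obj$mu_hat, nrow = length(obj$classes),
                                       dimnames = list(obj$classes, NULL)),
                       sigma2_hat = matrix(obj$sigma2_hat,
                                           nrow = length(obj$classes),
                                           dimnames = list(obj$classes, NULL)),
                       n_per_class = setNames(as.integer(obj$n_per_class),
                                              obj$classes)),
                  class = "class_stats")
  p <- compute_mixture_params(st, obj$w, subject = obj$subject,
                              layout = obj$feature_layout)
  p$created <- obj$created
  p
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> subject '%s', %d classes, %d features\n",
              x$subject, length(x$w), length(x$offset)))
  cat("  w:", paste(sprintf("%s=%.3f", names(x$w), x$w), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.mixture_params <- function(x, ...) {
  st <- x$class_stats
  tibble::tibble(
    feature = rep(seq_along(x$offset), each = length(st$classes)),
    class = rep(st$classes, times = length(x$offset)),
    mu_hat = as.vector(st$mu_hat),
    sigma2_hat = as.vector(st$sigma2_hat),
    w = rep(unname(x$w), times = length(x$offset))
  )
}

#' @export
glance.mixture_params <- function(x, ...) {
  tibble::tibble(subject = x$subject, n_classes = length(x$w),
                 n_features = length(x$offset),
                 n_calibration = sum(x$class_stats$n_per_class),
                 layout = x$layout)
}
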