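#' SS-ANN architecture configuration
#'
#' Three convolution - batch normalization - ReLU - max pooling blocks
#' (3x3 same-padded convolutions with 8, 16 and 32 filters; 2x2 pooling
#' with stride 2 and floor semantics) followed by a fully connected softmax
#' head. On 185 x 13 inputs the spatial maps shrink 185x13 -> 92x6 -> 46x3
#' -> 23x1, leaving 736 units for the final layer and 8,211 learnable
#' parameters in total.
#'
#' @param input_shape input image shape (height, width, channels).
#' @param conv_filters filters per convolution block.
#' @param kernel square kernel size.
#' @param pool pooling size and stride.
#' @param n_classes number of output classes.
#' @return an `ssann_config` object.
#' @export
ssann_config <- function(input_shape = c(185L, 13L, 1L),
                         conv_filters = c(8L, 16L, 32L),
                         kernel = 3L, pool = 2L, n_classes = 3L) {
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 n_classes = as.integer(n_classes)),
            class = "ssann_config")
}

#' Build an SS-ANN model
#'
#' Initializes weights (He-scaled Gaussian, seeded) and batch-norm state
#' for the configured architecture.
#'
#' @param config an [ssann_config()].
#' @param seed integer seed for weight initialization.
#' @return an `ssann` model object.
#' @export
build_model <- function(config = ssann_config(), seed = 1L) {
  set.seed(seed)
  H <- config$input_shape[1]; W <- config$input_shape[2]
  C_in <- config$input_shape[3]
  params <- list()
  for (l in seq_along(config$conv_filters)) {
    C_out <- config$conv_filters[l]
    sdev <- sqrt(2 / (9 * C_in))
    params[[paste0("conv", l)]] <- list(
      W = matrix(rnorm(C_out * 9 * C_in, sd = sdev), C_out, 9 * C_in),
      b = numeric(C_out),
      gamma = rep(1, C_out), beta = numeric(C_out))
    H <- H %/% 2L; W <- W %/% 2L
    if (H < 1L || W < 1L) {
      stop("architecture error: input too small for three pooling stages",
           call. = FALSE)
    }
    C_in <- C_out
  }
  n_flat <- C_in * H * W
  params$fc <- list(W = matrix(rnorm(config$n_classes * n_flat,
                                     sd = sqrt(2 / n_flat)),
                               config$n_classes, n_flat),
                    b = numeric(config$n_classes))
  state <- lapply(config$conv_filters, function(C)
    list(mean = numeric(C), var = rep(1, C)))
  structure(list(config = config, params = params, state = state,
                 layout = "ssann-185", trained = FALSE,
                 loss_trace = numeric(0), lr_trace = numeric(0)),
            class = "ssann")
}

#' @export
print.ssann <- function(x, ...) {
  cat(sprintf("<ssann> %s, %d parameters, %s\n",
              paste(x$config$conv_filters, collapse = "-"),
              count_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Count learnable parameters
#'
#' Counts convolution weights and biases, batch-normalization scale and
#' offset, and the final-layer weights and biases. Batch-norm running
#' statistics are not learnable and are excluded.
#'
#' @param model an `ssann` model.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ssann"))
  n <- 0L
  for (l in seq_along(model$config$conv_filters)) {
    p <- model$params[[paste0("conv", l)]]
    n <- n + length(p$W) + length(p$b) + length(p$gamma) + length(p$beta)
  }
  n + length(model$params$fc$W) + length(model$params$fc$b)
}

#' Oversample minority classes to balance
#'
#' Classes with fewer examples than the largest class are topped up by
#' sampling with replacement from themselves, so every class count equals
#' the original maximum.
#'
#' @param images an `epoch_images` array (F x context x n).
#' @param labels stage codes per image.
#' @param seed integer seed.
#' @return list with resampled `images` and `labels` (and the index used).
#' @export
oversample_balance <- function(images, labels, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < 1L)) stop("every class needs at least one example", call. = FALSE)
  set.seed(seed)
  target <- max(counts)
  extra <- unlist(lapply(names(counts), function(cl) {
    pool <- which(labels == as.integer(cl))
    need <- target - length(pool)
    if (need > 0) sample(pool, need, replace = TRUE) else integer(0)
  }))
  idx <- c(seq_along(labels), extra)
  list(images = images[, , idx, drop = FALSE], labels = labels[idx],
       index = idx)
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum 0.9 (configurable), mini-batch
#' size 256, 10 epochs, initial learning rate 0.015 decayed by 15% each
#' epoch (lr_e = 0.015 * 0.85^e).
#'
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative per-epoch decay.
#' @param momentum momentum coefficient.
#' @param seed integer seed for shuffling.
#' @return a `train_config` object.
#' @export
train_config <- function(batch_size = 256L, epochs = 10L, lr0 = 0.015,
                         lr_decay = 0.85, momentum = 0.9, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay = lr_decay, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train SS-ANN
#'
#' Cross-entropy training by SGD with momentum on standardized epoch
#' images (balance the classes first with [oversample_balance()]).
#'
#' @param model an `ssann` from [build_model()].
#' @param images standardized `epoch_images` (F x context x n).
#' @param labels stage codes per image.
#' @param config a [train_config()].
#' @return the trained model, with per-epoch `loss_trace` and `lr_trace`.
#' @export
train_ssann <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "ssann"))
  labels <- as.integer(labels)
  n <- dim(images)[3]
  stopifnot(length(labels) == n)
  set.seed(config$seed)
  vel <- grad_zero(model)
  loss_trace <- numeric(config$epochs)
  lr_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr0 * config$lr_decay^(ep - 1)
    lr_trace[ep] <- lr
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      X <- matrix(images[, , idx, drop = FALSE],
                  nrow = model$config$input_shape[3])
      fw <- ssann_forward(model, X, B, training = TRUE, keep = TRUE)
      model <- fw$model
      bk <- ssann_backward(model, fw, labels[idx], B)
      if (!is.finite(bk$loss)) {
        stop(sprintf("divergence: non-finite loss at epoch %d (lr %.4g)",
                     ep, lr), call. = FALSE)
      }
      losses <- c(losses, bk$loss)
      upd <- sgd_update(model, vel, bk$grads, lr, config$momentum)
      model <- upd$model; vel <- upd$vel
    }
    loss_trace[ep] <- mean(losses)
  }
  model$trained <- TRUE
  model$loss_trace <- loss_trace
  model$lr_trace <- lr_trace
  model
}

grad_zero <- function(model) {
  rapply(model$params, function(w) w * 0, how = "replace")
}

sgd_update <- function(model, vel, grads, lr, mom) {
  for (nm in c("conv1", "conv2", "conv3", "fc")) {
    for (fld in names(grads[[nm]])) {
      vel[[nm]][[fld]] <- mom * vel[[nm]][[fld]] - lr * grads[[nm]][[fld]]
      model$params[[nm]][[fld]] <- model$params[[nm]][[fld]] + vel[[nm]][[fld]]
    }
  }
  list(model = model, vel = vel)
}

#' Predict sleep stages for epoch images
#'
#' Softmax probabilities (batch-norm in inference mode, using training-set
#' running statistics) and argmax stage labels.
#'
#' @param object a trained `ssann`.
#' @param images `epoch_images` with the model's input layout.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return a `stage_prediction` tibble: `epoch`, `stage` (code), and class
#'   probabilities `p_rem`, `p_wake`, `p_nrem`.
#' @export
predict.ssann <- function(object, images, batch_size = 512L, ...) {
  lay <- attr(images, "layout")
  if (!is.null(lay) && !identical(lay, object$layout)) {
    stop(sprintf("image layout '%s' does not match model layout '%s'",
                 lay, object$layout), call. = FALSE)
  }
  d <- dim(images)
  if (d[1] != object$config$input_shape[1] ||
      d[2] != object$config$input_shape[2]) {
    stop("image shape does not match the model input shape", call. = FALSE)
  }
  n <- d[3]
  probs <- matrix(NA_real_, 3, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- matrix(images[, , idx, drop = FALSE],
                nrow = object$config$input_shape[3])
    fw <- ssann_forward(object, X, length(idx), training = FALSE)
    probs[, idx] <- softmax_cols(fw$logits)
  }
  out <- tibble::tibble(epoch = seq_len(n),
                        stage = apply(probs, 2, which.max),
                        p_rem = probs[1, ], p_wake = probs[2, ],
                        p_nrem = probs[3, ])
  class(out) <- c("stage_prediction", class(out))
  out
}

#' Merge sub-5-second bouts into their surroundings
#'
#' Scans left to right and reassigns every maximal interior run of
#' identical stage labels shorter than 5 s: to the shared neighboring
#' stage when the two neighbors agree, otherwise to the preceding stage.
#' Runs touching the record edges are truncated observations and are
#' left alone. Repeats until no interior sub-5 s bout remains; the
#' operation is idempotent.
#'
#' @param labels stage codes or a [label_series()].
#' @param epoch_len epoch length in seconds.
#' @return a [label_series()] of refined labels.
#' @export
refine_bouts <- function(labels, epoch_len = 2.5) {
  x <- as.integer(labels)
  el <- if (inherits(labels, "label_series")) attr(labels, "epoch_len") else epoch_len
  repeat {
    r <- rle(x)
    nr <- length(r$lengths)
    if (nr <= 2L) break
    short <- which(r$lengths * el < 5)
    short <- short[short > 1L & short < nr]  # edge runs are truncated bouts
    if (length(short) == 0L) break
    # shared-neighbor stage when the neighbors agree; otherwise the
    # preceding stage
    i <- short[1]
    r$values[i] <- r$values[i - 1]
    x <- inverse.rle(r)
  }
  label_series(x, epoch_len = el)
}

#' Evaluate predictions against reference labels
#'
#' Confusion matrix (rows = truth, columns = prediction), per-class
#' precision and recall, overall accuracy, and one-vs-rest ROC curves with
#' AUC and a label-permutation p-value against chance.
#'
#' @param pred a `stage_prediction` (from [predict.ssann()]) or a vector of
#'   predicted stage codes.
#' @param truth a [label_series()] or vector of true stage codes.
#' @param n_perm permutations for the AUC null distribution.
#' @param seed integer seed for the permutation test.
#' @return an `ssann_evaluation` object.
#' @export
evaluate_predictions <- function(pred, truth, n_perm = 200L, seed = 1L) {
  truth <- as.integer(truth)
  if (inherits(pred, "stage_prediction")) {
    labels <- as.integer(pred$stage)
    probs <- rbind(pred$p_rem, pred$p_wake, pred$p_nrem)
  } else {
    labels <- as.integer(pred)
    probs <- NULL
  }
  if (length(labels) != length(truth)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  cm <- table(factor(truth, 1:3, STAGES), factor(labels, 1:3, STAGES))
  names(dimnames(cm)) <- c("truth", "prediction")
  acc <- sum(diag(cm)) / sum(cm)
  precision <- diag(cm) / pmax(colSums(cm), 1)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  roc <- NULL
  if (!is.null(probs)) {
    set.seed(seed)
    roc <- lapply(1:3, function(cl) {
      resp <- as.integer(truth == cl)
      if (length(unique(resp)) < 2) return(NULL)
      r <- pROC::roc(resp, probs[cl, ], quiet = TRUE, direction = "<")
      a <- as.numeric(pROC::auc(r))
      null_auc <- vapply(seq_len(n_perm), function(i) {
        as.numeric(pROC::auc(pROC::roc(sample(resp), probs[cl, ],
                                       quiet = TRUE, direction = "<")))
      }, numeric(1))
      list(stage = STAGES[cl], auc = a,
           p_value = (1 + sum(null_auc >= a)) / (n_perm + 1),
           curve = tibble::tibble(fpr = 1 - r$specificities,
                                  tpr = r$sensitivities))
    })
    roc <- roc[!vapply(roc, is.null, logical(1))]
  }
  structure(list(confusion = cm, accuracy = acc, precision = precision,
                 recall = recall, roc = roc),
            class = "ssann_evaluation")
}

#' @export
print.ssann_evaluation <- function(x, ...) {
  cat(sprintf("<ssann_evaluation> accuracy %.1f%%\n", 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.ssann_evaluation <- function(x, ...) {
  tibble::tibble(stage = STAGES,
                 precision = unname(x$precision),
                 recall = unname(x$recall),
                 auc = if (length(x$roc)) {
                   vapply(STAGES, function(s) {
                     hit <- Filter(function(r) r$stage == s, x$roc)
                     if (length(hit)) hit[[1]]$auc else NA_real_
                   }, numeric(1))
                 } else NA_real_)
}

#' @export
glance.ssann_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$confusion),
                 mean_auc = if (length(x$roc))
                   mean(vapply(x$roc, `[[`, numeric(1), "auc")) else NA_real_)
}

#' @export
autoplot.ssann_evaluation <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(STAGES)) +
    ggplot2::labs(title = sprintf("accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}
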