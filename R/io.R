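#' Read and write recordings as columnar text
#'
#' Two numeric columns (eeg, emg) after a header line
#' `# fs=<Hz> subject=<id>`.
#'
#' @param rec a [recording()].
#' @param path file path.
#' @return `read_recording` returns a [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject=%s", rec$fs, rec$subject_id), con)
  writeLines("eeg\temg", con)
  writeLines(sprintf("%.8g\t%.8g", rec$eeg, rec$emg), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1L)
  fs <- as.numeric(sub(".*fs=([0-9.]+).*", "\\1", hdr))
  subject <- sub(".*subject=([^ ]+).*", "\\1", hdr)
  df <- if (requireNamespace("data.table", quietly = TRUE)) {
    as.data.frame(data.table::fread(path, skip = 1L))
  } else {
    read.delim(path, skip = 1L)
  }
  recording(df[[1]], df[[2]], fs = fs, subject_id = subject)
}

#' Read and write per-epoch label files
#'
#' CSV with header `epoch,stage`; `stage` is a name in REM/Wake/NREM.
#'
#' @param labels a [label_series()].
#' @param path file path.
#' @param epoch_len epoch length in seconds (stored in a comment-free
#'   sidecar column on write; supplied on read).
#' @return `read_labels` returns a [label_series()]; `write_labels`
#'   returns `path` invisibly.
#' @export
write_labels <- function(labels, path, epoch_len = NULL) {
  stopifnot(inherits(labels, "label_series"))
  el <- epoch_len %||% attr(labels, "epoch_len")
  df <- data.frame(epoch = seq_along(labels),
                   stage = stage_names(labels),
                   epoch_len = el)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, epoch_len = NULL) {
  df <- read.csv(path)
  el <- epoch_len %||% (if ("epoch_len" %in% names(df)) df$epoch_len[1] else 2.5)
  label_series(df$stage[order(df$epoch)], epoch_len = el)
}

#' Read and write prediction files
#'
#' CSV with columns `epoch,stage,p_rem,p_wake,p_nrem`.
#'
#' @param pred a `stage_prediction` tibble.
#' @param path file path.
#' @return `read_predictions` returns a `stage_prediction` tibble;
#'   `write_predictions` returns `path` invisibly.
#' @export
write_predictions <- function(pred, path) {
  df <- data.frame(epoch = pred$epoch, stage = STAGES[pred$stage],
                   p_rem = pred$p_rem, p_wake = pred$p_wake,
                   p_nrem = pred$p_nrem)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- read.csv(path)
  out <- tibble::tibble(epoch = df$epoch,
                        stage = match(df$stage, STAGES),
                        p_rem = df$p_rem, p_wake = df$p_wake,
                        p_nrem = df$p_nrem)
  class(out) <- c("stage_prediction", class(out))
  out
}

#' Save and load SS-ANN checkpoints
#'
#' Single-file JSON checkpoint holding the configuration, all weights,
#' batch-norm running statistics and the feature-layout fingerprint.
#'
#' @param model an `ssann`.
#' @param path file path.
#' @return `load_ssann` returns an `ssann`; `save_ssann` returns `path`
#'   invisibly.
#' @export
save_ssann <- function(model, path) {
  stopifnot(inherits(model, "ssann"))
  obj <- list(version = "1", layout = model$layout, trained = model$trained,
              config = unclass(model$config),
              params = model$params,
              state = model$state,
              loss_trace = model$loss_trace, lr_trace = model$lr_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ssann
#' @export
load_ssann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(ssann_config, obj$config)
  model <- build_model(cfg)
  as_mat <- function(w, nr, nc) {
    if (is.matrix(w)) w else matrix(unlist(w), nr, nc, byrow = TRUE)
  }
  for (l in 1:3) {
    nm <- paste0("conv", l)
    C_out <- cfg$conv_filters[l]
    C_in <- if (l == 1) cfg$input_shape[3] else cfg$conv_filters[l - 1]
    model$params[[nm]]$W <- as_mat(obj$params[[nm]]$W, C_out, 9 * C_in)
    model$params[[nm]]$b <- as.numeric(obj$params[[nm]]$b)
    model$params[[nm]]$gamma <- as.numeric(obj$params[[nm]]$gamma)
    model$params[[nm]]$beta <- as.numeric(obj$params[[nm]]$beta)
    model$state[[l]] <- list(mean = as.numeric(obj$state[[l]]$mean),
                             var = as.numeric(obj$state[[l]]$var))
  }
  model$params$fc$W <- as_mat(obj$params$fc$W, cfg$n_classes,
                              length(obj$params$fc$W) / cfg$n_classes)
  model$params$fc$b <- as.numeric(obj$params$fc$b)
  model$layout <- obj$layout
  model$trained <- isTRUE(obj$trained)
  model$loss_trace <- as.numeric(obj$loss_trace)
  model$lr_trace <- as.numeric(obj$lr_trace)
  model
}

#' Read and write feature matrices as columnar text
#'
#' Tab-separated numeric columns (one per epoch) after a single header
#' line `# layout=<tag> standardized=<0|1> features=<F> epochs=<n>`.
#'
#' @param features a [feature_matrix()].
#' @param path file path.
#' @return `read_features` returns a [feature_matrix()]; `write_features`
#'   returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  x <- as.matrix(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layout=%s standardized=%d features=%d epochs=%d",
                     feature_layout(features),
                     as.integer(is_standardized(features)),
                     nrow(x), ncol(x)), con)
  utils::write.table(x, con, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 1L)
  lay <- sub(".*layout=([^ ]+).*", "\\1", hdr)
  std <- sub(".*standardized=([01]).*", "\\1", hdr) == "1"
  m <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(m) <- NULL
  feature_matrix(m, standardized = std, layout = lay)
}
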