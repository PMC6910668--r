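#' Calibrate mixture z-scoring for a subject
#'
#' Computes the 185-feature matrix for the recording, estimates the
#' class-conditional statistics on the labeled epochs only (at least two
#' per stage), and returns the mixture parameters. The parameters are
#' reusable across recordings from the same subject; persist them with
#' [write_calibration()].
#'
#' @param rec a [recording()].
#' @param partial_labels sparse labels: tibble/data.frame with columns
#'   `epoch` (1-based index) and `stage` (name or code), or a full
#'   [label_series()].
#' @param w baseline mixture weights over (REM, Wake, NREM); typically the
#'   training-set class balance of the classifier that will be applied.
#' @param epoch_len epoch length in seconds.
#' @param features optional precomputed unstandardized [feature_matrix()]
#'   for `rec` (skips preprocessing).
#' @return a `mixture_params` object.
#' @export
calibrate_subject <- function(rec, partial_labels,
                              w = c(REM = 0.10, Wake = 0.45, NREM = 0.45),
                              epoch_len = 2.5, features = NULL) {
  feats <- features %||% preprocess_recording(rec, epoch_len = epoch_len)
  if (inherits(partial_labels, "label_series")) {
    lab <- tibble::tibble(epoch = seq_along(partial_labels),
                          stage = as.integer(partial_labels))
  } else {
    lab <- tibble::as_tibble(partial_labels)
    if (is.character(lab$stage) || is.factor(lab$stage)) {
      lab$stage <- match(as.character(lab$stage), STAGES)
    }
  }
  lab <- lab[lab$epoch >= 1 & lab$epoch <= ncol(feats), ]
  present <- sort(unique(lab$stage))
  missing <- setdiff(1:3, present)
  counts <- table(factor(lab$stage, 1:3))
  if (length(missing) > 0 || any(counts < 2)) {
    bad <- STAGES[union(missing, which(counts < 2))]
    stop(sprintf("calibration insufficient: stage(s) %s need at least 2 labeled epochs",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  st <- estimate_class_stats(as.matrix(feats)[, lab$epoch, drop = FALSE],
                             labels = lab$stage, classes = 1:3)
  st$classes <- STAGES
  rownames(st$mu_hat) <- rownames(st$sigma2_hat) <- STAGES
  names(st$n_per_class) <- STAGES
  w <- w[STAGES]
  compute_mixture_params(st, unname(w), subject = rec$subject_id,
                         layout = feature_layout(feats))
}

#' Score a recording automatically
#'
#' Full scoring pipeline: preprocess, mixture-standardize with the
#' subject's calibration, assemble context images, classify with SS-ANN,
#' and merge sub-5-second bouts.
#'
#' @param rec a [recording()].
#' @param params the subject's `mixture_params`.
#' @param model a trained `ssann`.
#' @param epoch_len epoch length in seconds; must match the model's
#'   training resolution.
#' @param refine merge sub-5-second bouts after classification.
#' @param features optional precomputed unstandardized [feature_matrix()].
#' @return a `stage_prediction` tibble with the refined `stage` column.
#' @export
score_recording <- function(rec, params, model, epoch_len = 2.5,
                            refine = TRUE, features = NULL) {
  stopifnot(inherits(params, "mixture_params"), inherits(model, "ssann"))
  if (!identical(params$layout, model$layout)) {
    stop(sprintf("calibration layout '%s' does not match model layout '%s'",
                 params$layout, model$layout), call. = FALSE)
  }
  feats <- features %||% preprocess_recording(rec, epoch_len = epoch_len)
  z <- apply_standardization(feats, params)
  imgs <- make_epoch_images(z)
  pr <- predict(model, imgs)
  if (refine) {
    pr$stage <- as.integer(refine_bouts(pr$stage, epoch_len = epoch_len))
  }
  pr
}

#' Accuracy as a function of the labeled calibration budget
#'
#' Emulates the workflow where a user hand-labels a few minutes of data for
#' mixture z-scoring: for each budget, randomly held-out labeled epochs
#' (redrawn until every stage has at least two) provide the calibration,
#' the remainder of the recording is scored, and accuracy on the remainder
#' is recorded. Repeats give mean and SEM per budget.
#'
#' @param rec a [recording()].
#' @param labels the full reference [label_series()].
#' @param model a trained `ssann`.
#' @param budgets_min labeled-data budgets in minutes.
#' @param w baseline mixture weights over (REM, Wake, NREM).
#' @param repeats random draws per budget.
#' @param seed integer seed.
#' @param epoch_len epoch length in seconds.
#' @return a `budget_sweep` tibble: `budget_min`, `draw`, `accuracy`.
#' @export
label_budget_sweep <- function(rec, labels, model,
                               budgets_min = c(0.5, 1, 2, 5, 10),
                               w = c(REM = 0.10, Wake = 0.45, NREM = 0.45),
                               repeats = 3L, seed = 1L, epoch_len = 2.5) {
  feats <- preprocess_recording(rec, epoch_len = epoch_len)
  n <- ncol(feats)
  truth <- as.integer(labels)[seq_len(n)]
  set.seed(seed)
  rows <- list()
  for (budget in budgets_min) {
    m <- round(budget * 60 / epoch_len)
    if (m > n) stop(sprintf("budget %.1f min exceeds the recording", budget),
                    call. = FALSE)
    for (rep_i in seq_len(repeats)) {
      idx <- NULL
      for (try_i in 1:50) {
        cand <- sample.int(n, m)
        if (all(table(factor(truth[cand], 1:3)) >= 2)) { idx <- cand; break }
        message("budget draw lacked a stage; resampled")
      }
      if (is.null(idx)) {
        stop(sprintf("budget %.1f min cannot cover every stage twice", budget),
             call. = FALSE)
      }
      params <- calibrate_subject(rec, tibble::tibble(epoch = idx,
                                                      stage = truth[idx]),
                                  w = w, features = feats)
      pr <- score_recording(rec, params, model, features = feats)
      rest <- setdiff(seq_len(n), idx)
      acc <- mean(pr$stage[rest] == truth[rest])
      rows[[length(rows) + 1L]] <- tibble::tibble(budget_min = budget,
                                                  draw = rep_i,
                                                  accuracy = acc)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("budget_sweep", class(out))
  out
}

#' @export
glance.budget_sweep <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x, .data$budget_min),
                        mean_accuracy = mean(.data$accuracy),
                        sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                        .groups = "drop")
  tibble::tibble(
    n_budgets = nrow(s),
    max_accuracy = max(s$mean_accuracy),
    plateau_budget = s$budget_min[which(s$mean_accuracy >=
                                          max(s$mean_accuracy) - 0.01)[1]])
}

#' @export
autoplot.budget_sweep <- function(object, ...) {
  s <- dplyr::summarise(dplyr::group_by(object, .data$budget_min),
                        mean_accuracy = mean(.data$accuracy),
                        sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                        .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$budget_min,
                                  y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$sem,
                                      ymax = .data$mean_accuracy + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "labeled data for calibration (minutes)",
                  y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' Run a named experiment from a configuration
#'
#' Dispatcher reproducing the package's experiments end to end. Selectors:
#' `simulate` (two-subject standardization experiment), `synth` (write a
#' synthetic labeled recording), `preprocess`, `calibrate`, `score`,
#' `rebalance`, `evaluate`, `sweep`. Every report embeds the seed and a
#' hash of the configuration for provenance.
#'
#' @param config named list with at least `experiment` and `seed`;
#'   path-valued entries as each selector requires (see the CLI script in
#'   `inst/cli` for the file-based interface).
#' @return a report list; file-writing selectors also write their outputs.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config), !is.null(config$experiment))
  seed <- as.integer(config$seed %||% 1L)
  cfg_hash <- digest_config(config)
  report <- switch(
    config$experiment,
    simulate = {
      rep <- run_shift_experiment(seed = seed)
      list(report = as.data.frame(rep), summary = as.data.frame(glance(rep)))
    },
    synth = {
      sp <- subject_spec(seed = seed,
                         duration = as.numeric(config$duration %||% 3600))
      bundle <- synth_subject(sp)
      if (!is.null(config$out_signals)) {
        write_recording(bundle$recording, config$out_signals)
      }
      if (!is.null(config$out_labels)) {
        write_labels(bundle$labels, config$out_labels)
      }
      list(balance = as.list(stage_balance(bundle$labels)),
           n_epochs = length(bundle$labels))
    },
    preprocess = {
      rec <- read_recording(config$signals)
      feats <- preprocess_recording(rec)
      list(n_features = nrow(feats), n_epochs = ncol(feats))
    },
    calibrate = {
      rec <- read_recording(config$signals)
      lab <- read_labels(config$labels)
      params <- calibrate_subject(rec, lab)
      if (!is.null(config$out)) write_calibration(params, config$out)
      as.data.frame(glance(params))
    },
    score = {
      rec <- read_recording(config$signals)
      params <- read_calibration(config$calibration)
      model <- load_ssann(config$model)
      pr <- score_recording(rec, params, model)
      if (!is.null(config$out)) write_predictions(pr, config$out)
      list(balance = as.list(stage_balance(label_series(pr$stage))),
           n_epochs = nrow(pr))
    },
    rebalance = {
      rec <- read_recording(config$signals)
      lab <- read_labels(config$labels)
      target <- c(Wake = as.numeric(config$wake),
                  NREM = as.numeric(config$nrem),
                  REM = as.numeric(config$rem))
      rb <- rebalance_recording(rec, lab, target, seed = seed)
      if (!is.null(config$out_signals)) {
        write_recording(rb$recording, config$out_signals)
      }
      if (!is.null(config$out_labels)) write_labels(rb$labels, config$out_labels)
      list(achieved = as.list(rb$achieved), removed_epochs = rb$removed_epochs)
    },
    evaluate = {
      pred <- read_predictions(config$predictions)
      lab <- read_labels(config$labels)
      ev <- evaluate_predictions(pred, lab, seed = seed)
      c(as.list(glance(ev)), list(confusion = unclass(ev$confusion)))
    },
    sweep = {
      rec <- read_recording(config$signals)
      lab <- read_labels(config$labels)
      model <- load_ssann(config$model)
      sw <- label_budget_sweep(rec, lab, model, seed = seed)
      as.data.frame(sw)
    },
    stop(sprintf("unknown experiment selector '%s'", config$experiment),
         call. = FALSE)
  )
  out <- list(experiment = config$experiment, seed = seed,
              config_hash = cfg_hash,
              package_version = as.character(utils::packageVersion("somnoshift")),
              report = report)
  if (!is.null(config$report)) {
    jsonlite::write_json(out, config$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(out)
}

# stable short hash of a configuration list (provenance stamp)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}
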