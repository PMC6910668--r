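#' Segment a label series into bouts
#'
#' Maximal runs of identical stage labels, half-open epoch intervals
#' \[start, end). Concatenating the bouts reconstructs the series exactly.
#'
#' @param labels a [label_series()] or stage-code vector.
#' @return tibble with `stage` (code), `start_epoch`, `end_epoch`, `length`.
#' @export
segment_bouts <- function(labels) {
  x <- as.integer(labels)
  r <- rle(x)
  end <- cumsum(r$lengths)
  tibble::tibble(stage = r$values,
                 start_epoch = c(0L, head(end, -1L)),
                 end_epoch = end,
                 length = r$lengths)
}

#' Total variation distance between balance vectors
#'
#' The L1 norm sum |q_i - q2_i| over the three stage occupancies (range
#' 0 to 2; no 1/2 factor).
#'
#' @param q,q2 named occupancy vectors over (Wake, NREM, REM) summing to 1.
#' @return nonnegative scalar.
#' @export
total_variation <- function(q, q2) {
  for (v in list(q, q2)) {
    if (abs(sum(v) - 1) > 1e-6 || any(v < -1e-12)) {
      stop("balance vectors must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  if (!is.null(names(q)) && !is.null(names(q2))) q2 <- q2[names(q)]
  sum(abs(q - q2))
}

#' Rebalance a labeled recording to a target stage occupancy
#'
#' Randomly removes whole bouts (seeded) until the achieved balance is
#' within `tol` of the target per stage. Bouts whose removal would strip
#' the required REM context are never removed: every retained REM bout
#' keeps at least 8 s of NREM immediately before it and at least 4 s of
#' Wake immediately after it (truncation at the record start is permitted).
#' Signal samples are removed in register with removed epochs.
#'
#' Supported targets span 5-95% wakefulness, 5-95% NREM and 0-25% REM.
#'
#' @param rec a [recording()].
#' @param labels a [label_series()] matching `rec`.
#' @param target named target proportions (Wake, NREM, REM) summing to 1.
#' @param seed integer seed.
#' @param tol per-stage tolerance on the achieved balance.
#' @return list with `recording`, `labels`, `achieved` (balance vector) and
#'   `removed_epochs`.
#' @export
rebalance_recording <- function(rec, labels, target, seed = 1L, tol = 0.01) {
  stopifnot(inherits(rec, "recording"), inherits(labels, "label_series"))
  target <- target[c("Wake", "NREM", "REM")]
  if (abs(sum(target) - 1) > 1e-9) stop("target must sum to 1", call. = FALSE)
  if (target[["Wake"]] < 0.05 || target[["Wake"]] > 0.95 ||
      target[["NREM"]] < 0.05 || target[["NREM"]] > 0.95 ||
      target[["REM"]] < 0 || target[["REM"]] > 0.25) {
    stop("target outside the supported region (Wake 5-95%, NREM 5-95%, REM 0-25%)",
         call. = FALSE)
  }
  el <- attr(labels, "epoch_len")
  spe <- as.integer(el * rec$fs)
  set.seed(seed)
  keep <- rep(TRUE, length(labels))
  x <- as.integer(labels)

  nrem_ctx <- ceiling(8 / el)  # >= 8 s NREM before each REM bout
  wake_ctx <- ceiling(4 / el)  # >= 4 s Wake after each REM bout

  current_bouts <- function(keep) segment_bouts(label_series(x[keep], el))

  protected <- function(b) {
    # bouts adjacent to a REM bout whose removal would break its context
    prot <- rep(FALSE, nrow(b))
    remi <- which(b$stage == 1L)
    for (i in remi) {
      if (i > 1 && b$stage[i - 1] == 3L) prot[i - 1] <- TRUE
      if (i < nrow(b) && b$stage[i + 1] == 2L) prot[i + 1] <- TRUE
    }
    prot
  }

  # Randomized two-phase search, restarted a few times if it stalls.
  # Phase 1 plans per-stage epoch-removal quotas from the target and fills
  # them by large-first subset selection over removable bouts (so short
  # fragments survive for fine adjustment; bouts whose removal would merge
  # two same-stage neighbors are deprioritized because merging destroys
  # granularity). Phase 2 polishes with a best-improvement loop over
  # single bouts until every stage is within tolerance.
  tgt <- c(target[["REM"]], target[["Wake"]], target[["NREM"]])  # code order

  # drop one or several bouts of the SAME bout table `b` against the keep
  # vector `b` was computed from (bouts are disjoint, so one position
  # snapshot serves them all; re-deriving positions between drops would
  # shift the mapping and remove the wrong epochs)
  drop_bouts <- function(keep, b, idx) {
    kept_pos <- which(keep)
    for (i in idx) {
      keep[kept_pos[(b$start_epoch[i] + 1L):b$end_epoch[i]]] <- FALSE
    }
    keep
  }

  merges_neighbors <- function(b) {
    n <- nrow(b)
    pre <- c(NA_integer_, b$stage[-n])
    nxt <- c(b$stage[-1], NA_integer_)
    !is.na(pre) & !is.na(nxt) & pre == nxt
  }

  attempt <- function(keep) {
    # --- phase 1: quota planning -----------------------------------------
    b <- current_bouts(keep)
    counts <- tabulate(x[keep], 3L)
    rem_bouts <- which(b$stage == 1L)
    # Two REM-removal policies are tried: dropping the largest bouts first
    # preserves small bouts for fine adjustment, while dropping the
    # smallest first minimizes the number of retained REM bouts and hence
    # the NREM/Wake context epochs that must stay whole (which binds for
    # wake-heavy targets). The feasible plan retaining the most data wins.
    orders <- list(rem_bouts[order(b$length[rem_bouts], decreasing = TRUE)],
                   rem_bouts[order(b$length[rem_bouts])])
    plan <- NULL
    for (rem_order in orders) {
      rem_lens <- b$length[rem_order]
      for (k in 0:length(rem_bouts)) {
        R_k <- counts[1L] - sum(head(rem_lens, k))
        n_f <- min(if (tgt[1] > 0) R_k / tgt[1] else Inf,
                   counts[2L] / tgt[2], counts[3L] / tgt[3])
        if (!is.finite(n_f) || n_f < 10) next  # degenerate, no output left
        rem_over <- if (tgt[1] > 0) R_k / n_f > tgt[1] + tol else R_k > 0
        if (rem_over && k < length(rem_bouts)) next
        # feasibility: removable epochs per stage must cover the quotas,
        # with protection recomputed as if the chosen REM bouts were gone;
        # a stage may keep up to (target + tol) * n_f epochs, so only the
        # excess beyond that must be removable
        drop_rem <- head(rem_order, k)
        b2 <- b; if (k > 0) b2 <- b[-drop_rem, ]
        prot2 <- protected(b2)
        q <- pmax(0, c(R_k - tgt[1] * n_f,
                       counts[2L] - tgt[2] * n_f,
                       counts[3L] - tgt[3] * n_f))
        q_need <- pmax(0, c(R_k, counts[2L], counts[3L]) - (tgt + tol) * n_f)
        removable <- vapply(2:3, function(sc)
          sum(b2$length[b2$stage == sc & !prot2]), numeric(1))
        if (q_need[2] <= removable[1] && q_need[3] <= removable[2]) {
          if (is.null(plan) || n_f > plan$n_f) {
            plan <- list(drop_rem = drop_rem, quota = q, n_f = n_f)
          }
          break
        }
      }
    }
    if (is.null(plan)) return(NULL)
    keep <- drop_bouts(keep, b, plan$drop_rem)
    # large-first subset selection per stage, random jitter for tie-breaks
    slack <- max(1, floor(tol * plan$n_f / 2))
    for (sc in c(2L, 3L)) {
      quota <- plan$quota[sc]
      if (quota < 1) next
      b <- current_bouts(keep)
      prot <- protected(b)
      merges <- merges_neighbors(b)
      cand <- which(b$stage == sc & !prot)
      key <- b$length[cand] * runif(length(cand), 0.9, 1.1) -
        1e6 * merges[cand]  # merge-causing bouts go last
      chosen <- integer(0)
      for (i in cand[order(key, decreasing = TRUE)]) {
        if (b$length[i] <= quota + slack) {
          chosen <- c(chosen, i)
          quota <- quota - b$length[i]
          if (quota <= slack) break
        }
      }
      keep <- drop_bouts(keep, b, chosen)
    }
    # --- phase 2: best-improvement polish --------------------------------
    for (iter in seq_len(1000L)) {
      lab_now <- x[keep]
      n_now <- length(lab_now)
      counts <- tabulate(lab_now, 3L)
      cur_dev <- max(abs(counts / n_now - tgt))
      if (cur_dev <= tol) return(keep)
      b <- segment_bouts(label_series(lab_now, el))
      cand <- which(!protected(b) & b$length < n_now)
      if (length(cand) == 0L) return(NULL)
      after_counts <- matrix(counts, 3L, length(cand))
      after_counts[cbind(b$stage[cand], seq_along(cand))] <-
        counts[b$stage[cand]] - b$length[cand]
      after_n <- n_now - b$length[cand]
      after_dev <- apply(abs(after_counts / rep(after_n, each = 3L) - tgt),
                         2, max)
      best <- min(after_dev)
      if (best >= cur_dev) return(NULL)
      near <- cand[after_dev <= best + 0.002]
      # among near-best, prefer not merging neighbors
      merges <- merges_neighbors(b)
      nm <- near[!merges[near]]
      if (length(nm)) near <- nm
      pick <- near[sample.int(length(near), 1)]
      keep <- drop_bouts(keep, b, pick)
    }
    NULL
  }

  keep0 <- keep
  result <- NULL
  for (try_i in 1:8) {
    res <- attempt(keep0)
    if (!is.null(res)) { result <- res; break }
  }
  if (is.null(result)) {
    bal <- stage_balance(x[keep0])
    stop(sprintf(paste0("rebalance infeasible: target unreachable by bout ",
                        "removal; best achievable balance Wake %.3f NREM ",
                        "%.3f REM %.3f"),
                 bal[["Wake"]], bal[["NREM"]], bal[["REM"]]),
         call. = FALSE)
  }
  keep <- result

  sample_keep <- rep(keep, each = spe)
  n_sig <- length(labels) * spe
  out_rec <- recording(rec$eeg[seq_len(n_sig)][sample_keep],
                       rec$emg[seq_len(n_sig)][sample_keep],
                       fs = rec$fs, subject_id = rec$subject_id)
  out_lab <- label_series(x[keep], el)
  list(recording = out_rec, labels = out_lab,
       achieved = stage_balance(out_lab),
       removed_epochs = sum(!keep))
}

#' Classifier-bias experiment over a balance grid
#'
#' For each synthetic subject and each target balance, rebalances the
#' subject's evaluation recording, scores it with the standard-z-scoring
#' arm and the mixture-z-scoring arm, and records the total variation
#' distance between predicted and true stage occupancies. Returns the
#' per-grid-point table plus mean TVD per arm and a paired t-test.
#'
#' @param model_std SS-ANN trained on standard-z-scored features.
#' @param model_mix SS-ANN trained on mixture-z-scored features.
#' @param subjects list of subject bundles; each needs `recording`, `labels`
#'   and `params` (the subject's [compute_mixture_params()] calibration).
#' @param balance_grid tibble/data.frame of target balances with columns
#'   `Wake`, `NREM`, `REM`.
#' @param train_balance the training-set class balance (used to audit the
#'   contraction direction of the standard arm).
#' @param seed integer seed.
#' @param refine apply [refine_bouts()] to predictions.
#' @return a `bias_experiment` tibble; `glance()` yields the arm means and
#'   the paired test.
#' @export
bias_experiment <- function(model_std, model_mix, subjects, balance_grid,
                            train_balance = c(Wake = 0.45, NREM = 0.45, REM = 0.10),
                            seed = 1L, refine = TRUE) {
  grid <- as.data.frame(balance_grid)
  rows <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    for (gi in seq_len(nrow(grid))) {
      target <- c(Wake = grid$Wake[gi], NREM = grid$NREM[gi], REM = grid$REM[gi])
      rb <- tryCatch(
        rebalance_recording(sub$recording, sub$labels, target,
                            seed = seed + 97L * si + gi),
        error = function(e) NULL)
      if (is.null(rb)) {
        message(sprintf("subject %d: grid point %d infeasible, skipped", si, gi))
        next
      }
      feats <- preprocess_recording(rb$recording)
      n <- ncol(feats)
      truth <- rb$labels[seq_len(n)]
      pred_bal <- function(model, std_feats) {
        imgs <- make_epoch_images(std_feats)
        pr <- predict(model, imgs)
        lab <- if (refine) refine_bouts(pr$stage) else label_series(pr$stage)
        stage_balance(lab)
      }
      bal_std <- pred_bal(model_std, standard_zscore(feats)$features)
      bal_mix <- pred_bal(model_mix, apply_standardization(feats, sub$params))
      truth_bal <- stage_balance(truth)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = si, grid = gi,
        target_wake = target[["Wake"]], target_nrem = target[["NREM"]],
        target_rem = target[["REM"]],
        achieved_wake = truth_bal[["Wake"]], achieved_nrem = truth_bal[["NREM"]],
        achieved_rem = truth_bal[["REM"]],
        pred_std_wake = bal_std[["Wake"]], pred_std_nrem = bal_std[["NREM"]],
        pred_std_rem = bal_std[["REM"]],
        pred_mix_wake = bal_mix[["Wake"]], pred_mix_nrem = bal_mix[["NREM"]],
        pred_mix_rem = bal_mix[["REM"]],
        tvd_std = total_variation(truth_bal, bal_std),
        tvd_mix = total_variation(truth_bal, bal_mix))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "train_balance") <- train_balance
  class(out) <- c("bias_experiment", class(out))
  out
}

#' @export
glance.bias_experiment <- function(x, ...) {
  tt <- t.test(x$tvd_std, x$tvd_mix, paired = TRUE)
  nsem <- function(v) sd(v) / sqrt(length(v))
  tb <- attr(x, "train_balance")
  # contraction audit: signed wake error of the standard arm should point
  # from the achieved balance toward the training balance
  toward <- sign(tb[["Wake"]] - x$achieved_wake) ==
    sign(x$pred_std_wake - x$achieved_wake)
  tibble::tibble(mean_tvd_std = mean(x$tvd_std), sem_tvd_std = nsem(x$tvd_std),
                 mean_tvd_mix = mean(x$tvd_mix), sem_tvd_mix = nsem(x$tvd_mix),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 contraction_rate = mean(toward[abs(tb[["Wake"]] - x$achieved_wake) > 0.05]),
                 n = nrow(x))
}

#' @export
autoplot.bias_experiment <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(source = "achieved", wake = object$achieved_wake,
                   nrem = object$achieved_nrem),
    tibble::tibble(source = "standard z", wake = object$pred_std_wake,
                   nrem = object$pred_std_nrem),
    tibble::tibble(source = "mixture z", wake = object$pred_mix_wake,
                   nrem = object$pred_mix_nrem))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wake, y = .data$nrem,
                                   colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "proportion Wake", y = "proportion NREM") +
    ggplot2::theme_minimal()
}
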