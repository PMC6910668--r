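#' Stage signature specification
#'
#' Relative band-amplitude weights (delta 1-4 Hz, theta 6-8 Hz, broadband
#' 10-50 Hz), EMG tone and mean bout duration per stage. Defaults emulate
#' the canonical mouse signatures: NREM with dominant delta and low tone,
#' REM with the highest theta/delta ratio and the lowest tone, Wake with
#' low-amplitude broadband EEG and high tone.
#'
#' @param weights 3 x 3 numeric matrix, rows REM/Wake/NREM, columns
#'   delta/theta/broadband (nonnegative amplitude weights).
#' @param tone EMG tone (relative RMS) per stage, nonnegative.
#' @param mean_bout mean bout duration in seconds per stage (> epoch length).
#' @return a `stage_spec` object.
#' @export
stage_spec <- function(weights = NULL, tone = NULL, mean_bout = NULL) {
  default_w <- rbind(REM  = c(delta = 0.5, theta = 2.5, broadband = 0.4),
                     Wake = c(delta = 0.7, theta = 0.8, broadband = 1.2),
                     NREM = c(delta = 3.0, theta = 0.8, broadband = 0.4))
  weights <- weights %||% default_w
  tone <- tone %||% c(REM = 0.15, Wake = 2.0, NREM = 0.3)
  mean_bout <- mean_bout %||% c(REM = 45, Wake = 60, NREM = 70)
  stopifnot(all(weights >= 0), all(tone >= 0), all(mean_bout > 2.5))
  structure(list(weights = weights, tone = tone, mean_bout = mean_bout),
            class = "stage_spec")
}

#' Subject specification for synthesis
#'
#' @param stage_spec a [stage_spec()].
#' @param target_balance named occupancy proportions (Wake, NREM, REM)
#'   summing to 1.
#' @param nuisance list of per-channel [affine_nuisance()]s (`eeg`, `emg`).
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds (truncated to a whole number
#'   of epochs).
#' @param epoch_len epoch length in seconds.
#' @param subject_id subject identifier.
#' @param seed integer seed.
#' @return a `subject_spec` object.
#' @export
subject_spec <- function(stage_spec = somnoshift::stage_spec(),
                         target_balance = c(Wake = 0.45, NREM = 0.45, REM = 0.10),
                         nuisance = list(eeg = affine_nuisance(),
                                         emg = affine_nuisance()),
                         fs = 128, duration = 3600, epoch_len = 2.5,
                         subject_id = "synthetic", seed = 1L) {
  stopifnot(abs(sum(target_balance) - 1) < 1e-9, all(target_balance >= 0),
            fs > 0, duration >= epoch_len)
  structure(list(stage_spec = stage_spec, target_balance = target_balance,
                 nuisance = nuisance, fs = fs, duration = duration,
                 epoch_len = epoch_len, subject_id = subject_id,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Sample a hypnogram
#'
#' Semi-Markov chain over Wake/NREM/REM with exponential-like bout
#' durations (mean-matched 1 + Poisson epochs, with small per-stage
#' minima). REM is entered only from NREM and always exits to Wake, so
#' every REM bout has NREM context before and Wake after — the structure
#' the rebalancing context rule relies on. The NREM -> REM transition
#' probability and the Wake/NREM mean durations are solved from the target
#' balance so long-run occupancy matches it.
#'
#' @param spec a [subject_spec()].
#' @return a [label_series()].
#' @export
sample_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  el <- spec$epoch_len
  n_epochs <- floor(spec$duration / el)
  b <- spec$target_balance
  d <- spec$stage_spec$mean_bout
  # cycle structure W -> N -> (R w.p. p -> brief arousal W) -> W; REM exits
  # into a short post-REM arousal (mean d_Ws) rather than a full wake bout.
  # Per NREM visit the expected cycle time is
  #   T = d_N + p (d_R + d_Ws) + (1 - p) d_Wl,
  # so T = d_N / b_N, p = b_R T / d_R, and d_Wl solves the Wake share.
  d_N <- d[["NREM"]]
  d_R <- d[["REM"]]
  d_Ws <- 12.5
  T_cycle <- d_N / max(b[["NREM"]], 1e-9)
  p_rem <- if (b[["REM"]] <= 0) 0 else min(1, b[["REM"]] * T_cycle / d_R)
  d_Wl <- if (p_rem >= 1) d_Ws else
    max(2 * el, (b[["Wake"]] * T_cycle - p_rem * d_Ws) / (1 - p_rem))
  mean_ep <- c(REM = d_R, Wake = d_Wl, NREM = d_N, Arousal = d_Ws) / el
  min_ep <- c(REM = 1L, Wake = 2L, NREM = 4L, Arousal = 2L)  # REM context
  # Wake and NREM bout lengths are bimodal: mostly long consolidated bouts
  # plus a fraction of brief fragments (arousals, light-sleep episodes),
  # as in fragmented rodent sleep. The long-bout mean is set so the
  # overall mean stays on target.
  frag_p <- c(REM = 0.35, Wake = 0.4, NREM = 0.35, Arousal = 0)
  frag_mean <- c(REM = 3, Wake = 3, NREM = 5, Arousal = 0)
  # fragments are scheduled by accumulator (every 1/frag_p-th bout) rather
  # than by coin flip, keeping long-run occupancy variance low
  frag_acc <- frag_p
  draw_len <- function(kind) {
    m <- mean_ep[[kind]]; fp <- frag_p[[kind]]
    if (fp > 0 && frag_acc[[kind]] >= 1) {
      frag_acc[kind] <<- frag_acc[[kind]] - 1
      max(min_ep[[kind]], rpois(1, frag_mean[[kind]]))
    } else {
      frag_acc[kind] <<- frag_acc[[kind]] + fp
      m_long <- (m - fp * frag_mean[[kind]]) / (1 - fp)
      max(min_ep[[kind]], 1L + rpois(1, max(m_long - 1, 0)))
    }
  }
  out <- integer(0)
  kind <- "Wake"
  rem_acc <- runif(1)  # low-discrepancy REM scheduling: stable occupancy
  while (length(out) < n_epochs) {
    len <- draw_len(kind)
    stage <- if (kind == "Arousal") "Wake" else kind
    out <- c(out, rep(match(stage, STAGES), len))
    if (kind == "NREM") {
      rem_acc <- rem_acc + p_rem
      if (rem_acc >= 1) {
        rem_acc <- rem_acc - 1
        kind <- "REM"
      } else kind <- "Wake"
    } else {
      kind <- switch(kind, Wake = "NREM", Arousal = "NREM", REM = "Arousal")
    }
  }
  out <- out[seq_len(n_epochs)]
  # truncation must not strand a REM bout without its trailing arousal:
  # relabel an orphaned tail as NREM (it merges into the preceding NREM)
  repeat {
    r <- rle(out)
    nr <- length(r$values)
    if (r$values[nr] == 1L ||
        (nr > 1 && r$values[nr] == 2L && r$lengths[nr] < 2L &&
         r$values[nr - 1] == 1L)) {
      out[(length(out) - r$lengths[nr] + 1L):length(out)] <- 3L
    } else break
  }
  label_series(out, epoch_len = el)
}

# band-limited unit-RMS noise over the whole recording
band_noise <- function(n, fs, band) {
  x <- rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sqrt(mean(y^2))
}

# per-sample gain envelope: stage value per epoch, smoothed so amplitude is
# continuous at epoch boundaries (0.25 s moving average)
smooth_envelope <- function(values_per_epoch, samples_per_epoch, n, fs) {
  env <- rep(values_per_epoch, each = samples_per_epoch)[seq_len(n)]
  wlen <- max(1L, as.integer(0.25 * fs))
  stats::filter(c(rep(env[1], wlen), env, rep(env[length(env)], wlen)),
                rep(1 / wlen, wlen), sides = 2)[wlen + seq_len(n)]
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' EEG is a sum of band-limited noise components (delta 1-4 Hz, theta
#' 6-8 Hz, broadband 10-50 Hz) whose amplitudes follow the stage's band
#' weights, plus a small white-noise floor; EMG is white noise scaled by
#' the stage's tone. Stage-to-stage amplitude changes are smoothed over
#' 0.25 s so the signals stay continuous at epoch boundaries. The
#' per-channel affine nuisance (gain, offset) is applied last.
#'
#' @param hypnogram a [label_series()].
#' @param spec a [subject_spec()].
#' @return a [recording()].
#' @export
synthesize_signals <- function(hypnogram, spec) {
  stopifnot(inherits(hypnogram, "label_series"), inherits(spec, "subject_spec"))
  set.seed(spec$seed + 1L)
  fs <- spec$fs
  spe <- as.integer(attr(hypnogram, "epoch_len") * fs)
  n <- length(hypnogram) * spe
  w <- spec$stage_spec$weights
  bands <- list(delta = c(1, 4), theta = c(6, 8), broadband = c(10, 50))
  eeg <- 0.05 * rnorm(n)  # noise floor
  for (bn in names(bands)) {
    comp <- band_noise(n, fs, bands[[bn]])
    env <- smooth_envelope(w[as.integer(hypnogram), bn], spe, n, fs)
    eeg <- eeg + env * comp
  }
  tone_env <- smooth_envelope(spec$stage_spec$tone[as.integer(hypnogram)],
                              spe, n, fs)
  emg <- tone_env * rnorm(n)
  nu <- spec$nuisance
  recording(nu$eeg$a * eeg + nu$eeg$b,
            nu$emg$a * emg + nu$emg$b,
            fs = fs, subject_id = spec$subject_id)
}

#' Synthesize one labeled subject
#'
#' Convenience wrapper: hypnogram plus signals for a [subject_spec()].
#'
#' @param spec a [subject_spec()].
#' @return list with `recording`, `labels` and the generating `spec`.
#' @export
synth_subject <- function(spec) {
  labels <- sample_hypnogram(spec)
  list(recording = synthesize_signals(labels, spec), labels = labels,
       spec = spec)
}

#' Generate a synthetic cohort
#'
#' Each subject draws its own affine nuisance (EEG/EMG gain log-uniform
#' within `nuisance_spread`, offset uniform in `offset_range`) and a
#' balance jittered around the base spec's target, then synthesizes a
#' labeled recording.
#'
#' @param n_subjects number of subjects.
#' @param base_spec a [subject_spec()] providing shared parameters.
#' @param nuisance_spread half-width of log2 gain spread (gain is
#'   2^U(-spread, spread)).
#' @param offset_range half-width of the uniform additive offset.
#' @param balance_jitter maximum absolute perturbation of Wake/NREM shares.
#' @param seed integer seed.
#' @return list of subject bundles as from [synth_subject()].
#' @export
make_cohort <- function(n_subjects, base_spec = subject_spec(),
                        nuisance_spread = 1, offset_range = 0.2,
                        balance_jitter = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    gains <- 2^runif(2, -nuisance_spread, nuisance_spread)
    offs <- runif(2, -offset_range, offset_range)
    jit <- runif(1, -balance_jitter, balance_jitter)
    b <- base_spec$target_balance
    b[["Wake"]] <- b[["Wake"]] + jit
    b[["NREM"]] <- b[["NREM"]] - jit
    sp <- base_spec
    sp$target_balance <- b
    sp$nuisance <- list(eeg = affine_nuisance(gains[1], offs[1]),
                        emg = affine_nuisance(gains[2], offs[2]))
    sp$subject_id <- sprintf("synthetic-%02d", i)
    sp$seed <- as.integer(seed + 1000L * i)
    synth_subject(sp)
  })
}

#' Oracle stage classifier from generator band weights
#'
#' Classifies epochs from delta power, theta/delta ratio and EMG activity
#' using the generating stage parameters (log-midpoint thresholds): the
#' Bayes-style ceiling against which the trained network is compared.
#'
#' @param features an unstandardized 185 x n [feature_matrix()] from
#'   [preprocess_recording()].
#' @param spec the [subject_spec()] that generated the recording.
#' @return a [label_series()] of oracle labels.
#' @export
oracle_classify <- function(features, spec) {
  x <- as.matrix(features)
  freqs <- as.numeric(sub("-.*", "", sub("eeg_", "", rownames(x)[1:176])))
  delta <- colMeans(x[which(freqs >= 1 & freqs <= 4), , drop = FALSE])
  theta <- colMeans(x[which(freqs >= 6 & freqs <= 8), , drop = FALSE])
  emg <- x[177, ]
  tone <- spec$stage_spec$tone
  w <- spec$stage_spec$weights
  # log-midpoint thresholds between Wake tone and the larger sleep tone;
  # EMG gain cancels within a subject only after centering, so use the
  # empirical split point between the two tone clusters
  km <- stats::kmeans(emg, centers = range(emg), iter.max = 50)
  high_cluster <- which.max(km$centers)
  is_wake <- km$cluster == high_cluster
  td <- theta - delta  # log ratio
  thr_td <- mean(c(2 * log(w["REM", "theta"] / w["REM", "delta"]),
                   2 * log(w["NREM", "theta"] / w["NREM", "delta"])))
  out <- ifelse(is_wake, 2L, ifelse(td > thr_td, 1L, 3L))
  label_series(out, epoch_len = attr(features, "epoch_len") %||% 2.5)
}
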