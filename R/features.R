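#' Recording container
#'
#' Paired EEG and EMG traces sampled at a common rate.
#'
#' @param eeg,emg numeric sample vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @return a `recording` object.
#' @export
recording <- function(eeg, emg, fs, subject_id = "unknown") {
  if (length(eeg) != length(emg)) {
    stop("eeg and emg must cover the same time span (equal lengths)",
         call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (anyNA(eeg) || anyNA(emg)) stop("signals contain NA", call. = FALSE)
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg),
                 fs = fs, subject_id = subject_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject '%s': %.1f s at %g Hz\n",
              x$subject_id, length(x$eeg) / x$fs, x$fs))
  invisible(x)
}

#' Label series container
#'
#' Per-epoch sleep-stage labels. Stages are stored as integer codes
#' 1 = REM, 2 = Wake, 3 = NREM (frozen across all file formats).
#'
#' @param stages integer codes in 1:3 or character stage names.
#' @param epoch_len epoch length in seconds.
#' @return a `label_series` object (integer vector with attributes).
#' @export
label_series <- function(stages, epoch_len = 2.5) {
  if (is.character(stages) || is.factor(stages)) {
    stages <- match(as.character(stages), STAGES)
  }
  stages <- as.integer(stages)
  if (anyNA(stages) || any(stages < 1L | stages > 3L)) {
    stop("stages must be REM/Wake/NREM (codes 1/2/3)", call. = FALSE)
  }
  if (epoch_len <= 0) stop("epoch_len must be positive", call. = FALSE)
  structure(stages, epoch_len = epoch_len, class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  b <- stage_balance(x)
  cat(sprintf("<label_series> %d epochs of %g s | Wake %.1f%% NREM %.1f%% REM %.1f%%\n",
              length(x), attr(x, "epoch_len"),
              100 * b[["Wake"]], 100 * b[["NREM"]], 100 * b[["REM"]]))
  invisible(x)
}

#' @export
`[.label_series` <- function(x, i, ...) {
  label_series(unclass(x)[i], epoch_len = attr(x, "epoch_len"))
}

stage_names <- function(x) STAGES[as.integer(x)]

#' Stage occupancy of a label series
#'
#' @param labels a [label_series()] or integer stage codes.
#' @return named proportions over (Wake, NREM, REM), summing to 1.
#' @export
stage_balance <- function(labels) {
  x <- as.integer(labels)
  n <- length(x)
  c(Wake = sum(x == 2L) / n, NREM = sum(x == 3L) / n, REM = sum(x == 1L) / n)
}

#' Resample a recording to 128 Hz
#'
#' Polyphase resampling with anti-aliasing (via [signal::resample()]) of
#' both channels. Recordings already at 128 Hz pass through unchanged.
#'
#' @param rec a [recording()] with `fs >= 128`.
#' @return a [recording()] at 128 Hz.
#' @export
resample_to_128 <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs < 128) {
    stop(sprintf("unsupported sampling rate %g Hz: at least 128 Hz required",
                 rec$fs), call. = FALSE)
  }
  if (rec$fs == 128) return(rec)
  # rational p/q with fs scaled to integers
  scale <- if (rec$fs == round(rec$fs)) 1 else 1000
  p <- 128 * scale; q <- round(rec$fs * scale)
  g <- gcd_int(p, q); p <- p / g; q <- q / g
  recording(signal::resample(rec$eeg, p, q),
            signal::resample(rec$emg, p, q),
            fs = 128, subject_id = rec$subject_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# ---- multitaper -------------------------------------------------------------

# Discrete prolate spheroidal sequences by the symmetric tridiagonal
# formulation: eigenvectors of the matrix with diagonal
# ((N-1-2t)/2)^2 cos(2 pi W) and off-diagonal t(N-t)/2 give the tapers in
# order of decreasing concentration. Cached per (n, nw, k).
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  w <- nw / n
  t <- seq_len(n) - 1
  diagonal <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  tt <- seq_len(n - 1)
  off <- tt * (n - tt) / 2
  A <- matrix(0, n, n)
  diag(A) <- diagonal
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # normalize: unit energy, conventional sign (positive mean for symmetric
  # tapers, positive initial slope for antisymmetric ones)
  for (i in seq_len(k)) {
    v[, i] <- v[, i] / sqrt(sum(v[, i]^2))
    if (i %% 2 == 1) {
      if (sum(v[, i]) < 0) v[, i] <- -v[, i]
    } else {
      if (v[2, i] - v[1, i] < 0) v[, i] <- -v[, i]
    }
  }
  dpss_cache[[key]] <- v
  v
}

#' Multitaper spectrogram of an EEG trace
#'
#' Power between 0 and 50 Hz with a 5 s window and a 2.5 s step at 128 Hz:
#' FFT length equals the window length (640 samples), giving 0.2 Hz bins
#' and 251 frequencies from 0.0 to 50.0 Hz inclusive. One column per 2.5 s
#' epoch; windows are centered on epoch midpoints and the record edges are
#' padded by reflection. Tapers are DPSS with time-bandwidth product `nw`
#' and `k` tapers, averaged with equal weight.
#'
#' @param eeg numeric EEG vector at 128 Hz, at least 5 s long.
#' @param fs sampling rate (must be 128).
#' @param epoch_len epoch length in seconds.
#' @param window_len analysis window in seconds.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return matrix of nonnegative power, 251 frequencies x n epochs, with
#'   frequencies in rownames.
#' @export
multitaper_spectrogram <- function(eeg, fs = 128, epoch_len = 2.5,
                                   window_len = 5, nw = 3, k = 5) {
  if (fs != 128) stop("multitaper_spectrogram expects 128 Hz input", call. = FALSE)
  nwin <- as.integer(window_len * fs)      # 640
  nstep <- as.integer(epoch_len * fs)      # 320
  if (length(eeg) < nwin) {
    stop(sprintf("signal too short: need at least %g s", window_len),
         call. = FALSE)
  }
  n_epochs <- floor(length(eeg) / nstep)
  pad <- nwin %/% 2
  x <- c(rev(eeg[seq_len(pad) + 1]), eeg, eeg[length(eeg) - seq_len(pad)])
  # epoch i midpoint (i - 0.5) * epoch_len -> window start in padded signal
  starts <- (seq_len(n_epochs) - 1L) * nstep + (nstep %/% 2) + pad - (nwin %/% 2)
  seg_idx <- outer(seq_len(nwin), starts, `+`)
  segs <- matrix(x[seg_idx], nrow = nwin)
  tapers <- dpss_tapers(nwin, nw, k)
  n_keep <- as.integer(50 / (fs / nwin)) + 1L   # 251 bins, 0-50 Hz
  psd <- matrix(0, n_keep, n_epochs)
  for (i in seq_len(k)) {
    ft <- stats::mvfft(segs * tapers[, i])
    psd <- psd + (Mod(ft[seq_len(n_keep), , drop = FALSE])^2) / k
  }
  rownames(psd) <- sprintf("%.1f", (seq_len(n_keep) - 1) * fs / nwin)
  psd
}

#' Reduce high-band frequency resolution
#'
#' Keeps the 101 bins at or below 20 Hz verbatim and averages the 150 bins
#' spanning 20.2-50.0 Hz in consecutive non-overlapping pairs (75 bins),
#' yielding the 176 spectral components used by the classifier.
#'
#' @param spec spectrogram matrix with 251 rows at 0.2 Hz spacing.
#' @return matrix with 176 rows.
#' @export
reduce_frequencies <- function(spec) {
  if (nrow(spec) != 251L) {
    stop(sprintf("expected 251 frequency bins at 0.2 Hz spacing, got %d",
                 nrow(spec)), call. = FALSE)
  }
  low <- spec[1:101, , drop = FALSE]
  hi <- spec[102:251, , drop = FALSE]
  odd <- hi[seq(1, 149, by = 2), , drop = FALSE]
  even <- hi[seq(2, 150, by = 2), , drop = FALSE]
  merged <- (odd + even) / 2
  rownames(merged) <- paste(rownames(odd), rownames(even), sep = "-")
  rbind(low, merged)
}

#' Per-epoch EMG activity
#'
#' Zero-phase 20-50 Hz band-pass (4th-order Butterworth run forwards and
#' backwards) followed by the root-mean-square over each epoch. A trailing
#' partial epoch is dropped with a message.
#'
#' @param emg numeric EMG vector.
#' @param fs sampling rate in Hz (128 after resampling).
#' @param epoch_len epoch length in seconds.
#' @return nonnegative numeric vector, one value per complete epoch.
#' @export
emg_activity <- function(emg, fs = 128, epoch_len = 2.5) {
  bf <- signal::butter(4, c(20, 50) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, emg)
  nstep <- as.integer(epoch_len * fs)
  n_epochs <- floor(length(filt) / nstep)
  extra <- length(filt) - n_epochs * nstep
  if (extra > 0) {
    message(sprintf("dropping trailing partial epoch (%d samples)", extra))
  }
  m <- matrix(filt[seq_len(n_epochs * nstep)], nrow = nstep)
  sqrt(colMeans(m^2))
}

#' Assemble the 185-feature matrix
#'
#' Rows 1-176 are the log-scaled reduced spectrogram; rows 177-185 are nine
#' identical copies of the log-scaled EMG activity (replication upweights
#' the single EMG feature relative to the 176 spectral rows in the
#' convolutional input). A small offset guards log(0) on synthetic silence.
#'
#' @param spec176 reduced spectrogram, 176 x n.
#' @param emg_rms per-epoch EMG activity, length n.
#' @param log_eps offset added before the log.
#' @return an unstandardized [feature_matrix()], 185 x n.
#' @export
build_feature_matrix <- function(spec176, emg_rms, log_eps = 1e-12) {
  if (nrow(spec176) != 176L) {
    stop(sprintf("expected 176 spectral rows, got %d", nrow(spec176)),
         call. = FALSE)
  }
  if (ncol(spec176) != length(emg_rms)) {
    stop(sprintf("epoch-count mismatch: spectrogram %d vs EMG %d",
                 ncol(spec176), length(emg_rms)), call. = FALSE)
  }
  emg_row <- log(emg_rms + log_eps)
  vals <- rbind(log(spec176 + log_eps),
                matrix(rep(emg_row, each = 9), nrow = 9))
  spec_names <- rownames(spec176) %||% sprintf("f%03d", 1:176)
  rownames(vals) <- c(paste0("eeg_", spec_names), paste0("emg_", 1:9))
  feature_matrix(vals, standardized = FALSE, layout = "ssann-185")
}

#' Full preprocessing pipeline for one recording
#'
#' Resamples to 128 Hz, computes the multitaper spectrogram, reduces the
#' high band, computes EMG activity, and assembles the 185 x n feature
#' matrix (not yet standardized).
#'
#' @param rec a [recording()].
#' @param epoch_len epoch length in seconds.
#' @return an unstandardized [feature_matrix()], 185 x n.
#' @export
preprocess_recording <- function(rec, epoch_len = 2.5) {
  rec <- resample_to_128(rec)
  spec <- multitaper_spectrogram(rec$eeg, fs = 128, epoch_len = epoch_len)
  spec176 <- reduce_frequencies(spec)
  emg <- suppressMessages(emg_activity(rec$emg, fs = 128, epoch_len = epoch_len))
  n <- min(ncol(spec176), length(emg))
  build_feature_matrix(spec176[, seq_len(n), drop = FALSE], emg[seq_len(n)])
}

#' Per-epoch context images
#'
#' Image i holds feature columns i-6 .. i+6 (13 columns, 32.5 s of context
#' at 2.5 s epochs) of the standardized feature matrix; boundary epochs are
#' padded by replicating the first/last column.
#'
#' @param features a standardized [feature_matrix()].
#' @param context odd number of columns per image.
#' @return an `epoch_images` object: array of dim (F, context, n) with the
#'   epoch index attached.
#' @export
make_epoch_images <- function(features, context = 13L) {
  if (context %% 2 == 0) stop("context must be odd", call. = FALSE)
  if (!is_standardized(features)) {
    stop("features must be standardized before image assembly", call. = FALSE)
  }
  x <- as.matrix(features)
  n <- ncol(x); h <- context %/% 2
  cols <- outer(-h:h, seq_len(n), `+`)
  cols[cols < 1L] <- 1L
  cols[cols > n] <- n
  img <- array(x[, as.vector(cols)], dim = c(nrow(x), context, n))
  structure(img, center_index = seq_len(n), layout = feature_layout(features),
            class = "epoch_images")
}

#' @export
print.epoch_images <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<epoch_images> %d images of %d x %d\n", d[3], d[1], d[2]))
  invisible(x)
}

n_images <- function(images) dim(images)[3]
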