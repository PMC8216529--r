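# Signal conditioning: zero-lag Butterworth band-pass, 50 Hz notch,
# task-level amplitude normalization and fixed-length windowing.

#' Preprocessing configuration
#'
#' @param bp_lo,bp_hi Band-pass corner frequencies in Hz.  A `bp_hi` at or
#'   above the Nyquist frequency is clipped to `0.99 * fs/2` with a warning
#'   when the filter is applied (a band edge at Nyquist is not realizable:
#'   at fs = 1000 the nominal 500 Hz corner becomes 495 Hz).
#' @param bp_order Butterworth order (applied forward and backward, so the
#'   effective magnitude response is squared).
#' @param notch_hz Notch centre frequency in Hz.
#' @param notch_bw Notch -3 dB bandwidth in Hz (default 2 Hz, quality
#'   factor 25).
#' @param norm_epoch_s Epoch length for amplitude normalization.
#' @param norm_method `"rms"` normalizes by the maximal epoch RMS over the
#'   task; `"peak"` by the maximal epoch peak of `|x|`.
#' @param window_s Non-overlapping analysis window length for feature
#'   extraction; `window_s * fs` must be an integer.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(bp_lo = 10, bp_hi = 500, bp_order = 4,
                              notch_hz = 50, notch_bw = 2,
                              norm_epoch_s = 0.5,
                              norm_method = c("rms", "peak"),
                              window_s = 0.5) {
  norm_method <- match.arg(norm_method)
  stopifnot(bp_lo > 0, bp_lo < bp_hi, bp_order >= 1,
            notch_hz > 0, notch_bw > 0, norm_epoch_s > 0, window_s > 0)
  structure(list(bp_lo = bp_lo, bp_hi = bp_hi, bp_order = bp_order,
                 notch_hz = notch_hz, notch_bw = notch_bw,
                 norm_epoch_s = norm_epoch_s, norm_method = norm_method,
                 window_s = window_s),
            class = "preprocess_config")
}

#' Zero-lag Butterworth band-pass filter
#'
#' Forward-backward application of an order-`bp_order` Butterworth band-pass
#' (net zero phase shift; the magnitude response is applied twice).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered signal of the same length.
#' @export
bandpass_zero_lag <- function(x, fs, cfg = preprocess_config()) {
  stopifnot(all(is.finite(x)), length(x) > 3 * cfg$bp_order)
  hi <- cfg$bp_hi
  if (hi >= fs / 2) {
    hi <- 0.99 * fs / 2
    warning(sprintf("band-pass upper corner %g Hz >= Nyquist (%g Hz); clipped to %g Hz",
                    cfg$bp_hi, fs / 2, hi))
  }
  b <- signal::butter(cfg$bp_order, c(cfg$bp_lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Zero-lag IIR notch filter
#'
#' Second-order (biquad) notch centred at `notch_hz`, applied forward and
#' backward.
#'
#' @inheritParams bandpass_zero_lag
#' @return Filtered signal of the same length.
#' @export
notch_zero_lag <- function(x, fs, cfg = preprocess_config()) {
  stopifnot(all(is.finite(x)))
  if (cfg$notch_hz >= fs / 2) stop("notch_hz must be below the Nyquist frequency")
  w0 <- 2 * pi * cfg$notch_hz / fs
  q <- cfg$notch_hz / cfg$notch_bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))
}

## RMS of consecutive nonoverlapping epochs (trailing partial epoch dropped;
## if the signal is shorter than one epoch, the whole signal is one epoch)
epoch_rms <- function(x, fs, epoch_s) {
  len <- as.integer(round(epoch_s * fs))
  if (length(x) < len) return(sqrt(mean(x^2)))
  n_ep <- length(x) %/% len
  m <- matrix(x[seq_len(n_ep * len)], nrow = len)
  sqrt(colMeans(m^2))
}

epoch_peak <- function(x, fs, epoch_s) {
  len <- as.integer(round(epoch_s * fs))
  if (length(x) < len) return(max(abs(x)))
  n_ep <- length(x) %/% len
  m <- matrix(abs(x[seq_len(n_ep * len)]), nrow = len)
  apply(m, 2, max)
}

#' Amplitude-normalization constant of a channel over a task
#'
#' The maximal EMG amplitude over 0.5-s epochs: by default the maximum epoch
#' RMS across all trials of the task (robust to single-sample artifacts); the
#' epoch peak of `|x|` is available via `norm_method = "peak"`.
#'
#' @param trials List of numeric vectors (the channel's filtered trials).
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Scalar normalization constant.
#' @export
normalization_constant <- function(trials, fs, cfg = preprocess_config()) {
  if (!is.list(trials)) trials <- list(trials)
  f <- if (cfg$norm_method == "rms") epoch_rms else epoch_peak
  max(unlist(lapply(trials, f, fs = fs, epoch_s = cfg$norm_epoch_s)))
}

#' Normalize a filtered signal by its maximal 0.5-s epoch amplitude
#'
#' @inheritParams bandpass_zero_lag
#' @param constant Optional externally computed task-level constant (used
#'   when the maximum is taken over several trials); defaults to the
#'   constant of `x` itself.
#' @return Normalized signal; the maximal epoch amplitude of the output is 1
#'   when `constant` is computed from `x`.  An all-zero channel is returned
#'   unchanged with a warning.
#' @export
normalize_amplitude <- function(x, fs, cfg = preprocess_config(),
                                constant = NULL) {
  if (is.null(constant)) constant <- normalization_constant(x, fs, cfg)
  if (constant == 0) {
    warning("all-zero channel: normalization skipped")
    return(x)
  }
  x / constant
}

#' Split a signal into non-overlapping fixed-length windows
#'
#' @inheritParams bandpass_zero_lag
#' @return Matrix with `window_s * fs` rows and one column per window
#'   (`floor(N / (window_s * fs))` columns; the trailing remainder is
#'   discarded).  A signal shorter than one window yields zero columns with
#'   a warning.
#' @export
segment_windows <- function(x, fs, cfg = preprocess_config()) {
  len <- as.integer(round(cfg$window_s * fs))
  if (abs(cfg$window_s * fs - len) > 1e-9)
    stop("window_s * fs must be an integer")
  n_win <- length(x) %/% len
  if (n_win == 0) {
    warning("signal shorter than one window: no windows returned")
    return(matrix(numeric(0), nrow = len, ncol = 0))
  }
  matrix(x[seq_len(n_win * len)], nrow = len)
}

#' Filter all channels of a recording
#'
#' Band-pass then notch, per channel.  Normalization is a task-level step
#' (the constant spans all trials of a task); see [preprocess_cohort()].
#'
#' @param rec An `emg_recording`.
#' @param cfg A [preprocess_config()].
#' @return The recording with filtered samples.
#' @export
filter_recording <- function(rec, cfg = preprocess_config()) {
  rec$samples <- apply(rec$samples, 2, function(ch) {
    notch_zero_lag(bandpass_zero_lag(ch, rec$fs, cfg), rec$fs, cfg)
  })
  rec
}

#' Preprocess a whole cohort
#'
#' Filters every trial (band-pass + notch) and normalizes each channel by
#' its maximal 0.5-s epoch amplitude over all trials of each
#' (subject, task) — signals are filtered before normalization, and
#' normalization precedes windowing.
#'
#' In addition to the fully conditioned signals, a "wideband" variant
#' (notch only, no band-pass) is kept for the coherence and network path:
#' the 10 Hz high-pass would otherwise remove the low-frequency (delta,
#' theta) content those analyses quantify, while MSC itself is invariant to
#' any per-channel filter gain shared by both signals of a pair.
#'
#' @param cohort An `emg_cohort`.
#' @param cfg A [preprocess_config()].
#' @return Object of class `emg_prep`: `index` (subject_id, group, task),
#'   `signals` (list of preprocessed N x 6 trial-matrix lists) and
#'   `wideband` (notch-only trial matrices for coherence), plus `fs` and
#'   `cfg`.
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  keyed <- split(cohort$recordings, vapply(cohort$recordings, function(r)
    paste(r$subject_id, r$task, sep = "|"), ""))
  index <- list(); signals <- list(); wideband <- list()
  fs <- cohort$recordings[[1]]$fs
  hi_clip_warned <- FALSE
  for (key in names(keyed)) {
    recs <- keyed[[key]]
    recs <- recs[order(vapply(recs, function(r) r$trial, 1L))]
    filtered <- withCallingHandlers(
      lapply(recs, filter_recording, cfg = cfg),
      warning = function(w) {
        if (grepl("Nyquist", conditionMessage(w))) {
          if (!hi_clip_warned) {
            hi_clip_warned <<- TRUE
            warning(conditionMessage(w), call. = FALSE)
          }
          invokeRestart("muffleWarning")
        }
      })
    wb <- lapply(recs, function(r) {
      apply(r$samples, 2, notch_zero_lag, fs = r$fs, cfg = cfg)
    })
    chans <- recs[[1]]$channel_labels
    consts <- vapply(seq_along(chans), function(c) {
      normalization_constant(lapply(filtered, function(r) r$samples[, c]),
                             fs, cfg)
    }, 1.0)
    trials <- lapply(filtered, function(r) {
      out <- r$samples
      for (c in seq_along(chans))
        out[, c] <- normalize_amplitude(out[, c], fs, cfg, constant = consts[c])
      out
    })
    index[[length(index) + 1L]] <- data.frame(
      subject_id = recs[[1]]$subject_id, group = recs[[1]]$group,
      task = recs[[1]]$task, stringsAsFactors = FALSE)
    signals[[length(signals) + 1L]] <- trials
    wideband[[length(wideband) + 1L]] <- wb
  }
  index <- do.call(rbind, index)
  ## stable ordering: subjects in roster order, then task
  ord <- order(match(index$subject_id, unique(cohort$subjects$subject_id)),
               match(index$task, cohort_tasks()))
  structure(list(index = index[ord, , drop = FALSE],
                 signals = signals[ord], wideband = wideband[ord],
                 fs = fs, cfg = cfg),
            class = "emg_prep")
}

#' @export
print.emg_prep <- function(x, ...) {
  cat(sprintf("Preprocessed EMG cohort: %d (subject, task) entries at %g Hz\n",
              nrow(x$index), x$fs))
  invisible(x)
}
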