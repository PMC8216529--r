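# Spectrotemporal EMG features per 500-ms window, aggregated to a
# per-(subject, task) feature table.

#' Time-domain EMG features of one window
#'
#' `MAV = mean(|x|)`, `RMS = sqrt(mean(x^2))`, `VAR = sum(x^2)/(N-1)`
#' (no mean subtraction: band-passed EMG is near zero-mean and the
#' conventional definition in this literature omits centering),
#' `WL = sum(|diff(x)|)`, `SSI = sum(x^2)`.
#'
#' @param x Numeric window of length `N >= 2`.
#' @return Named numeric vector `c(MAV, RMS, VAR, WL, SSI)`.
#' @export
time_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("window must contain at least 2 samples (VAR undefined)")
  ss <- sum(x^2)
  c(MAV = mean(abs(x)),
    RMS = sqrt(ss / n),
    VAR = ss / (n - 1),
    WL = sum(abs(diff(x))),
    SSI = ss)
}

#' One-sided periodogram of a window
#'
#' Raw FFT periodogram scaled so that `sum(power) * df` equals the window's
#' mean-square power (Parseval), with the DC bin excluded.
#'
#' @param x Numeric window (length >= 8).
#' @param fs Sampling rate in Hz.
#' @return Object of class `emg_spectrum`: `freqs` (Hz, strictly increasing)
#'   and `power` (normalized-amplitude^2 / Hz).
#' @export
compute_psd <- function(x, fs) {
  n <- length(x)
  if (n < 8) stop("window too short for a PSD")
  if (!all(is.finite(x))) stop("non-finite samples in window")
  X <- stats::fft(x)
  m <- n %/% 2
  j <- seq_len(m)                       # bins 1..floor(N/2), DC excluded
  p <- Mod(X[j + 1])^2 / (fs * n)
  double_it <- if (n %% 2 == 0) j < m else j <= m  # Nyquist bin not doubled
  p[double_it] <- 2 * p[double_it]
  structure(list(freqs = j * fs / n, power = p), class = "emg_spectrum")
}

#' Frequency-domain EMG features of a spectrum
#'
#' `MNF` is the power-weighted mean frequency, `MDF` the smallest grid
#' frequency at which cumulative power reaches half the total, `PKF` the
#' frequency of the maximal spectral bin (ties toward the lowest frequency;
#' `pkf = "power"` returns the maximal power value itself, the literal
#' textbook-table variant), `MNP` the mean and `TTP` the total spectral
#' power.
#'
#' @param spectrum An `emg_spectrum` from [compute_psd()].
#' @param pkf `"frequency"` (default) or `"power"`.
#' @return Named numeric vector `c(MNF, MDF, PKF, MNP, TTP)`.
#' @export
freq_features <- function(spectrum, pkf = c("frequency", "power")) {
  pkf <- match.arg(pkf)
  f <- spectrum$freqs; p <- spectrum$power
  tot <- sum(p)
  if (tot <= 0) stop("all-zero spectrum: MNF/MDF undefined")
  peak <- which.max(p)                   # which.max takes the first maximum
  c(MNF = sum(f * p) / tot,
    MDF = f[which(cumsum(p) >= tot / 2)[1]],
    PKF = if (pkf == "frequency") f[peak] else max(p),
    MNP = tot / length(p),
    TTP = tot)
}

#' All ten spectrotemporal features of one window
#'
#' @inheritParams compute_psd
#' @param pkf Passed to [freq_features()].
#' @return Named numeric vector of the five time-domain and five
#'   frequency-domain features.
#' @export
window_features <- function(x, fs, pkf = "frequency") {
  c(time_features(x), freq_features(compute_psd(x, fs), pkf = pkf))
}

feature_names_time_freq <- function() {
  c("MAV", "RMS", "VAR", "WL", "SSI", "MNF", "MDF", "PKF", "MNP", "TTP")
}

#' Build the per-(subject, task) feature table
#'
#' Window-level features (ten per channel per 500-ms window) are averaged
#' over all windows of all trials of each (subject, task); band-wise MSC
#' features from [coherence_features()] are attached.  One row per subject
#' per task; the "combine" view is simply both tasks' rows pooled, with the
#' `task` column as indicator.
#'
#' @param prep An `emg_prep` from [preprocess_cohort()].
#' @param coh_cfg A [coherence_config()] (set to `NULL` to skip MSC
#'   features).
#' @param pkf Passed to [freq_features()].
#' @return Data frame of class `feature_table`: columns `subject_id`,
#'   `group`, `task`, then `<feature>_<muscle>_<side>` for the 10 features x
#'   6 channels and `msc_<band>_<pair>_<side>` MSC columns.
#' @export
build_feature_table <- function(prep, coh_cfg = coherence_config(),
                                pkf = "frequency") {
  cfg <- prep$cfg
  rows <- vector("list", nrow(prep$index))
  for (i in seq_len(nrow(prep$index))) {
    trials <- prep$signals[[i]]
    chans <- colnames(trials[[1]])
    vals <- numeric(0)
    for (c in seq_along(chans)) {
      w <- do.call(cbind, lapply(trials, function(tr)
        segment_windows(tr[, c], prep$fs, cfg)))
      if (ncol(w) == 0) { vals <- NULL; break }
      feats <- apply(w, 2, window_features, fs = prep$fs, pkf = pkf)
      vals <- c(vals, stats::setNames(rowMeans(feats),
                                      paste(rownames(feats), chans[c],
                                            sep = "_")))
    }
    if (is.null(vals)) {
      warning("no complete windows for ", prep$index$subject_id[i], " / ",
              prep$index$task[i], "; row omitted")
      next
    }
    if (!is.null(coh_cfg))
      vals <- c(vals, coherence_features(prep$wideband[[i]], prep$fs, coh_cfg))
    rows[[i]] <- cbind(prep$index[i, , drop = FALSE],
                       as.data.frame(as.list(vals), check.names = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the numeric feature matrix and labels from a feature table
#'
#' @param table A `feature_table` data frame.
#' @param task One of `"rectilinear"`, `"curvilinear"`, `"combine"` or
#'   `NULL` (no filtering); `"combine"` pools both tasks' rows.
#' @param features Optional character vector restricting the columns.
#' @return List with `X` (numeric matrix), `y` (factor of group labels,
#'   levels CNP then control), `subject_id` and `task` per row.
#' @export
feature_matrix <- function(table, task = NULL, features = NULL) {
  if (!is.null(task) && task != "combine")
    table <- table[table$task == task, , drop = FALSE]
  meta <- c("subject_id", "group", "task")
  cols <- setdiff(names(table), meta)
  if (!is.null(features)) {
    missing <- setdiff(features, cols)
    if (length(missing))
      stop("unknown feature columns: ", paste(missing, collapse = ", "))
    cols <- features
  }
  list(X = as.matrix(table[cols]),
       y = factor(table$group, levels = cohort_groups()),
       subject_id = table$subject_id, task = table$task)
}

#' Parse a feature column name into its components
#'
#' Single-channel features follow `<FEAT>_<MUSCLE>_<SIDE>`; coherence
#' features follow `msc_<band>_<M1>_<M2>_<SIDE>`.
#'
#' @param name Feature column name(s).
#' @return Data frame with columns `name`, `feature`, `muscles`
#'   (list-column of one or two muscle codes) and `side`.
#' @export
parse_feature_name <- function(name) {
  out <- lapply(name, function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    muscles <- emg_muscles()
    if (identical(parts[1], "msc")) {
      np <- length(parts)   # band names may themselves contain underscores
      if (np < 5 || !all(parts[(np - 2):(np - 1)] %in% muscles) ||
          !(parts[np] %in% c("L", "R")))
        stop("unparseable feature name: ", nm)
      list(name = nm,
           feature = paste(parts[seq_len(np - 3)], collapse = "_"),
           muscles = list(parts[(np - 2):(np - 1)]), side = parts[np])
    } else {
      if (length(parts) != 3 || !(parts[2] %in% muscles) ||
          !(parts[3] %in% c("L", "R")) ||
          !(parts[1] %in% feature_names_time_freq()))
        stop("unparseable feature name: ", nm)
      list(name = nm, feature = parts[1], muscles = list(parts[2]),
           side = parts[3])
    }
  })
  data.frame(name = vapply(out, `[[`, "", "name"),
             feature = vapply(out, `[[`, "", "feature"),
             muscles = I(lapply(out, function(o) o$muscles[[1]])),
             side = vapply(out, `[[`, "", "side"),
             stringsAsFactors = FALSE)
}
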