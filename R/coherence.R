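# Magnitude-squared coherence (MSC) between muscle pairs:
# Welch-type segment-averaged estimator and band-wise aggregation.

#' Default coherence frequency bands
#'
#' delta (1-4], theta (4-8], alpha (8-12], beta (12-25] and high beta
#' (25-30] Hz.  Bins are assigned by `lo < f <= hi` so shared band edges are
#' never double-counted.
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "high_beta"),
             lo = c(1, 4, 8, 12, 25),
             hi = c(4, 8, 12, 25, 30),
             stringsAsFactors = FALSE)
}

#' Coherence estimation configuration
#'
#' @param seg_s Segment length in seconds (default 0.5, giving 2 Hz
#'   resolution).
#' @param overlap_frac Fractional segment overlap in `[0, 1)`; default 0
#'   (non-overlapping segments).
#' @param bands Band table as in [band_definitions()].
#' @param broadband `c(lo, hi)` of the additional broadband summary feature.
#' @return Object of class `coherence_config`.
#' @export
coherence_config <- function(seg_s = 0.5, overlap_frac = 0,
                             bands = band_definitions(),
                             broadband = c(1, 30)) {
  stopifnot(seg_s > 0, overlap_frac >= 0, overlap_frac < 1)
  structure(list(seg_s = seg_s, overlap_frac = overlap_frac, bands = bands,
                 broadband = broadband),
            class = "coherence_config")
}

## complex segment FFTs of one signal: matrix (bins excl. DC) x segments
segment_ffts <- function(x, seg, hop) {
  starts <- seq(1, length(x) - seg + 1, by = hop)
  m <- vapply(starts, function(s) x[s:(s + seg - 1)], numeric(seg))
  X <- stats::mvfft(m)
  X[2:(seg %/% 2 + 1), , drop = FALSE]
}

## segment FFTs across a list of trials; segments never span a trial join
trial_segment_ffts <- function(trials, fs, cfg) {
  seg <- as.integer(round(cfg$seg_s * fs))
  hop <- max(1L, as.integer(round(seg * (1 - cfg$overlap_frac))))
  blocks <- lapply(trials, function(x) {
    if (length(x) < seg) NULL else segment_ffts(x, seg, hop)
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks)) stop("no trial long enough for a single segment")
  list(X = do.call(cbind, blocks),
       freqs = seq_len(seg %/% 2) * fs / seg)
}

msc_from_ffts <- function(Xa, Xb) {
  pxx <- rowMeans(Mod(Xa)^2)
  pyy <- rowMeans(Mod(Xb)^2)
  pxy <- rowMeans(Xa * Conj(Xb))
  msc <- Mod(pxy)^2 / (pxx * pyy)
  msc[!is.finite(msc)] <- 0
  pmin(pmax(msc, 0), 1)
}

#' Magnitude-squared coherence between two signals
#'
#' Welch-type estimate: auto- and cross-spectra averaged over fixed-length
#' segments (rectangular taper), then
#' `MSC(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))` in `[0, 1]`.  A single segment
#' would give MSC identically 1, so at least two segments are required.
#' For two independent signals the estimator's expected value is
#' approximately `1/L` with `L` averaged segments (estimator bias).
#'
#' @param x,y Equal-length numeric signals, or lists of equal-length trial
#'   vectors (segments never span a trial boundary).
#' @param fs Sampling rate in Hz.
#' @param cfg A [coherence_config()].
#' @return Object of class `coherence_spectrum`: `pair`, `freqs`, `msc`,
#'   `n_segments`.
#' @export
msc <- function(x, y, fs, cfg = coherence_config()) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  if (length(x) != length(y) ||
      !all(lengths(x) == lengths(y)))
    stop("x and y must have identical lengths (per trial)")
  fx <- trial_segment_ffts(x, fs, cfg)
  fy <- trial_segment_ffts(y, fs, cfg)
  if (ncol(fx$X) < 2)
    stop("fewer than 2 segments: the averaged MSC estimator is degenerate ",
         "(a single segment gives MSC = 1 at every frequency)")
  structure(list(pair = c(deparse(substitute(x)), deparse(substitute(y))),
                 freqs = fx$freqs,
                 msc = msc_from_ffts(fx$X, fy$X),
                 n_segments = ncol(fx$X)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("MSC spectrum: %d bins (%g-%g Hz), %d segments, mean %.3f\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_segments,
              mean(x$msc)))
  invisible(x)
}

#' Band-aggregated MSC
#'
#' Arithmetic mean of the MSC over the grid bins with `lo < f <= hi`.
#'
#' @param cohspec A `coherence_spectrum`, or any list with `freqs` and `msc`.
#' @param band Either a row-like list/vector with `lo` and `hi`, a numeric
#'   `c(lo, hi)`, or a band name from [band_definitions()].
#' @return Scalar band MSC.
#' @export
band_msc <- function(cohspec, band) {
  if (is.character(band)) {
    bd <- band_definitions()
    i <- match(band, bd$name)
    if (is.na(i)) stop("unknown band name: ", band)
    band <- c(bd$lo[i], bd$hi[i])
  }
  lo <- as.numeric(band[[1]]); hi <- as.numeric(band[[2]])
  sel <- cohspec$freqs > lo & cohspec$freqs <= hi
  if (!any(sel))
    stop(sprintf(paste0("no frequency bins in (%g, %g] Hz at resolution ",
                        "%g Hz; use a longer coherence segment"),
                 lo, hi, cohspec$freqs[1]))
  mean(cohspec$msc[sel])
}

within_side_pairs <- function() {
  list(c("SCM", "SC"), c("SCM", "UT"), c("SC", "UT"))
}

#' Band-wise MSC features of one (subject, task)
#'
#' For each body side, the three within-side muscle pairs (SCM-SC, SCM-UT,
#' SC-UT): one feature per pair per configured band, named
#' `msc_<band>_<M1>_<M2>_<side>`, plus a broadband (default 1-30 Hz) mean
#' per pair named `msc_broadband_<M1>_<M2>_<side>`.
#'
#' @param trials List of preprocessed N x 6 trial matrices with the
#'   canonical channel columns.
#' @param fs Sampling rate in Hz.
#' @param cfg A [coherence_config()].
#' @return Named numeric vector of 3 pairs x 2 sides x (bands + broadband)
#'   features.
#' @export
coherence_features <- function(trials, fs, cfg = coherence_config()) {
  chans <- colnames(trials[[1]])
  ffts <- lapply(seq_along(chans), function(c)
    trial_segment_ffts(lapply(trials, function(m) m[, c]), fs, cfg))
  names(ffts) <- chans
  out <- numeric(0)
  for (side in c("L", "R")) {
    for (pr in within_side_pairs()) {
      ca <- paste(pr[1], side, sep = "_"); cb <- paste(pr[2], side, sep = "_")
      if (!(ca %in% chans) || !(cb %in% chans))
        stop("missing channel for pair ", ca, " / ", cb)
      spec <- list(freqs = ffts[[ca]]$freqs,
                   msc = msc_from_ffts(ffts[[ca]]$X, ffts[[cb]]$X))
      for (i in seq_len(nrow(cfg$bands))) {
        nm <- paste("msc", cfg$bands$name[i], pr[1], pr[2], side, sep = "_")
        out[nm] <- band_msc(spec, c(cfg$bands$lo[i], cfg$bands$hi[i]))
      }
      nm <- paste("msc_broadband", pr[1], pr[2], side, sep = "_")
      out[nm] <- band_msc(spec, cfg$broadband)
    }
  }
  out
}

#' Band MSC matrix over all channel pairs
#'
#' Symmetric 6 x 6 matrix of band-aggregated MSC over all 15 unordered
#' channel pairs (within- and cross-side), zero diagonal.
#'
#' @inheritParams coherence_features
#' @param band `c(lo, hi)` or a band name.
#' @param pairs `"all"` (default) for all 15 pairs, `"within_side"` to
#'   restrict edges to same-side pairs (cross-side entries zero).
#' @return 6 x 6 named symmetric matrix.
#' @export
msc_band_matrix <- function(trials, fs, band, cfg = coherence_config(),
                            pairs = c("all", "within_side")) {
  pairs <- match.arg(pairs)
  chans <- colnames(trials[[1]])
  ffts <- lapply(seq_along(chans), function(c)
    trial_segment_ffts(lapply(trials, function(m) m[, c]), fs, cfg))
  W <- matrix(0, length(chans), length(chans), dimnames = list(chans, chans))
  for (a in seq_along(chans)) {
    for (b in seq_len(a - 1)) {
      if (pairs == "within_side" &&
          sub(".*_", "", chans[a]) != sub(".*_", "", chans[b])) next
      spec <- list(freqs = ffts[[a]]$freqs,
                   msc = msc_from_ffts(ffts[[a]]$X, ffts[[b]]$X))
      W[a, b] <- W[b, a] <- band_msc(spec, band)
    }
  }
  W
}
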