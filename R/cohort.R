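# Synthetic multichannel EMG cohort generator.
#
# Each channel is built as
#   x_c(t) = A_c * e_c(t) * [ sum_b  kappa_{c,b} u_b(t) + eta_{c,b} nu_{c,b}(t) ]
#            + eps * w_c(t)
# where u_b is a zero-mean unit-variance Gaussian process band-limited to band
# b and shared by the channels of that drive, nu_{c,b} are independent
# band-limited noises, w_c is broadband measurement noise, e_c a periodic gait
# envelope and A_c an amplitude scale.  kappa^2/(kappa^2 + eta^2) equals the
# configured shared-power fraction gamma, so the population band MSC of a
# channel pair is gamma_c * gamma_d (see expected_msc).

#' Fixed EMG channel order
#'
#' Sternocleidomastoid (SCM), splenius capitis (SC) and upper trapezius (UT),
#' left then right within each muscle.
#'
#' @return Character vector of the six channel labels in canonical order.
#' @export
emg_channels <- function() {
  c("SCM_L", "SCM_R", "SC_L", "SC_R", "UT_L", "UT_R")
}

#' Muscle groups and sides
#' @return Character vectors used throughout for name parsing.
#' @keywords internal
emg_muscles <- function() c("SCM", "SC", "UT")

#' Default band-limited shared drives
#'
#' Two drives: a delta-band (1--4 Hz) common drive across all six muscles,
#' reflecting the shared synaptic input associated with force production
#' during gait, and a beta-band (12--25 Hz) corticospinal drive with weaker
#' coupling.  The delta drive carries the group effect: in the chronic
#' neck-pain (CNP) group during curvilinear gait the shared fraction drops by
#' 0.25, emulating the weaker low-frequency connectivity that distinguishes
#' the groups.
#'
#' @return List of drive definitions (band, channels, gamma rules).
#' @export
default_band_drives <- function() {
  list(
    list(
      name = "delta", band = c(1, 4), channels = emg_channels(),
      gamma = list(
        list(group = "all", task = "all", channels = "all", value = 0.6),
        list(group = "CNP", task = "curvilinear", channels = "all", value = 0.35)
      )
    ),
    list(
      name = "beta", band = c(12, 25), channels = emg_channels(),
      gamma = list(
        list(group = "all", task = "all", channels = "all", value = 0.3)
      )
    )
  )
}

#' Default per-channel amplitude scaling rules
#'
#' Baseline 1 for every channel; SCM amplitude is raised by 30% in the CNP
#' group during curvilinear gait (augmented superficial flexor activity).
#'
#' @return List of scaling rules applied in order.
#' @export
default_amplitude_scale <- function() {
  list(
    list(group = "all", task = "all", channels = "all", value = 1),
    list(group = "CNP", task = "curvilinear",
         channels = c("SCM_L", "SCM_R"), value = 1.3)
  )
}

#' Cohort generation parameters
#'
#' @param n_per_group Subjects per group (CNP and control).
#' @param fs Sampling rate in Hz.
#' @param duration_s Trial duration in seconds; `duration_s * fs` must be an
#'   integer number of samples.
#' @param n_trials Trials per subject per task.
#' @param stride_hz Stride (gait-cycle) frequency of the activation envelope.
#' @param band_drives List of shared-drive definitions; see
#'   [default_band_drives()].
#' @param amplitude_scale List of per-channel scaling rules; see
#'   [default_amplitude_scale()].
#' @param noise_floor Broadband measurement-noise power relative to the
#'   band-limited signal power.
#' @param envelope `"gait"` for the periodic activation envelope, `"flat"`
#'   for a constant envelope (the regime in which [expected_msc()] is exact).
#' @param seed Integer master seed; every recording derives its own stream.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 20, fs = 1000, duration_s = 10,
                          n_trials = 3, stride_hz = 1,
                          band_drives = default_band_drives(),
                          amplitude_scale = default_amplitude_scale(),
                          noise_floor = 0.05,
                          envelope = c("gait", "flat"),
                          seed = 1L) {
  envelope <- match.arg(envelope)
  p <- structure(list(
    n_per_group = as.integer(n_per_group), fs = fs, duration_s = duration_s,
    n_trials = as.integer(n_trials), stride_hz = stride_hz,
    channels = emg_channels(), band_drives = band_drives,
    amplitude_scale = amplitude_scale, noise_floor = noise_floor,
    envelope = envelope, seed = as.integer(seed)
  ), class = "cohort_params")
  validate_cohort_params(p)
  p
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic EMG cohort parameters\n")
  cat(sprintf("  %d subjects/group, %d trial(s) x %.3g s at %g Hz, stride %g Hz\n",
              x$n_per_group, x$n_trials, x$duration_s, x$fs, x$stride_hz))
  cat(sprintf("  drives: %s; envelope: %s; noise floor: %g\n",
              paste(vapply(x$band_drives, function(d)
                sprintf("%s [%g-%g Hz]", d$name, d$band[1], d$band[2]), ""),
                collapse = ", "),
              x$envelope, x$noise_floor))
  invisible(x)
}

validate_cohort_params <- function(p) {
  stopifnot(p$n_per_group >= 1, p$n_trials >= 1, p$fs > 0, p$duration_s > 0)
  n <- p$duration_s * p$fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs must be an integer sample count")
  for (d in p$band_drives) {
    if (d$band[1] >= d$band[2])
      stop(sprintf("invalid band [%g, %g]: lo >= hi", d$band[1], d$band[2]))
    if (d$band[2] >= p$fs / 2)
      stop(sprintf("invalid band [%g, %g]: hi >= fs/2", d$band[1], d$band[2]))
    if (!all(d$channels %in% p$channels))
      stop("drive channels must be a subset of the six EMG channels")
    for (rule in d$gamma) {
      if (rule$value < 0 || rule$value > 1)
        stop("shared fractions gamma must lie in [0, 1]")
    }
  }
  if (p$noise_floor < 0) stop("noise_floor must be nonnegative")
  invisible(p)
}

#' Cohort group and task levels
#' @name cohort-levels
#' @keywords internal
NULL
cohort_groups <- function() c("CNP", "control")
cohort_tasks <- function() c("rectilinear", "curvilinear")

## resolve rule lists of the form list(group=, task=, channels=, value=)
## to a named per-channel vector; later rules override earlier ones.
resolve_rules <- function(rules, group, task, channels, default = 0) {
  v <- stats::setNames(rep(default, length(channels)), channels)
  for (rule in rules) {
    if (!(rule$group %in% c("all", group))) next
    if (!(rule$task %in% c("all", task))) next
    ch <- if (identical(rule$channels, "all")) channels else rule$channels
    ch <- intersect(ch, channels)
    v[ch] <- rule$value
  }
  v
}

drive_gamma <- function(drive, group, task, channels) {
  g <- stats::setNames(rep(0, length(channels)), channels)
  in_drive <- intersect(drive$channels, channels)
  g[in_drive] <- resolve_rules(drive$gamma, group, task, in_drive)
  g
}

#' Analytic band MSC of the generator
#'
#' Population magnitude-squared coherence between two channels that share a
#' band-limited drive with shared-power fractions `gamma_c` and `gamma_d`:
#' for x = a s + n1, y = b s + n2 with independent noises the coherence is
#' the product of the two shared-power fractions.  Exact for a flat envelope
#' and no broadband noise; the periodic gait envelope attenuates the
#' segment-averaged estimate below this value.
#'
#' @param params A [cohort_params()] object.
#' @param pair Character vector of two channel labels.
#' @param band Either a drive name (e.g. `"delta"`) or a numeric `c(lo, hi)`
#'   matching a configured drive band.
#' @param group,task Condition for which the gamma rules are resolved.
#' @return Expected band MSC in `[0, 1]`; 0 if no drive covers the pair.
#' @export
expected_msc <- function(params, pair, band, group = "control",
                         task = "rectilinear") {
  stopifnot(length(pair) == 2, all(pair %in% params$channels))
  for (d in params$band_drives) {
    hit <- if (is.character(band)) identical(d$name, band)
           else isTRUE(all.equal(as.numeric(d$band), as.numeric(band)))
    if (!hit) next
    g <- drive_gamma(d, group, task, params$channels)
    return(unname(g[pair[1]] * g[pair[2]]))
  }
  0
}

## zero-phase band-limiting of white noise by FFT masking: spectrum exactly
## flat inside [lo, hi], zero outside; output standardized to unit variance.
band_limited_noise <- function(n, fs, lo, hi, x = stats::rnorm(n)) {
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[!(f >= lo & f <= hi)] <- 0 + 0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Gait activation envelope
#'
#' `e(t) = 0.2 + 0.8 * (0.5 * (1 + sin(2 pi stride_hz t + phi)))^2`:
#' nonnegative, periodic at the stride frequency, with a per-channel phase
#' offset `phi`.
#'
#' @param t Time vector in seconds.
#' @param stride_hz Stride frequency in Hz.
#' @param phase Phase offset in radians.
#' @return Envelope values, same length as `t`.
#' @export
gait_envelope <- function(t, stride_hz, phase = 0) {
  0.2 + 0.8 * (0.5 * (1 + sin(2 * pi * stride_hz * t + phase)))^2
}

subject_number <- function(subject_id) {
  if (is.numeric(subject_id)) return(as.integer(subject_id))
  n <- suppressWarnings(as.integer(gsub("\\D", "", as.character(subject_id))))
  if (is.na(n)) stop("subject_id must contain a numeric index")
  n
}

## deterministic per-recording stream seed, independent of generation order
recording_seed <- function(seed, subject_id, task, trial) {
  task_num <- match(task, cohort_tasks())
  base <- subject_number(subject_id) * 1000 + task_num * 100 + trial
  as.integer((as.double(seed) %% 65521 + base * 2971) %% 2147483647)
}

#' Generate one synthetic EMG recording
#'
#' @param params A [cohort_params()] object.
#' @param subject_id Subject identifier (must contain a numeric index).
#' @param group `"CNP"` or `"control"`.
#' @param task `"rectilinear"` or `"curvilinear"`.
#' @param trial Trial index (1-based).
#' @return Object of class `emg_recording`: fields `subject_id`, `group`,
#'   `task`, `trial`, `fs`, `channel_labels` and `samples`, an N x 6 matrix
#'   (time in rows, channels in the fixed order of [emg_channels()]).
#' @export
generate_recording <- function(params, subject_id, group, task, trial = 1L) {
  validate_cohort_params(params)
  group <- match.arg(group, cohort_groups())
  task <- match.arg(task, cohort_tasks())
  n <- as.integer(round(params$duration_s * params$fs))
  chans <- params$channels
  nc <- length(chans)
  t <- (seq_len(n) - 1) / params$fs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(recording_seed(params$seed, subject_id, task, trial))

  sig <- matrix(0, n, nc, dimnames = list(NULL, chans))
  for (d in params$band_drives) {
    u <- band_limited_noise(n, params$fs, d$band[1], d$band[2])
    g <- drive_gamma(d, group, task, chans)
    for (c in seq_len(nc)) {
      nu <- band_limited_noise(n, params$fs, d$band[1], d$band[2])
      sig[, c] <- sig[, c] + sqrt(g[c]) * u + sqrt(1 - g[c]) * nu
    }
  }

  amp <- resolve_rules(params$amplitude_scale, group, task, chans, default = 1)
  eps <- sqrt(params$noise_floor * length(params$band_drives))
  for (c in seq_len(nc)) {
    e <- if (params$envelope == "gait")
      gait_envelope(t, params$stride_hz, phase = 2 * pi * (c - 1) / nc)
    else rep(1, n)
    w <- stats::rnorm(n)
    sig[, c] <- amp[c] * e * sig[, c] + eps * w
  }
  stopifnot(all(is.finite(sig)))

  structure(list(
    subject_id = as.character(subject_id), group = group, task = task,
    trial = as.integer(trial), fs = params$fs, channel_labels = chans,
    samples = sig
  ), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording %s [%s, %s, trial %d]: %d samples x %d channels at %g Hz\n",
              x$subject_id, x$group, x$task, x$trial,
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

## save/restore the global RNG state so generation order never matters
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Subject roster of a cohort
#'
#' @param params A [cohort_params()] object.
#' @return Data frame with columns `subject_id` and `group`; CNP subjects
#'   first, then controls.
#' @export
cohort_subjects <- function(params) {
  n <- params$n_per_group
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(2 * n)),
    group = rep(cohort_groups(), each = n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort in memory
#'
#' @param params A [cohort_params()] object.
#' @return Object of class `emg_cohort`: `params`, `subjects` roster and a
#'   list `recordings` of [generate_recording()] outputs covering
#'   2 x n_per_group subjects x 2 tasks x n_trials trials.
#' @export
simulate_cohort <- function(params) {
  validate_cohort_params(params)
  subj <- cohort_subjects(params)
  recs <- list()
  for (i in seq_len(nrow(subj))) {
    for (task in cohort_tasks()) {
      for (tr in seq_len(params$n_trials)) {
        recs[[length(recs) + 1L]] <-
          generate_recording(params, subj$subject_id[i], subj$group[i], task, tr)
      }
    }
  }
  structure(list(params = params, subjects = subj, recordings = recs),
            class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EMG cohort: %d recordings (%d subjects x 2 tasks x %d trials)\n",
              length(x$recordings), nrow(x$subjects), x$params$n_trials))
  invisible(x)
}

#' Cohort manifest
#'
#' @param cohort An `emg_cohort`.
#' @param dir Directory the per-recording CSV paths are relative to.
#' @return Data frame with one row per recording: `subject_id`, `group`,
#'   `task`, `trial`, `fs_hz`, `path`.
#' @export
cohort_manifest <- function(cohort, dir = ".") {
  rows <- lapply(cohort$recordings, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group, task = r$task,
               trial = r$trial, fs_hz = r$fs,
               path = file.path("recordings",
                                sprintf("%s_%s_t%d.csv", r$subject_id, r$task, r$trial)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk
#'
#' Writes one headered CSV per recording (`time_s` plus the six channel
#' columns), a `manifest.csv`, and the generation parameters echoed to
#' `params.yaml`.  Regeneration with the same seed is bit-identical.
#'
#' @param params A [cohort_params()] object.
#' @param dir Output directory (created if absent).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return (Invisibly) the manifest data frame.
#' @export
generate_cohort <- function(params, dir, overwrite = FALSE) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE to regenerate")
  cohort <- simulate_cohort(params)
  dir.create(file.path(dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort, dir)
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    df <- data.frame(time_s = (seq_len(nrow(r$samples)) - 1) / r$fs)
    df <- cbind(df, as.data.frame(r$samples))
    data.table::fwrite(df, file.path(dir, man$path[i]))
  }
  data.table::fwrite(man, manifest_path)
  yaml::write_yaml(params_to_list(params), file.path(dir, "params.yaml"))
  invisible(man)
}

params_to_list <- function(params) {
  p <- unclass(params)
  p$n_per_group <- as.integer(p$n_per_group)
  p
}

#' Read a cohort written by [generate_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return An `emg_cohort` (without generation parameters unless
#'   `params.yaml` is present).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", dir)
  man <- as.data.frame(data.table::fread(manifest_path))
  required <- c("subject_id", "group", "task", "trial", "fs_hz", "path")
  if (!all(required %in% names(man)))
    stop("manifest.csv is missing columns: ",
         paste(setdiff(required, names(man)), collapse = ", "))
  recs <- lapply(seq_len(nrow(man)), function(i) {
    df <- as.data.frame(data.table::fread(file.path(dir, man$path[i])))
    chans <- setdiff(names(df), "time_s")
    if (!identical(chans, emg_channels()))
      stop("recording ", man$path[i], " does not have the canonical channel order")
    structure(list(
      subject_id = as.character(man$subject_id[i]), group = man$group[i],
      task = man$task[i], trial = as.integer(man$trial[i]), fs = man$fs_hz[i],
      channel_labels = chans, samples = as.matrix(df[chans])
    ), class = "emg_recording")
  })
  params <- NULL
  pf <- file.path(dir, "params.yaml")
  if (file.exists(pf)) params <- yaml::read_yaml(pf)
  subj <- unique(man[c("subject_id", "group")])
  rownames(subj) <- NULL
  structure(list(params = params, subjects = subj, recordings = recs),
            class = "emg_cohort")
}
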