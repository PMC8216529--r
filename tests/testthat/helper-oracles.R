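# Independent oracles and fixture builders shared across the suite.

# Brute-force betweenness centrality: enumerate all simple paths between
# every node pair, find the shortest total length (edge length = 1/weight),
# and count, with fractional tie splitting, the shortest paths passing
# through each intermediate node.  Independent of the package's igraph
# route.
brute_force_bc <- function(W, tol = 1e-9) {
  n <- nrow(W)
  bc <- numeric(n)
  len <- ifelse(W > 0, 1 / W, Inf)
  all_paths <- function(s, t) {
    paths <- list()
    recurse <- function(path, total) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(path = path, len = total)
        return()
      }
      for (u in seq_len(n)) {
        if (u %in% path || !is.finite(len[v, u])) next
        recurse(c(path, u), total + len[v, u])
      }
    }
    recurse(s, 0)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, 1.0, "len")
      best <- min(lens)
      sp <- paths[lens <= best + tol]
      through <- vapply(seq_len(n), function(v) {
        sum(vapply(sp, function(p)
          v %in% p$path[-c(1, length(p$path))], TRUE))
      }, 1.0)
      bc <- bc + through / length(sp)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# random symmetric nonnegative weight matrix with zero diagonal
random_symmetric_w <- function(n = 6, density = 1, rng = NULL) {
  W <- matrix(0, n, n)
  w <- stats::runif(n * (n - 1) / 2)
  if (density < 1) w[stats::runif(length(w)) > density] <- 0
  W[upper.tri(W)] <- w
  W <- W + t(W)
  dimnames(W) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  W
}

# feature table with one perfectly separating column among pure noise,
# in the package's naming scheme so muscle parsing works
planted_feature_table <- function(n_per_group = 20, n_noise = 9,
                                  sep = 3, noise_sd = 1,
                                  signal_col = "SSI_SC_L") {
  n <- 2 * n_per_group
  noise_cols <- c("MAV_SCM_L", "RMS_SCM_R", "VAR_SC_R", "WL_UT_L",
                  "MNF_UT_R", "MDF_SCM_L", "PKF_SC_L", "MNP_UT_L",
                  "TTP_SCM_R", "MAV_UT_R", "RMS_SC_R", "VAR_SCM_L")
  stopifnot(n_noise <= length(noise_cols))
  X <- matrix(stats::rnorm(n * n_noise, sd = noise_sd), n, n_noise)
  colnames(X) <- noise_cols[seq_len(n_noise)]
  signal <- c(stats::rnorm(n_per_group, -sep / 2, 0.5),
              stats::rnorm(n_per_group, sep / 2, 0.5))
  df <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                   group = rep(c("CNP", "control"), each = n_per_group),
                   task = "curvilinear", stringsAsFactors = FALSE)
  df[[signal_col]] <- signal
  df <- cbind(df, as.data.frame(X))
  class(df) <- c("feature_table", "data.frame")
  df
}

# pure-noise feature table (null fixture)
null_feature_table <- function(n_per_group = 20, n_feat = 10) {
  ft <- planted_feature_table(n_per_group, n_noise = n_feat - 1, sep = 0)
  ft
}

# small but fully exercised synthetic cohort for integration tests
tiny_cohort_params <- function(seed = 7, ...) {
  cohort_params(n_per_group = 3, duration_s = 4, n_trials = 2, seed = seed,
                ...)
}

# quietly preprocess (the Nyquist-clip warning is expected at fs = 1000)
quiet_prep <- function(cohort, cfg = preprocess_config()) {
  suppressWarnings(preprocess_cohort(cohort, cfg))
}
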