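# Band-wise functional muscle networks: MSC adjacency, proportional
# thresholding and graph-topology metrics (strength, betweenness centrality).

#' Build the band-wise MSC adjacency of one (subject, task)
#'
#' @param trials List of preprocessed N x 6 trial matrices.
#' @param fs Sampling rate in Hz.
#' @param band `c(lo, hi)` or a band name from [band_definitions()].
#' @param cfg A [coherence_config()].
#' @param pairs `"all"` for all 15 pairs (default; cross-side edges
#'   included so the 6-node graph is connected) or `"within_side"`.
#' @return Object of class `band_network`: `nodes`, `W` (symmetric, zero
#'   diagonal, entries in `[0, 1]`), `band`, `density_retained` (1 before
#'   thresholding).
#' @export
build_adjacency <- function(trials, fs, band, cfg = coherence_config(),
                            pairs = "all") {
  W <- msc_band_matrix(trials, fs, band, cfg, pairs = pairs)
  structure(list(nodes = colnames(W), W = W, band = band,
                 density_retained = 1),
            class = "band_network")
}

#' @export
print.band_network <- function(x, ...) {
  cat(sprintf("Muscle network (%s): %d nodes, %d nonzero edges, density %.2f\n",
              paste(format(x$band), collapse = "-"), length(x$nodes),
              sum(x$W[upper.tri(x$W)] > 0), x$density_retained))
  invisible(x)
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # lexicographic (row, col)
}

#' Proportional threshold of a weighted adjacency
#'
#' Keeps the `ceiling(p * n_edges)` largest upper-triangle weights (ties
#' broken by the fixed lexicographic node-pair order), zeroes the rest and
#' re-symmetrizes.  Retained edges keep their weights (weighted, not
#' binarized), so every subject's network has the same connection density
#' regardless of its weight scale.
#'
#' @param W Symmetric nonnegative matrix (or a `band_network`).
#' @param p Fraction of edges to retain, in `(0, 1]`.
#' @return Thresholded matrix (or `band_network` with updated
#'   `density_retained`).
#' @export
proportional_threshold <- function(W, p) {
  if (inherits(W, "band_network")) {
    W$W <- proportional_threshold(W$W, p)
    W$density_retained <- p
    return(W)
  }
  if (p <= 0) stop("p must be positive")
  if (p > 1) stop("p must not exceed 1")
  stopifnot(isSymmetric(unname(W)))
  n <- nrow(W)
  pairs <- upper_pairs(n)
  w <- W[pairs]
  keep_n <- ceiling(p * nrow(pairs))
  keep <- order(-w, seq_along(w))[seq_len(keep_n)]
  out <- matrix(0, n, n, dimnames = dimnames(W))
  kp <- pairs[keep, , drop = FALSE]
  out[kp] <- w[keep]
  out[kp[, c(2, 1), drop = FALSE]] <- w[keep]
  out
}

#' Node strength
#'
#' Sum of the weights of the links connected to each node.
#'
#' @param W Symmetric nonnegative matrix (or a `band_network`).
#' @return Named numeric vector of per-node strengths.
#' @export
node_strength <- function(W) {
  if (inherits(W, "band_network")) W <- W$W
  rowSums(W)
}

#' Mean incident edge weight per node
#'
#' Strength divided by degree (0 for isolated nodes); on a proportionally
#' thresholded network this is the mean weight of the retained connections
#' of each muscle.
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
node_strength_mean <- function(W) {
  if (inherits(W, "band_network")) W <- W$W
  deg <- rowSums(W > 0)
  out <- rowSums(W) / pmax(deg, 1)
  out[deg == 0] <- 0
  out
}

#' Normalized weighted betweenness centrality
#'
#' Shortest paths on edge lengths `1/weight` (the conventional mapping for
#' connectivity-weighted graphs), fractional counting of equal-length path
#' ties, normalized by `(n-1)(n-2)/2` so values lie in `[0, 1]`.
#' Disconnected node pairs contribute no paths.
#'
#' @inheritParams node_strength
#' @return Named numeric vector of per-node centralities in `[0, 1]`.
#' @export
betweenness_centrality <- function(W) {
  if (inherits(W, "band_network")) W <- W$W
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = len)
  # vertex order equals matrix order (isolated nodes included)
  stats::setNames(as.numeric(b) / ((n - 1) * (n - 2) / 2), rownames(W))
}

#' Per-subject band networks of a cohort
#'
#' @param prep An `emg_prep` from [preprocess_cohort()].
#' @param band `c(lo, hi)` or a band name.
#' @param p Proportional-threshold density (default 0.5; the source
#'   literature does not publish its density, so it is exposed prominently).
#' @param cfg A [coherence_config()].
#' @param task Optional task filter (`"rectilinear"` or `"curvilinear"`).
#' @param pairs Passed to [build_adjacency()].
#' @return List of `band_network` objects, one per (subject, task) entry,
#'   each carrying `subject_id`, `group`, `task`.
#' @export
subject_networks <- function(prep, band, p = 0.5, cfg = coherence_config(),
                             task = NULL, pairs = "all") {
  idx <- seq_len(nrow(prep$index))
  if (!is.null(task)) idx <- idx[prep$index$task == task]
  lapply(idx, function(i) {
    net <- build_adjacency(prep$wideband[[i]], prep$fs, band, cfg, pairs = pairs)
    net <- proportional_threshold(net, p)
    net$subject_id <- prep$index$subject_id[i]
    net$group <- prep$index$group[i]
    net$task <- prep$index$task[i]
    net
  })
}

network_metric <- function(net, metric) {
  switch(metric,
         strength = node_strength(net),
         strength_mean = node_strength_mean(net),
         bc = betweenness_centrality(net),
         stop("unknown metric: ", metric))
}

#' Group comparison of a network metric
#'
#' For each subject the metric is averaged across the six nodes; groups are
#' summarized as mean +/- SD and compared with a two-sample Student's
#' t-test.  The group-average adjacency matrices (before node averaging)
#' are returned for graph export.
#'
#' @param prep An `emg_prep`.
#' @param band `c(lo, hi)` or a band name.
#' @param task Task to analyze (`"rectilinear"` or `"curvilinear"`).
#' @param metric `"strength"`, `"strength_mean"` or `"bc"`.
#' @param p Proportional-threshold density.
#' @param cfg A [coherence_config()].
#' @param pairs Passed to [build_adjacency()].
#' @return List of class `network_comparison`: `per_subject` data frame,
#'   `summary` (group means and SDs), `test` ([ttest_two_sample()] result)
#'   and `group_mean_adjacency` (named list of matrices).
#' @export
group_network_analysis <- function(prep, band, task, metric = "strength",
                                   p = 0.5, cfg = coherence_config(),
                                   pairs = "all") {
  nets <- subject_networks(prep, band, p, cfg, task = task, pairs = pairs)
  if (!length(nets)) stop("no subjects for task ", task)
  per <- do.call(rbind, lapply(nets, function(net) {
    data.frame(subject_id = net$subject_id, group = net$group, task = net$task,
               value = mean(network_metric(net, metric)),
               stringsAsFactors = FALSE)
  }))
  counts <- table(per$group)
  if (length(counts) < 2 || any(counts < 2))
    stop("each group needs at least 2 subjects")
  a <- per$value[per$group == "CNP"]
  b <- per$value[per$group == "control"]
  test <- ttest_two_sample(a, b)
  summary_df <- data.frame(
    group = cohort_groups(),
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(stats::sd(a), stats::sd(b)))
  mean_adj <- lapply(stats::setNames(cohort_groups(), cohort_groups()),
                     function(g) {
    Ws <- lapply(nets[vapply(nets, function(n) n$group, "") == g],
                 function(n) n$W)
    Reduce(`+`, Ws) / length(Ws)
  })
  structure(list(band = band, task = task, metric = metric, p = p,
                 per_subject = per, summary = summary_df, test = test,
                 group_mean_adjacency = mean_adj),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison: %s, %s task, band %s, density %.2f\n",
              x$metric, x$task, paste(format(x$band), collapse = "-"), x$p))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s %5.3f +/- %.3f (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g\n",
              x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' Edge list of an adjacency matrix
#'
#' @param W Symmetric matrix (or `band_network`).
#' @return Data frame `node_a`, `node_b`, `weight` over nonzero
#'   upper-triangle edges, in lexicographic pair order.
#' @export
adjacency_edge_list <- function(W) {
  if (inherits(W, "band_network")) W <- W$W
  pairs <- upper_pairs(nrow(W))
  w <- W[pairs]
  keep <- w > 0
  data.frame(node_a = rownames(W)[pairs[keep, 1]],
             node_b = colnames(W)[pairs[keep, 2]],
             weight = w[keep], stringsAsFactors = FALSE)
}
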