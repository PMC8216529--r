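# Neighbourhood component analysis (NCA) feature weighting:
# gradient ascent on the expected leave-one-out nearest-neighbour accuracy
# under a stochastic neighbour rule, with per-feature weights.

#' Z-score standardization with stored scaler parameters
#'
#' @param X Numeric matrix (rows = samples).
#' @param scaler Optional scaler from a previous call, to apply training
#'   parameters to held-out rows.
#' @return List: `X` standardized (zero-variance columns dropped, recorded
#'   in `dropped`), `center`, `scale`, `dropped`.
#' @export
standardize <- function(X, scaler = NULL) {
  if (!is.null(scaler)) {
    X <- X[, setdiff(colnames(X), scaler$dropped), drop = FALSE]
    Xs <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
    return(list(X = Xs, center = scaler$center, scale = scaler$scale,
                dropped = scaler$dropped))
  }
  stopifnot(nrow(X) >= 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[scl == 0]
  if (length(dropped))
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  list(X = Xs, center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' NCA hyperparameters
#'
#' @param lambda Ridge penalty on the squared weights; default `1/n` at fit
#'   time (`NULL` here).
#' @param sigma Softmax kernel width on standardized features.
#' @param learning_rate Initial gradient-ascent step size (adapted during
#'   the fit: halved after a decrease, grown 5% after an increase).
#' @param max_iter Iteration budget.
#' @param tol Convergence: objective change below `tol` over 5 consecutive
#'   iterations.
#' @return List of hyperparameters.
#' @export
nca_config <- function(lambda = NULL, sigma = 1, learning_rate = 0.2,
                       max_iter = 200, tol = 1e-6) {
  list(lambda = lambda, sigma = sigma, learning_rate = learning_rate,
       max_iter = max_iter, tol = tol)
}

#' Fit NCA feature weights
#'
#' Maximizes `F(w) = sum_i p_i - lambda sum_r w_r^2`, where
#' `p_i = sum_{j != i, y_j = y_i} p_ij`,
#' `p_ij = exp(-d_w(x_i, x_j)/sigma) / sum_{l != i} exp(-d_w(x_i, x_l)/sigma)`
#' and `d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|` (the standard
#' feature-weighting form with a quadratic weight parameterization).
#' Gradient ascent starts from the all-ones weight vector; the objective is
#' deterministic, so `seed` only labels the result.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Class labels (>= 2 samples per class).
#' @param cfg An [nca_config()].
#' @param seed Recorded in the result for provenance.
#' @return Object of class `nca_result`: `feature_names`, `weights`
#'   (nonnegative), `ranking` (feature indices, descending weight, ties by
#'   column order), `objective_trace`, `hyperparams`, `converged`.
#' @export
nca_fit <- function(X, y, cfg = nca_config(), seed = NULL) {
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  lambda <- if (is.null(cfg$lambda)) 1 / n else cfg$lambda
  same <- outer(y, y, `==`); diag(same) <- FALSE

  ## |x_ir - x_jr| flattened to (n*n) x p for fast d and gradient contraction
  A <- matrix(0, n * n, p)
  for (r in seq_len(p))
    A[, r] <- abs(rep(X[, r], times = n) - rep(X[, r], each = n))

  objective_and_grad <- function(w) {
    d <- matrix(A %*% (w^2), n, n)           # d[i, j], symmetric
    K <- exp(-d / cfg$sigma)
    diag(K) <- 0
    denom <- rowSums(K)
    denom[denom == 0] <- .Machine$double.eps
    P <- K / denom                           # p_ij
    p_i <- rowSums(P * same)
    ## dF/dw_r = (2 w_r / sigma) sum_ij (p_i p_ij - p_ij 1[same]) A_ijr - 2 lambda w_r
    Mc <- p_i * P - P * same                 # row-recycled p_i
    g <- (2 * w / cfg$sigma) * as.numeric(crossprod(A, as.numeric(t(Mc)))) -
      2 * lambda * w
    list(f = sum(p_i) - lambda * sum(w^2), g = g)
  }

  w <- rep(1, p)
  lr <- cfg$learning_rate
  trace <- numeric(0)
  og <- objective_and_grad(w)
  stalled <- 0L; converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    if (!all(is.finite(og$g)))
      stop("non-finite NCA gradient at iteration ", it)
    w_new <- w + lr * og$g
    og_new <- objective_and_grad(w_new)
    if (og_new$f >= og$f) {
      delta <- og_new$f - og$f
      w <- w_new; og <- og_new
      lr <- lr * 1.05
      stalled <- if (delta < cfg$tol) stalled + 1L else 0L
    } else {
      lr <- lr / 2                        # overshoot: back off, keep trying
      if (lr < 1e-12) { converged <- TRUE; break }
    }
    trace[it] <- og$f
    if (stalled >= 5L) { converged <- TRUE; break }
  }
  weights <- abs(w)
  structure(list(
    feature_names = colnames(X), weights = stats::setNames(weights, colnames(X)),
    ranking = order(-weights, seq_along(weights)),
    objective_trace = trace, converged = converged,
    hyperparams = list(lambda = lambda, sigma = cfg$sigma,
                       learning_rate = cfg$learning_rate,
                       max_iter = cfg$max_iter, tol = cfg$tol, seed = seed)
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA fit: %d features, %d iterations (%sconverged)\n",
              length(x$weights), length(x$objective_trace),
              if (x$converged) "" else "not "))
  top <- x$ranking[seq_len(min(5, length(x$ranking)))]
  cat("  top weights:",
      paste(sprintf("%s = %.3f", x$feature_names[top], x$weights[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Select the top-k features by NCA weight
#'
#' @param result An `nca_result`.
#' @param k Number of features to keep (ties broken by fixed column order).
#' @return Character vector of k feature names.
#' @export
rank_and_select <- function(result, k) {
  stopifnot(k >= 1, k <= length(result$weights))
  result$feature_names[result$ranking[seq_len(k)]]
}

#' Cross-validated accuracy as a function of subset size
#'
#' For each k in `k_grid`, runs [cross_validate()] with an NCA-selected
#' top-k subset (NCA refit inside each training fold by default; set
#' `paper_mode = TRUE` to fit once on all rows).
#'
#' @param table A `feature_table`.
#' @param classifier A classifier contract (e.g. [svm_rbf_classifier()]).
#' @param k_grid Integer vector of subset sizes.
#' @param cv_cfg A [cv_config()].
#' @param task Task view passed to [feature_matrix()].
#' @param nca_cfg An [nca_config()].
#' @param paper_mode Fit NCA once on the full table instead of per fold.
#' @return Data frame `(k, accuracy)` with attribute `best` (the k of the
#'   maximal accuracy, earliest on ties).
#' @export
accuracy_vs_k <- function(table, classifier, k_grid, cv_cfg = cv_config(),
                          task = NULL, nca_cfg = nca_config(),
                          paper_mode = FALSE) {
  acc <- vapply(k_grid, function(k) {
    rep <- cross_validate(table, classifier, cv_cfg, task = task,
                          select = list(method = "nca", k = k,
                                        cfg = nca_cfg,
                                        refit = !paper_mode))
    rep$accuracy
  }, 1.0)
  out <- data.frame(k = k_grid, accuracy = acc)
  attr(out, "best") <- k_grid[which.max(acc)]
  out
}

#' Per-muscle NCA weight summary
#'
#' Pools weights across sides per muscle (MSC pair features contribute to
#' both muscles of the pair) and reports median and quartiles, mirroring
#' the per-muscle weight distributions used to judge which muscle carries
#' discriminative information.
#'
#' @param result An `nca_result` whose feature names parse with
#'   [parse_feature_name()].
#' @return Data frame: `muscle`, `n`, `q1`, `median`, `q3`.
#' @export
muscle_weight_summary <- function(result) {
  parsed <- parse_feature_name(result$feature_names)
  rows <- lapply(emg_muscles(), function(m) {
    sel <- vapply(parsed$muscles, function(ms) m %in% ms, TRUE)
    w <- result$weights[sel]
    q <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(muscle = m, n = length(w), q1 = q[1], median = q[2], q3 = q[3])
  })
  do.call(rbind, rows)
}
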