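# K-NN, LDA and RBF-SVM under stratified 5-fold cross-validation, with
# pooled confusion-matrix metrics per task, feature set and muscle.

#' Cross-validation configuration
#'
#' @param n_folds Number of folds (>= 2).
#' @param stratified Stratify folds by class (default TRUE).
#' @param seed Seed for the fold shuffle; fold membership is a pure
#'   function of `(seed, subject order)`.
#' @param positive_class Class treated as positive for
#'   sensitivity/specificity (default `"CNP"`; the choice is recorded in
#'   every report).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5, stratified = TRUE, seed = 1L,
                      positive_class = "CNP") {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed), positive_class = positive_class),
            class = "cv_config")
}

#' K-nearest-neighbours classifier contract
#'
#' Majority vote of the k nearest training samples under Euclidean
#' distance.  Distance ties are broken by training-row order, vote ties by
#' the lowest class index — both deterministic.
#'
#' @param k Number of neighbours (default 5).
#' @return Classifier contract (list with `name`, `fit`, `predict`,
#'   `hyperparams`).
#' @export
knn_classifier <- function(k = 5) {
  list(
    name = "KNN", hyperparams = list(k = k),
    fit = function(X, y) {
      if (k > nrow(X)) stop("k exceeds the training-set size")
      list(X = X, y = as.factor(y), k = k)
    },
    predict = function(model, X) {
      lev <- levels(model$y)
      pred <- apply(X, 1, function(q) {
        d <- sqrt(colSums((t(model$X) - q)^2))
        nb <- order(d, seq_along(d))[seq_len(model$k)]
        votes <- tabulate(as.integer(model$y[nb]), nbins = length(lev))
        lev[which.max(votes)]           # vote tie -> lowest class index
      })
      factor(pred, levels = lev)
    })
}

## shared-covariance linear discriminant with ridge regularization,
## used when MASS::lda cannot be fit (e.g. exactly singular covariance)
ridge_lda_fit <- function(X, y, reg = 1e-3) {
  y <- as.factor(y)
  classes <- levels(y)
  means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(ncol(X))))
  n <- nrow(X)
  Sw <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xc <- scale(X[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - length(classes))
  Sw <- Sw + reg * mean(diag(Sw)) * diag(ncol(X))
  Sinv <- solve(Sw)
  priors <- as.numeric(table(y)) / n
  list(means = means, Sinv = Sinv, priors = priors, classes = classes)
}

ridge_lda_predict <- function(model, X) {
  scores <- vapply(seq_along(model$classes), function(i) {
    mu <- model$means[i, ]
    as.numeric(X %*% (model$Sinv %*% mu)) -
      0.5 * as.numeric(mu %*% model$Sinv %*% mu) + log(model$priors[i])
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(model$classes[max.col(scores, ties.method = "first")],
         levels = model$classes)
}

#' Linear discriminant analysis classifier contract
#'
#' Shared-covariance linear discriminant via [MASS::lda()]; if the
#' within-class covariance is exactly singular the fit falls back to an
#' in-package ridge-regularized discriminant (the fallback is flagged in
#' the fitted model).
#'
#' @return Classifier contract.
#' @export
lda_classifier <- function() {
  list(
    name = "LDA", hyperparams = list(),
    fit = function(X, y) {
      m <- tryCatch(suppressWarnings(MASS::lda(X, grouping = as.factor(y))),
                    error = function(e) NULL)
      if (is.null(m)) list(ridge = ridge_lda_fit(X, y), regularized = TRUE)
      else list(lda = m, regularized = FALSE)
    },
    predict = function(model, X) {
      if (model$regularized) ridge_lda_predict(model$ridge, X)
      else stats::predict(model$lda, X)$class
    })
}

#' RBF-kernel support vector machine classifier contract
#'
#' @param C Cost parameter.
#' @param gamma Kernel width; `NULL` (default) uses `1/n_features` on the
#'   standardized inputs.
#' @return Classifier contract.
#' @export
svm_rbf_classifier <- function(C = 1, gamma = NULL) {
  list(
    name = "SVM", hyperparams = list(C = C, gamma = gamma),
    fit = function(X, y) {
      if (!all(is.finite(X))) stop("non-finite feature values")
      g <- if (is.null(gamma)) 1 / ncol(X) else gamma
      e1071::svm(X, as.factor(y), kernel = "radial", cost = C, gamma = g,
                 scale = FALSE)
    },
    predict = function(model, X) stats::predict(model, X))
}

#' The three study classifiers
#' @return Named list of classifier contracts (KNN, SVM, LDA).
#' @export
default_classifiers <- function() {
  list(KNN = knn_classifier(), SVM = svm_rbf_classifier(),
       LDA = lda_classifier())
}

#' Confusion-matrix metrics
#'
#' @param tp,fn,fp,tn Pooled confusion-matrix counts.
#' @return List `accuracy`, `sensitivity` (`tp/(tp+fn)`), `specificity`
#'   (`tn/(tn+fp)`), as proportions.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  tp <- unname(tp); fn <- unname(fn); fp <- unname(fp); tn <- unname(tn)
  total <- tp + fn + fp + tn
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Integer confusion matrices consistent with printed rates
#'
#' Enumerates all nonnegative integer matrices `(TP, FN, FP, TN)` summing
#' to `n` whose percentage accuracy, sensitivity and specificity agree with
#' the printed values within `tol` percentage points (printed tables often
#' truncate rather than round, so the default tolerance is one unit in the
#' last printed digit).
#'
#' @param accuracy,sensitivity,specificity Printed percentages.
#' @param n Total number of pooled predictions.
#' @param tol Matching tolerance in percentage points.
#' @return Data frame of consistent matrices with their exact rates (in
#'   percent).
#' @export
consistent_confusion_matrix <- function(accuracy, sensitivity, specificity,
                                        n = 40, tol = 0.01) {
  out <- list()
  for (pos in 1:(n - 1)) {
    for (tp in 0:pos) {
      fn <- pos - tp
      neg <- n - pos
      for (tn in 0:neg) {
        fp <- neg - tn
        m <- confusion_metrics(tp, fn, fp, tn)
        if (abs(100 * m$accuracy - accuracy) <= tol &&
            abs(100 * m$sensitivity - sensitivity) <= tol &&
            abs(100 * m$specificity - specificity) <= tol)
          out[[length(out) + 1L]] <- data.frame(
            TP = tp, FN = fn, FP = fp, TN = tn,
            accuracy = 100 * m$accuracy, sensitivity = 100 * m$sensitivity,
            specificity = 100 * m$specificity)
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

## stratified (or plain) fold assignment; a pure function of (seed, y order)
make_folds <- function(y, cv_cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cv_cfg$seed)
  n <- length(y)
  fold <- integer(n)
  if (cv_cfg$stratified) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(cv_cfg$n_folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(cv_cfg$n_folds), n)
  }
  fold
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified folds from a seeded shuffle; standardization (and, when
#' requested, NCA feature selection) is fit on the training folds only and
#' applied to the held-out fold.  All held-out predictions are pooled into
#' a single confusion matrix (micro pooling); per-fold metrics are also
#' reported.
#'
#' @param table A `feature_table`.
#' @param classifier Classifier contract (see [knn_classifier()]).
#' @param cv_cfg A [cv_config()].
#' @param task Task view (`"rectilinear"`, `"curvilinear"`, `"combine"` or
#'   `NULL`).
#' @param features Optional fixed feature subset (column names).
#' @param select Optional selection spec
#'   `list(method = "nca", k, cfg = nca_config(), refit = TRUE)`;
#'   `refit = FALSE` fits NCA once on all rows before cross-validation (the
#'   optimistic single-fit variant, labelled in the report).
#' @return Object of class `classification_report`.
#' @export
cross_validate <- function(table, classifier, cv_cfg = cv_config(),
                           task = NULL, features = NULL, select = NULL) {
  fm <- feature_matrix(table, task = task, features = features)
  y <- droplevels(fm$y)
  if (nlevels(y) < 2) stop("both classes must be present")
  fold <- make_folds(y, cv_cfg)

  global_subset <- NULL
  if (!is.null(select) && !isTRUE(select$refit)) {
    sc <- standardize(fm$X)
    fit <- nca_fit(sc$X, y, cfg = select$cfg %||% nca_config(),
                   seed = cv_cfg$seed)
    global_subset <- rank_and_select(fit, select$k)
  }

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  per_fold <- list()
  for (f in seq_len(cv_cfg$n_folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) next
    if (nlevels(droplevels(y[tr])) < 2)
      stop("fold ", f, " has a training set without both classes")
    sc <- standardize(fm$X[tr, , drop = FALSE])
    Xte <- standardize(fm$X[te, , drop = FALSE], scaler = sc)$X
    Xtr <- sc$X
    if (!is.null(select)) {
      subset <- global_subset
      if (is.null(subset)) {
        fit <- nca_fit(Xtr, y[tr], cfg = select$cfg %||% nca_config(),
                       seed = cv_cfg$seed)
        subset <- rank_and_select(fit, min(select$k, ncol(Xtr)))
      }
      subset <- intersect(subset, colnames(Xtr))
      Xtr <- Xtr[, subset, drop = FALSE]
      Xte <- Xte[, subset, drop = FALSE]
    }
    model <- classifier$fit(Xtr, y[tr])
    pf <- classifier$predict(model, Xte)
    pred[te] <- pf
    cm <- fold_confusion(y[te], pf, cv_cfg$positive_class)
    per_fold[[f]] <- data.frame(fold = f, n = sum(te),
                                accuracy = cm$metrics$accuracy)
  }
  cm <- fold_confusion(y, pred, cv_cfg$positive_class)
  structure(list(
    classifier = classifier$name,
    task = if (is.null(task)) "all" else task,
    feature_set = if (!is.null(select)) {
      sprintf("nca_top%d%s", select$k,
              if (isTRUE(select$refit)) "" else "_singlefit")
    } else if (!is.null(features)) "custom" else "all",
    confusion = cm$counts,
    accuracy = cm$metrics$accuracy,
    sensitivity = cm$metrics$sensitivity,
    specificity = cm$metrics$specificity,
    per_fold = do.call(rbind, per_fold),
    n = length(y),
    positive_class = cv_cfg$positive_class,
    hyperparams = classifier$hyperparams,
    seed = cv_cfg$seed
  ), class = "classification_report")
}

fold_confusion <- function(truth, pred, positive_class) {
  pos <- truth == positive_class
  ppos <- pred == positive_class
  counts <- c(TP = sum(pos & ppos), FN = sum(pos & !ppos),
              FP = sum(!pos & ppos), TN = sum(!pos & !ppos))
  list(counts = counts,
       metrics = confusion_metrics(counts["TP"], counts["FN"],
                                   counts["FP"], counts["TN"]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s | task %s | features %s (positive class: %s)\n",
              x$classifier, x$task, x$feature_set, x$positive_class))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$confusion["TP"],
              x$confusion["FN"], x$confusion["FP"], x$confusion["TN"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Classification power of each muscle individually
#'
#' Cross-validates the classifier restricted to the single-muscle features
#' of each muscle (both sides; MSC pair features span two muscles and are
#' excluded from the per-muscle views).
#'
#' @inheritParams cross_validate
#' @return Named list of `classification_report`s keyed by muscle.
#' @export
per_muscle_evaluation <- function(table, classifier, cv_cfg = cv_config(),
                                  task = NULL) {
  meta <- c("subject_id", "group", "task")
  parsed <- parse_feature_name(setdiff(names(table), meta))
  out <- list()
  for (m in emg_muscles()) {
    cols <- parsed$name[vapply(parsed$muscles, function(ms)
      length(ms) == 1 && ms == m, TRUE)]
    out[[m]] <- cross_validate(table, classifier, cv_cfg, task = task,
                               features = cols)
  }
  out
}

#' Full task x classifier x feature-set comparison grid
#'
#' Evaluates every classifier on each task view (curvilinear, rectilinear,
#' combine) with all features and with the NCA-selected top-k subset:
#' 3 x 3 x 2 = 18 reports.
#'
#' @param table A `feature_table` holding both tasks.
#' @param cv_cfg A [cv_config()].
#' @param classifiers Named list of classifier contracts.
#' @param k NCA subset size (default 16).
#' @param nca_cfg An [nca_config()].
#' @param paper_mode Fit NCA once per task instead of per training fold.
#' @return Object of class `task_comparison`: `reports` (nested list
#'   `[[feature_set]][[classifier]][[task]]`) and `summary`, a flat data
#'   frame with one row per (feature_set, classifier, metric) and one
#'   column per task.
#' @export
task_comparison <- function(table, cv_cfg = cv_config(),
                            classifiers = default_classifiers(), k = 16,
                            nca_cfg = nca_config(), paper_mode = FALSE) {
  tasks <- c("curvilinear", "rectilinear", "combine")
  sets <- list(all = NULL,
               nca = list(method = "nca", k = k, cfg = nca_cfg,
                          refit = !paper_mode))
  reports <- list()
  for (set_name in names(sets)) {
    for (cl_name in names(classifiers)) {
      for (task in tasks) {
        reports[[set_name]][[cl_name]][[task]] <-
          cross_validate(table, classifiers[[cl_name]], cv_cfg, task = task,
                         select = sets[[set_name]])
      }
    }
  }
  rows <- list()
  for (set_name in names(sets)) {
    for (cl_name in names(classifiers)) {
      for (metric in c("accuracy", "specificity", "sensitivity")) {
        vals <- vapply(tasks, function(task)
          100 * reports[[set_name]][[cl_name]][[task]][[metric]], 1.0)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(feature_set = set_name, classifier = cl_name,
                     metric = toupper(substr(metric, 1, 4))),
          as.data.frame(as.list(vals)))
      }
    }
  }
  structure(list(reports = reports, summary = do.call(rbind, rows), k = k),
            class = "task_comparison")
}

#' @export
print.task_comparison <- function(x, ...) {
  cat("Classification performance (%) per trajectory\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
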