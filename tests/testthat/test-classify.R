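# fixtures: two well-separated Gaussian blobs, and label-free noise
blob_table <- function(n_per_group = 20, sep = 2, sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  df <- data.frame(subject_id = sprintf("sub%03d", 1:n),
                   group = rep(c("CNP", "control"), each = n_per_group),
                   task = "curvilinear", stringsAsFactors = FALSE)
  df$MAV_SCM_L <- rnorm(n, rep(c(-sep / 2, sep / 2), each = n_per_group), sd)
  df$RMS_SC_L <- rnorm(n, rep(c(sep / 2, -sep / 2), each = n_per_group), sd)
  class(df) <- c("feature_table", "data.frame")
  df
}

test_that("confusion-matrix metrics satisfy their defining identities", {
  m <- confusion_metrics(16, 2, 4, 18)
  expect_equal(100 * m$accuracy, 85.00)
  expect_equal(100 * m$sensitivity, 88.89, tolerance = 0.001)
  expect_equal(100 * m$specificity, 81.82, tolerance = 0.001)

  p <- confusion_metrics(20, 0, 0, 20)
  expect_equal(c(p$accuracy, p$sensitivity, p$specificity), c(1, 1, 1))

  # all-positive predictor on balanced data
  q <- confusion_metrics(20, 0, 20, 0)
  expect_equal(q$accuracy, 0.5)
  expect_equal(q$sensitivity, 1)
  expect_equal(q$specificity, 0)
})

test_that("printed per-class rates identify a unique 40-sample confusion matrix", {
  svm_row <- consistent_confusion_matrix(85.00, 88.88, 81.81, n = 40)
  expect_equal(nrow(svm_row), 1)
  expect_equal(svm_row$TP, 16); expect_equal(svm_row$FN, 2)
  expect_equal(svm_row$FP, 4); expect_equal(svm_row$TN, 18)
  expect_equal(svm_row$accuracy, 85.00)

  lda_row <- consistent_confusion_matrix(75.00, 77.77, 72.72, n = 40)
  expect_equal(nrow(lda_row), 1)
  expect_equal(unlist(lda_row[1, c("TP", "FN", "FP", "TN")]),
               c(TP = 14, FN = 4, FP = 6, TN = 16))
})

test_that("K-NN votes deterministically among the nearest neighbours", {
  clf <- knn_classifier(k = 5)
  X <- matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE)
  y <- factor(rep("CNP", 5), levels = c("CNP", "control"))
  model <- clf$fit(X, y)
  expect_equal(as.character(clf$predict(model, matrix(c(0, 0), 1))), "CNP")
  expect_error(knn_classifier(k = 10)$fit(X, y), "exceeds")
})

test_that("all three classifiers separate blobs and are at chance on noise", {
  seps <- blob_table()
  nulls <- null_feature_table()
  for (clf in default_classifiers()) {
    r <- cross_validate(seps, clf, cv_config(seed = 2))
    expect_equal(r$accuracy, 1)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$specificity, 1)
    rn <- cross_validate(nulls, clf, cv_config(seed = 2))
    expect_gte(rn$accuracy, 0.2)   # binomial band around 0.5 at n = 40
    expect_lte(rn$accuracy, 0.8)
  }
})

test_that("SVM degenerates gracefully to nearest-mean with one sample per class", {
  X <- rbind(c(-1, 0), c(1, 0))
  colnames(X) <- c("a", "b")
  y <- factor(c("CNP", "control"))
  clf <- svm_rbf_classifier()
  model <- clf$fit(X, y)
  pred <- clf$predict(model, rbind(c(-0.9, 0.1), c(0.9, -0.1)))
  expect_equal(as.character(pred), c("CNP", "control"))
})

test_that("LDA falls back to a ridge discriminant when the fit is singular", {
  # p >> n with duplicated columns: exercise the in-package fallback directly
  set.seed(3)
  X <- matrix(rnorm(10 * 4), 10, 4); X <- cbind(X, X)
  colnames(X) <- paste0("f", 1:8)
  y <- factor(rep(c("CNP", "control"), each = 5))
  m <- musclenet:::ridge_lda_fit(X, y)
  pred <- musclenet:::ridge_lda_predict(m, X)
  expect_s3_class(pred, "factor")
  expect_length(pred, 10)
})

test_that("cross-validation pools held-out predictions into one confusion matrix", {
  ft <- blob_table(sep = 0.8, sd = 0.5, seed = 4)
  r <- cross_validate(ft, lda_classifier(), cv_config(seed = 7))
  cm <- r$confusion
  expect_equal(unname(sum(cm)), r$n)
  expect_equal(r$accuracy, unname((cm["TP"] + cm["TN"]) / sum(cm)))
  expect_equal(r$sensitivity, unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_equal(r$specificity, unname(cm["TN"] / (cm["TN"] + cm["FP"])))
  # per-fold metrics cover every fold
  expect_equal(nrow(r$per_fold), 5)

  # reports are bit-identical across reruns with the same seed
  r2 <- cross_validate(ft, lda_classifier(), cv_config(seed = 7))
  expect_identical(r, r2)
  # and fold membership responds to the seed
  r3 <- cross_validate(ft, lda_classifier(), cv_config(seed = 8))
  expect_false(identical(r$per_fold, r3$per_fold))
})

test_that("degenerate class layouts are refused", {
  ft <- blob_table(n_per_group = 3)
  ft$group <- c("CNP", rep("control", 5))   # one-sample class
  expect_error(cross_validate(ft, knn_classifier(k = 1), cv_config(seed = 1)),
               "both classes")
})

test_that("per-muscle evaluation isolates the informative muscle", {
  set.seed(8)
  ft <- planted_feature_table(n_per_group = 15, n_noise = 9)
  reports <- per_muscle_evaluation(ft, knn_classifier(), cv_config(seed = 3))
  expect_named(reports, c("SCM", "SC", "UT"))
  accs <- vapply(reports, `[[`, 1.0, "accuracy")
  expect_equal(names(which.max(accs)), "SC")
  expect_equal(unname(accs["SC"]), 1)
})

test_that("task comparison evaluates the full 3 x 3 x 2 grid", {
  set.seed(9)
  p <- cohort_params(n_per_group = 4, duration_s = 4, n_trials = 1, seed = 7)
  co <- simulate_cohort(p)
  prep <- quiet_prep(co)
  ft <- build_feature_table(prep)
  clfs <- list(KNN = knn_classifier(3), SVM = svm_rbf_classifier(),
               LDA = lda_classifier())
  tc <- task_comparison(ft, cv_config(n_folds = 2, seed = 5),
                        classifiers = clfs, k = 8)
  expect_equal(sum(vapply(tc$reports, function(s) sum(lengths(s)), 1L)), 18)
  expect_equal(nrow(tc$summary), 18)   # 2 sets x 3 classifiers x 3 metrics
  expect_named(tc$summary,
               c("feature_set", "classifier", "metric",
                 "curvilinear", "rectilinear", "combine"))
  # the combine view pools both tasks' rows
  expect_equal(tc$reports$all$KNN$combine$n, 2 * tc$reports$all$KNN$curvilinear$n)
})
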