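test_that("standardization zeroes means, units SDs, and round-trips", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5, mean = 3, sd = 2), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  sc <- standardize(X)
  expect_equal(unname(colMeans(sc$X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sc$X, 2, sd)), rep(1, 5), tolerance = 1e-12)
  again <- standardize(X, scaler = sc)
  expect_equal(again$X, sc$X, tolerance = 1e-12)

  Xc <- cbind(X, const = 7)
  expect_warning(sc2 <- standardize(Xc), "zero-variance")
  expect_false("const" %in% colnames(sc2$X))
  expect_equal(sc2$dropped, "const")
})

test_that("NCA recovers a planted separating feature among noise", {
  top_hits <- 0
  for (seed in 1:3) {
    set.seed(seed)
    ft <- planted_feature_table(n_per_group = 20, n_noise = 9)
    fm <- feature_matrix(ft)
    sc <- standardize(fm$X)
    fit <- nca_fit(sc$X, fm$y, seed = seed)
    w <- fit$weights
    if (names(which.max(w)) == "SSI_SC_L") top_hits <- top_hits + 1
    expect_lt(median(w[names(w) != "SSI_SC_L"]), 0.25 * max(w))
  }
  expect_gte(top_hits, 2)
})

test_that("duplicated features share the squared weight of a single copy", {
  set.seed(2)
  n <- 40
  x <- c(rnorm(20, -1.5, 0.6), rnorm(20, 1.5, 0.6))
  y <- rep(c("CNP", "control"), each = 20)
  noise <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("n", 1:5)))
  X1 <- cbind(sig = x, noise)
  X2 <- cbind(sig = x, sig2 = x, noise)
  f1 <- nca_fit(standardize(X1)$X, y)
  f2 <- nca_fit(standardize(X2)$X, y)
  expect_equal(f2$weights["sig"], f2$weights["sig2"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f2$weights["sig"]^2 + f2$weights["sig2"]^2,
               f1$weights["sig"]^2, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("strong regularization drives all weights to zero", {
  set.seed(3)
  ft <- planted_feature_table(n_per_group = 10, n_noise = 4)
  fm <- feature_matrix(ft)
  sc <- standardize(fm$X)
  fit <- nca_fit(sc$X, fm$y, cfg = nca_config(lambda = 100))
  expect_lt(max(fit$weights), 0.05)
})

test_that("the objective is invariant to sample order and equivariant to column permutation", {
  set.seed(4)
  ft <- planted_feature_table(n_per_group = 10, n_noise = 5)
  fm <- feature_matrix(ft)
  sc <- standardize(fm$X)
  f_ref <- nca_fit(sc$X, fm$y)

  perm_rows <- sample(nrow(sc$X))
  f_rows <- nca_fit(sc$X[perm_rows, ], fm$y[perm_rows])
  expect_equal(f_rows$weights, f_ref$weights, tolerance = 1e-6)

  perm_cols <- sample(ncol(sc$X))
  f_cols <- nca_fit(sc$X[, perm_cols], fm$y)
  expect_equal(f_cols$weights, f_ref$weights[perm_cols], tolerance = 1e-6)

  # objective trace is non-decreasing at convergence
  expect_true(all(diff(f_ref$objective_trace) > -1e-9))
})

test_that("ranking and selection break ties by column order", {
  fake <- structure(list(feature_names = c("a", "b", "c"),
                         weights = c(a = 3, b = 1, c = 2),
                         ranking = order(-c(3, 1, 2), 1:3)),
                    class = "nca_result")
  expect_equal(rank_and_select(fake, 3), c("a", "c", "b"))
  expect_equal(rank_and_select(fake, 2), c("a", "c"))
  tied <- structure(list(feature_names = c("a", "b"),
                         weights = c(a = 1, b = 1),
                         ranking = order(-c(1, 1), 1:2)),
                    class = "nca_result")
  expect_equal(rank_and_select(tied, 1), "a")
  expect_error(rank_and_select(fake, 4))
})

test_that("accuracy_vs_k sweeps the subset size and finds separable structure", {
  set.seed(5)
  ft <- planted_feature_table(n_per_group = 10, n_noise = 5)
  curve <- accuracy_vs_k(ft, knn_classifier(), k_grid = c(1, 3, 6),
                         cv_cfg = cv_config(seed = 5))
  expect_equal(nrow(curve), 3)
  expect_equal(curve$accuracy[1], 1)         # the planted feature alone
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  expect_true(attr(curve, "best") %in% curve$k)
})

test_that("per-muscle weight pooling summarizes the planted muscle highest", {
  set.seed(6)
  ft <- planted_feature_table(n_per_group = 20, n_noise = 9)
  # plant the signal in a second SC column so the SC median is pulled up
  ft$VAR_SC_R <- ft$SSI_SC_L + rnorm(nrow(ft), sd = 0.2)
  fm <- feature_matrix(ft)
  sc <- standardize(fm$X)
  fit <- nca_fit(sc$X, fm$y)
  ms <- muscle_weight_summary(fit)
  expect_equal(nrow(ms), 3)
  expect_setequal(ms$muscle, c("SCM", "SC", "UT"))
  expect_equal(ms$muscle[which.max(ms$median)], "SC")

  flat <- structure(list(feature_names = c("MAV_SCM_L", "MAV_SC_L", "MAV_UT_L"),
                         weights = c(MAV_SCM_L = 1, MAV_SC_L = 1, MAV_UT_L = 1),
                         ranking = 1:3),
                    class = "nca_result")
  expect_equal(unique(muscle_weight_summary(flat)$median), 1)
})
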