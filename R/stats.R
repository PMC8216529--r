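# Group-comparison statistics: pooled-variance Student's t-test and
# Lilliefors-corrected Kolmogorov-Smirnov normality screening.

new_test_result <- function(statistic, p_value, df, means, sds, alpha,
                            method) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 means = means, sds = sds, alpha = alpha,
                 decision = p_value < alpha, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g (%s at alpha = %g)\n",
              x$method, x$statistic,
              if (is.null(x$df)) "NA" else format(x$df), x$p_value,
              if (x$decision) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test with `df = n_a + n_b - 2`.  The
#' degenerate zero-pooled-variance case is handled explicitly: equal means
#' give p = 1, unequal means p = 0.
#'
#' @param a,b Numeric samples of size >= 2 each.
#' @param alpha Significance threshold for the decision flag.
#' @return Object of class `test_result` with `statistic`, `p_value`, `df`,
#'   group `means` and `sds`, `alpha` and `decision`.
#' @export
ttest_two_sample <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  means <- c(mean(a), mean(b)); sds <- c(stats::sd(a), stats::sd(b))
  df <- length(a) + length(b) - 2
  if (all(sds == 0)) {
    p <- if (means[1] == means[2]) 1 else 0
    t <- if (means[1] == means[2]) 0 else sign(means[1] - means[2]) * Inf
    return(new_test_result(t, p, df, means, sds, alpha, "Student's t-test"))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  new_test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
                  means, sds, alpha, "Student's t-test")
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic against a normal distribution with the sample's
#' own mean and SD.  Because the parameters are estimated from the data the
#' Lilliefors correction is applied (the naive KS null would be
#' anti-conservative); p-values follow the Dallal-Wilkinson approximation
#' of `nortest::lillie.test`.
#'
#' @param sample Numeric sample, n >= 5, non-constant.
#' @param alpha Significance threshold for the decision flag.
#' @return Object of class `test_result`; `statistic` is the KS distance in
#'   `[0, 1]`.
#' @export
ks_normality <- function(sample, alpha = 0.05) {
  if (length(sample) < 5) stop("KS normality screen needs n >= 5")
  if (stats::sd(sample) == 0) stop("constant sample: normality test undefined")
  ht <- nortest::lillie.test(sample)
  new_test_result(unname(ht$statistic), ht$p.value, NULL,
                  means = mean(sample), sds = stats::sd(sample), alpha,
                  "Lilliefors (KS) normality test")
}
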