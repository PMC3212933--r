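#' @title Nonparametric validation statistics
#' @description Small wrappers with a uniform result shape around the
#'   rank-based tests used to relate marker levels and cluster labels to
#'   clinical variables: Mann-Whitney, Kruskal-Wallis, Spearman
#'   correlation, a Lilliefors-style Kolmogorov-Smirnov normality check
#'   and Pearson's chi-square. Mid-ranks are used for ties and all
#'   p-values are two-sided.
#' @name nonparam_stats
NULL

.test_result <- function(test, statistic, p_value, method, sizes,
                         estimate = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), method = method,
                 sizes = sizes, estimate = estimate),
            class = "comod_test")
}

#' @export
print.comod_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g\n", x$test, x$method,
              x$statistic, x$p_value))
  if (!is.null(x$estimate))
    cat(sprintf("  estimate = %.4g\n", x$estimate))
  invisible(x)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null distribution of the U statistic when the sample is small
#' and tie-free; tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= 25` and no
#'   ties), `"exact"` or `"asymptotic"`.
#' @return A `comod_test` with the U statistic for the first group.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  n <- length(x) + length(y)
  exact <- switch(mode,
                  auto = n <= 25L && !ties,
                  exact = TRUE,
                  asymptotic = FALSE)
  if (exact && ties) {
    warning("ties present; falling back to the asymptotic method")
    exact <- FALSE
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .test_result("mann_whitney", wt$statistic, min(1, wt$p.value),
               if (exact) "exact" else "asymptotic",
               c(length(x), length(y)))
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return A `comod_test` with the tie-corrected H statistic and its
#'   chi-square p-value on `k - 1` degrees of freedom. All observations
#'   identical gives H = 0, p = 1.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L)
    return(.test_result("kruskal_wallis", 0, 1, "asymptotic",
                        lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  .test_result("kruskal_wallis", kt$statistic, kt$p.value, "asymptotic",
               lengths(groups))
}

#' Spearman rank correlation with significance test
#'
#' Rho is the Pearson correlation of mid-ranks; the p-value is exact (by
#' permutation distribution) for `n <= 9` without ties and otherwise uses
#' the t approximation.
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @return A `comod_test` with `estimate` = rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman rho undefined")
    return(.test_result("spearman", NA_real_, NA_real_, "undefined",
                        length(x), estimate = NA_real_))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 9L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  .test_result("spearman", ct$statistic, min(1, ct$p.value),
               if (exact) "exact" else "asymptotic", length(x),
               estimate = unname(ct$estimate))
}

.ks_normal_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F0 <- stats::pnorm(z)
  max(seq_len(n) / n - F0, F0 - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' One-sample KS statistic of the data against a normal distribution
#' with the sample's own mean and standard deviation. Because the
#' parameters are estimated, the null distribution of D is simulated
#' (Lilliefors-style): `n_mc` normal samples of the same size are drawn,
#' each standardized by its own estimates, and the Monte-Carlo p-value is
#' `(1 + #{D_sim >= D}) / (n_mc + 1)`.
#'
#' @param x Numeric vector of length >= 5 with positive variance.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed Seed for the simulation.
#' @return A `comod_test` with the D statistic (in `[0, 1]`).
#' @export
ks_normality <- function(x, n_mc = 1000, seed = 1) {
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("zero variance")
  D <- .ks_normal_stat(x)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(x)
  sims <- matrix(stats::rnorm(n * n_mc), nrow = n)
  D_sim <- apply(sims, 2L, .ks_normal_stat)
  p <- (1 + sum(D_sim >= D)) / (n_mc + 1)
  .test_result("ks_normality", D, p, "monte_carlo", n)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Yates continuity correction is applied to 2x2 tables (and only those)
#' under the default `"auto"`; `"none"` gives the uncorrected statistic.
#'
#' @param table Matrix of nonnegative integer counts.
#' @param correct `"auto"`, `"none"` or `"yates"`.
#' @return A `comod_test` with the chi-square statistic; degrees of
#'   freedom `(r-1)(c-1)` are stored in `sizes`.
#' @export
chi_square <- function(table, correct = c("auto", "none", "yates")) {
  correct <- match.arg(correct)
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal row or column")
  is2x2 <- all(dim(table) == c(2L, 2L))
  yates <- switch(correct, auto = is2x2, none = FALSE, yates = TRUE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  .test_result("chi_square", ct$statistic, ct$p.value,
               if (yates) "yates" else "uncorrected",
               unname(ct$parameter))
}
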