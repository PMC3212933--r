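# Independent oracles used across the suite. These deliberately avoid the
# code paths (and, where possible, the distribution functions) they check.

# Inclusive hypergeometric upper tail P(X >= k) by direct summation of
# binomial-coefficient ratios. For N <= 30 every choose() value is an
# exactly representable integer, so the sum is accurate to ~1e-15.
oracle_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  lo <- max(k, n - (N - K))
  hi <- min(K, n)
  if (lo > hi) return(0)
  x <- lo:hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Build a one-sample discrete matrix realizing exact counts
# (N genes, K induced, R repressed; module = n genes of which k induced
# and r repressed). Returns list(D, module).
discrete_fixture <- function(N, K, n, k, R = 0, r = 0, sample = "s1") {
  stopifnot(k <= K, k <= n, K + R <= N, n <= N, r <= R, k + r <= n)
  d <- rep(0L, N)
  if (K > 0) d[seq_len(K)] <- 1L
  if (R > 0) d[K + seq_len(R)] <- -1L
  genes <- sprintf("g%03d", seq_len(N))
  module <- c(if (k > 0) genes[seq_len(k)],
              if (r > 0) genes[K + seq_len(r)],
              if (n - k - r > 0) genes[(K + R) + seq_len(n - k - r)])
  D <- matrix(d, ncol = 1, dimnames = list(genes, sample))
  list(D = D, module = module)
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# rank splits (feasible for tiny groups only).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  u_all <- apply(splits, 2, function(idx)
    sum(ranks[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Adjusted Rand index between two labelings (closed form on the
# contingency table).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(as.numeric(sij == mx))
  (sij - expected) / (mx - expected)
}

# Simulate the sample correlation of n bivariate-normal pairs with
# population correlation rho, vectorized over `reps`.
simulate_correlations <- function(reps, n, rho) {
  z1 <- matrix(rnorm(reps * n), n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(rnorm(reps * n), n)
  cz1 <- sweep(z1, 2, colMeans(z1))
  cz2 <- sweep(z2, 2, colMeans(z2))
  colSums(cz1 * cz2) / sqrt(colSums(cz1^2) * colSums(cz2^2))
}
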