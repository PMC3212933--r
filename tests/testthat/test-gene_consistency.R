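# Build a tiny cohort where the module status and per-sample fractions
# are fully controlled: each column gets K_ind induced and K_rep
# repressed genes out of N.
consistency_fixture <- function(gene_calls, K_ind, K_rep = 0, N = 20) {
  ns <- length(gene_calls)
  K_ind <- rep(K_ind, length.out = ns)
  K_rep <- rep(K_rep, length.out = ns)
  D <- matrix(0L, N, ns,
              dimnames = list(sprintf("g%02d", seq_len(N)),
                              sprintf("s%02d", seq_len(ns))))
  D[1, ] <- gene_calls                      # the gene under test is g01
  for (j in seq_len(ns)) {
    others <- setdiff(which(D[, j] == 0L), 1L)
    need_ind <- K_ind[j] - (gene_calls[j] == 1L)
    need_rep <- K_rep[j] - (gene_calls[j] == -1L)
    if (need_ind > 0) D[others[seq_len(need_ind)], j] <- 1L
    if (need_rep > 0)
      D[rev(others)[seq_len(need_rep)], j] <- -1L
  }
  D
}

test_that("the worked two-sample score and exact p-value are reproduced", {
  # two induced samples with p_i = 0.1 and 0.25 (N = 20: K_ind 2 and 5),
  # gene induced in both
  D <- consistency_fixture(c(1L, 1L), K_ind = c(2L, 5L))
  statuses <- data.frame(module = "m", sample = c("s01", "s02"),
                         status = "induced", stringsAsFactors = FALSE)
  sc <- consistency_score(D, statuses, "m", "g01")
  expect_equal(sc$score, -log(0.1) - log(0.25), tolerance = 1e-12)
  expect_equal(sc$score, 3.6889, tolerance = 1e-4)
  pv <- consistency_pvalue(sc$terms, sc$score, method = "exact")
  # only the both-match outcome reaches the observed score
  expect_equal(pv$p_value, 0.1 * 0.25, tolerance = 1e-12)
})

test_that("disagreeing and status-free samples contribute nothing", {
  D <- consistency_fixture(c(0L, 1L, -1L), K_ind = c(2L, 2L, 0L),
                           K_rep = c(0L, 0L, 4L))
  statuses <- data.frame(module = "m",
                         sample = c("s01", "s02", "s03"),
                         status = c("induced", "none", "induced"),
                         stringsAsFactors = FALSE)
  sc <- consistency_score(D, statuses, "m", "g01")
  # s01: gene 0 in induced sample; s02: no status; s03: gene repressed
  # in an induced sample (disagreement) -- all contribute 0
  expect_equal(sc$score, 0)
  expect_equal(consistency_pvalue(sc$terms, sc$score)$p_value, 1)
})

test_that("a single matching sample scores -ln(p_i)", {
  D <- consistency_fixture(c(1L, 0L), K_ind = c(2L, 2L))
  statuses <- data.frame(module = "m", sample = c("s01", "s02"),
                         status = "induced", stringsAsFactors = FALSE)
  sc <- consistency_score(D, statuses, "m", "g01")
  expect_equal(sc$score, -log(0.1), tolerance = 1e-12)
})

test_that("the exact null is a proper distribution and score is additive", {
  set.seed(31)
  q <- runif(10, 0.05, 0.4)
  terms <- data.frame(sample = paste0("s", 1:10), status = "induced",
                      q = q, w = -log(q), match = TRUE)
  # total probability over all 2^m outcomes is 1
  p0 <- consistency_pvalue(terms, 0)$p_value
  expect_equal(p0, 1)
  # P(score >= smallest positive sum) = 1 - P(nothing matches)
  eps <- consistency_pvalue(terms, min(terms$w) / 2,
                            method = "exact")$p_value
  expect_equal(eps, 1 - prod(1 - q), tolerance = 1e-12)
  # additivity over disjoint subsets
  expect_equal(sum(terms$w[1:4]) + sum(terms$w[5:10]), sum(terms$w))
})

test_that("Monte-Carlo p agrees with exact enumeration within 3 SE", {
  set.seed(32)
  for (m in c(2, 6, 12)) {
    q <- runif(m, 0.05, 0.35)
    w <- -log(q)
    terms <- data.frame(sample = paste0("s", seq_len(m)),
                        status = "induced", q = q, w = w, match = TRUE)
    obs <- sum(sort(w, decreasing = TRUE)[seq_len(ceiling(m / 2))])
    exact <- consistency_pvalue(terms, obs, method = "exact")$p_value
    mc <- consistency_pvalue(terms, obs, method = "monte_carlo",
                             n_mc = 2e4, seed = 99)
    se <- sqrt(exact * (1 - exact) / mc$n_mc)
    expect_lt(abs(mc$p_value - exact), 3 * se + 2 / mc$n_mc)
  }
})

test_that("lowering a matching sample's p_i raises score, lowers p", {
  base_q <- c(0.3, 0.2)
  mk <- function(q1) {
    q <- c(q1, base_q[2])
    data.frame(sample = c("s1", "s2"), status = "induced", q = q,
               w = -log(q), match = TRUE)
  }
  t1 <- mk(0.3); t2 <- mk(0.1)
  s1 <- sum(t1$w); s2 <- sum(t2$w)
  expect_gt(s2, s1)
  p1 <- consistency_pvalue(t1, s1, method = "exact")$p_value
  p2 <- consistency_pvalue(t2, s2, method = "exact")$p_value
  expect_lte(p2, p1)
})

test_that("null consistency p-values are super-uniform", {
  set.seed(33)
  m <- 10
  q <- runif(m, 0.05, 0.3)
  terms <- data.frame(sample = paste0("s", seq_len(m)),
                      status = "induced", q = q, w = -log(q),
                      match = TRUE)
  n_rep <- 400
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    match_draw <- runif(m) < q
    obs <- sum(terms$w[match_draw])
    pvals[r] <- consistency_pvalue(terms, obs, method = "exact")$p_value
  }
  for (alpha in c(0.01, 0.05, 0.1)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals <= alpha), alpha + tol)
  }
})

test_that("top_genes deduplicates by best p-value", {
  res <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                    module = c("a", "b", "c", "a"),
                    score = c(5, 7, 6, 1),
                    p_value = c(1e-4, 1e-6, 1e-5, 0.2),
                    stringsAsFactors = FALSE)
  tg <- top_genes(res, 1e-3)
  expect_equal(nrow(tg), 1L)
  expect_identical(tg$gene, "g1")
  expect_equal(tg$p_value, 1e-6)
  expect_equal(nrow(top_genes(res[0, ], 1e-3)), 0L)
})
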