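test_that("pairwise correlations match hand-computed values", {
  X <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),    # duplicate direction of g1
             g3 = c(4, 3, 2, 1),    # negation of g1
             g4 = c(1, 3, 2, 5))
  colnames(X) <- paste0("s", 1:4)
  pc <- pairwise_correlations(X, rownames(X), colnames(X))
  get_r <- function(a, b)
    pc$r[(pc$gene_i == a & pc$gene_j == b) |
           (pc$gene_i == b & pc$gene_j == a)]
  expect_equal(get_r("g1", "g2"), 1, tolerance = 1e-12)
  expect_equal(get_r("g1", "g3"), -1, tolerance = 1e-12)
  # direct covariance formula by hand for g1 vs g4
  x <- X["g1", ]; y <- X["g4", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(get_r("g1", "g4"), r_hand, tolerance = 1e-12)
  expect_true(all(pc$r2 == pc$r^2))
  expect_true(all(pc$n == 4L))
})

test_that("pairs below the sample floor and constant genes are omitted", {
  X <- rbind(g1 = c(1, 2, 3, NA, NA),
             g2 = c(2, 1, NA, 4, 5),
             g3 = c(5, 5, 5, 5, 5),
             g4 = c(1, 4, 2, 6, 3))
  colnames(X) <- paste0("s", 1:5)
  expect_warning(
    pc <- suppressMessages(
      pairwise_correlations(X, rownames(X), colnames(X))),
    "zero-variance")
  # g1/g2 share only 2 complete samples; g3 is constant
  expect_false(any(pc$gene_i == "g3" | pc$gene_j == "g3"))
  expect_false(any((pc$gene_i == "g1" & pc$gene_j == "g2")))
})

test_that("permutation cut-off is reproducible and monotone in quantile", {
  set.seed(41)
  X <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  c1 <- estimate_cutoff(X, rownames(X), colnames(X), B = 20, seed = 5)
  c2 <- estimate_cutoff(X, rownames(X), colnames(X), B = 20, seed = 5)
  expect_equal(as.numeric(c1), as.numeric(c2))
  # invariant to gene order
  c3 <- estimate_cutoff(X[sample(8), ], rownames(X), colnames(X),
                        B = 20, seed = 5)
  expect_equal(as.numeric(c1), as.numeric(c3))
  # monotone non-increasing in the quantile
  qs <- c(0.5, 0.9, 1.0)
  cs <- sapply(qs, function(q)
    as.numeric(estimate_cutoff(X, rownames(X), colnames(X), B = 20,
                               quantile = q, seed = 5)))
  expect_true(all(diff(cs) >= 0))
  expect_error(estimate_cutoff(X, rownames(X), colnames(X), B = 0),
               "B must be")
})

test_that("a strongly correlated planted pair survives the cut-off", {
  set.seed(42)
  n <- 40
  z <- rnorm(n)
  X <- rbind(p1 = z + rnorm(n, 0, 0.3),
             p2 = z + rnorm(n, 0, 0.3),
             matrix(rnorm(6 * n), 6, n,
                    dimnames = list(paste0("noise", 1:6), NULL)))
  colnames(X) <- paste0("s", 1:n)
  net <- relevance_network(X, rownames(X), colnames(X), B = 50, seed = 9)
  expect_true(any(net$gene_i == "p1" & net$gene_j == "p2"))
})

test_that("Fisher Z difference test matches its closed form", {
  # identity case
  fz0 <- fisher_z_diff(0.5, 30, 0.5, 12)
  expect_equal(fz0$Z, 0)
  expect_equal(fz0$p_value, 1)
  # worked example evaluated independently
  fz <- fisher_z_diff(0.9, 20, 0.3, 20)
  z_hand <- (atanh(0.9) - atanh(0.3)) / sqrt(2 / 17)
  expect_equal(fz$Z, z_hand, tolerance = 1e-12)
  expect_equal(fz$Z, 3.39, tolerance = 0.01)
  # p agrees with numerically integrating the normal density
  p_num <- 2 * integrate(dnorm, abs(z_hand), Inf,
                         rel.tol = 1e-12)$value
  expect_equal(fz$p_value, p_num, tolerance = 1e-8)
  # antisymmetry under swapping the groups
  fz_sw <- fisher_z_diff(0.3, 20, 0.9, 20)
  expect_equal(fz_sw$Z, -fz$Z)
  expect_equal(fz_sw$p_value, fz$p_value)
  expect_error(fisher_z_diff(1, 20, 0.3, 20), "infinite")
  expect_error(fisher_z_diff(0.5, 3, 0.3, 20), "n >= 4")
})

test_that("atanh of simulated correlations recovers the transform mean", {
  set.seed(43)
  rs <- simulate_correlations(2000, 12, 0.971)
  m <- mean(atanh(rs))
  se <- sd(atanh(rs)) / sqrt(length(rs))
  # Fisher transform is ~normal around atanh(rho) with small-n bias
  # below 3 SE at this sample count
  expect_lt(abs(m - atanh(0.971)), max(3 * se, 0.06))
})

test_that("differential network annotates bands and rejects overlap", {
  set.seed(44)
  n1 <- 30; n2 <- 30
  z <- rnorm(n1)
  X <- cbind(
    rbind(a = z, b = 0.99 * z + 0.14 * rnorm(n1), c = rnorm(n1)),
    rbind(a = rnorm(n2), b = rnorm(n2), c = rnorm(n2)))
  colnames(X) <- paste0("s", 1:(n1 + n2))
  g1 <- colnames(X)[1:n1]; g2 <- colnames(X)[-(1:n1)]
  edges <- differential_network(X, rownames(X), g1, g2, p_cutoff = 0.01)
  hit <- edges[edges$gene_i == "a" & edges$gene_j == "b", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$band1, "high")
  expect_error(differential_network(X, rownames(X), g1, colnames(X)),
               "share sample")
  expect_identical(comodmap:::.correlation_band(c(0.5, 0.7, 0.9, -0.9,
                                                  0.2)),
                   c("regular", "moderate", "high", "high", "none"))
})

test_that("difference matrices are symmetric with unit diagonal", {
  edges <- data.frame(gene_i = "a", gene_j = "b", r1 = 0.9, n1 = 12,
                      r2 = -0.2, n2 = 40, Z = 4, p_value = 1e-5,
                      band1 = "high", band2 = "none")
  dm <- difference_matrix(edges, c("a", "b", "c"))
  expect_equal(dm$r1, t(dm$r1))
  expect_equal(diag(dm$r1), c(a = 1, b = 1, c = 1))
  expect_equal(dm$r1["a", "b"], 0.9)
  # untested pair: zero correlation (black) and p = 1
  expect_equal(dm$r1["a", "c"], 0)
  expect_equal(dm$p["a", "c"], 1)
  expect_equal(dm$p, t(dm$p))
})
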