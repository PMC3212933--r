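test_that("discretization is inclusive at the 2-fold threshold", {
  X <- matrix(c(1.0, 0.99, -1.5, -0.99, 0, NA), nrow = 6,
              dimnames = list(paste0("g", 1:6), "s1"))
  D <- discretize(X)
  expect_identical(as.vector(D), c(1L, 0L, -1L, 0L, 0L, NA))
})

test_that("discretize(center_genes(.)) ignores per-gene constants", {
  set.seed(21)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  shift <- X + rnorm(20)  # adds a constant per gene (recycled by column)
  expect_identical(discretize(center_genes(X)),
                   discretize(center_genes(shift)))
})

test_that("per-sample module status matches the worked hypergeometric case", {
  fx <- discrete_fixture(N = 10, K = 5, n = 4, k = 4)
  st <- sample_module_status(fx$D, fx$module, "s1")
  # P(X >= 4) = C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(st$p_induced, 5 / 210, tolerance = 1e-12)
  expect_identical(st$status, "induced")
  # k = 0: upper tail is 1, never induced
  fx0 <- discrete_fixture(N = 10, K = 5, n = 4, k = 0)
  st0 <- sample_module_status(fx0$D, fx0$module, "s1")
  expect_equal(st0$p_induced, 1)
  expect_identical(st0$status, "none")
  # module = whole genome forces k = K and p = 1
  fxall <- discrete_fixture(N = 10, K = 5, n = 10, k = 5)
  expect_equal(sample_module_status(fxall$D, fxall$module, "s1")$p_induced,
               1)
})

test_that("p_induced is non-increasing in k at fixed (N, K, n)", {
  for (cfg in list(c(20, 8, 6), c(30, 15, 10), c(12, 4, 5))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    ps <- sapply(0:min(K, n), function(k) {
      fx <- discrete_fixture(N, K, n, k)
      sample_module_status(fx$D, fx$module, "s1")$p_induced
    })
    expect_true(all(diff(ps) <= 1e-14))
  }
})

test_that("module with no unmasked genes yields status none with warning", {
  D <- matrix(c(1L, NA, 0L), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  expect_warning(st <- sample_module_status(D, "g2", "s1"), "no unmasked")
  expect_identical(st$status, "none")
  expect_equal(st$p_induced, 1)
})

test_that("module_status_table agrees with the one-sample function", {
  set.seed(22)
  D <- discretize(center_genes(
    matrix(rnorm(50 * 8, sd = 0.8), 50, 8,
           dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))))
  mods <- list(a = sprintf("g%02d", 1:10), b = sprintf("g%02d", 30:45))
  tab <- module_status_table(D, mods)
  for (i in sample(nrow(tab), 10)) {
    one <- sample_module_status(D, mods[[tab$module[i]]], tab$sample[i])
    expect_equal(tab$p_induced[i], one$p_induced)
    expect_equal(tab$p_repressed[i], one$p_repressed)
    expect_identical(tab$status[i], one$status)
  }
})

make_status_df <- function(N, K_ind, K_rep = 0) {
  status <- rep("none", N)
  if (K_ind > 0) status[seq_len(K_ind)] <- "induced"
  if (K_rep > 0) status[K_ind + seq_len(K_rep)] <- "repressed"
  data.frame(module = "m", sample = sprintf("s%03d", seq_len(N)),
             status = status, stringsAsFactors = FALSE)
}

test_that("group summary reproduces the exact enrichment example", {
  st <- make_status_df(N = 60, K_ind = 10)
  # group of 8 holding 6 of the 10 induced samples
  grp <- list(g = c(sprintf("s%03d", 1:6), "s059", "s060"))
  attr(grp, "category") <- "test"
  gs <- group_module_summary(st, grp)
  expect_equal(gs$p_induced, oracle_hyper_tail(6, 60, 10, 8),
               tolerance = 1e-12)
  expect_equal(gs$f, 6 / 8)
  # no induced/repressed sample in the group -> f = 0
  grp2 <- list(g = sprintf("s%03d", 30:37))
  attr(grp2, "category") <- "test"
  expect_equal(group_module_summary(st, grp2)$f, 0)
  # group = whole cohort is degenerate: k = K, p = 1, f = 0
  grp3 <- list(g = st$sample)
  attr(grp3, "category") <- "test"
  gs3 <- group_module_summary(st, grp3)
  expect_equal(gs3$p_induced, 1)
  expect_equal(gs3$f, 0)
})

test_that("null cohorts yield ~alpha significant group calls", {
  set.seed(23)
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    K <- 12
    st <- make_status_df(60, K)
    st$status <- sample(st$status)        # random placement of statuses
    grp <- list(g1 = sample(st$sample, 20))
    grp$g2 <- sample(setdiff(st$sample, grp$g1), 20)
    attr(grp, "category") <- "null"
    gs <- group_module_summary(st, grp)
    hits <- hits + sum(gs$p_induced < 0.05)
    total <- total + nrow(gs)
  }
  rate <- hits / total
  # discrete p-values are conservative; rate must not exceed the level
  # by more than Monte-Carlo noise (2 SE at n = 400)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("module selection enforces significance and redundancy rules", {
  mods <- list(big = sprintf("g%02d", 1:10),
               twin = sprintf("g%02d", 1:10),
               other = sprintf("g%02d", 40:49))
  summ <- rbind(
    data.frame(module = "big", category = "c1", group = c("a", "b", "c"),
               f = c(0.5, 0.5, 0.4), p_value = 0.01),
    data.frame(module = "twin", category = "c1", group = c("a", "b", "c"),
               f = c(0.5, 0, 0), p_value = 0.02),
    data.frame(module = "other", category = "c1", group = c("a", "b", "c"),
               f = 0, p_value = 0.5))
  expect_identical(select_modules(summ, mods), "big")
  # nothing significant -> empty selection
  summ$f <- 0
  expect_length(select_modules(summ, mods), 0)
})

test_that("formatted module table distinguishes '---' from '0.0'", {
  summ <- data.frame(module = c("m1", "m1", "m2"),
                     category = c("c1", "c1", "c2"),
                     group = c("a", "b", "a"),
                     f = c(0.5, 0, -0.4), p_value = 0.01)
  tab <- format_module_table(summ)
  expect_identical(tab["m1", "c1:a"], "0.5")
  expect_identical(tab["m1", "c1:b"], "0.0")
  expect_identical(tab["m2", "c1:a"], "---")
  expect_identical(tab["m2", "c2:a"], "-0.4")
})
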