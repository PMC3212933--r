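#' Pairwise Pearson correlations of module genes within a sample group
#'
#' Computes the correlation of every unordered gene pair of a module over
#' the samples of one group, using for each pair only the samples where
#' both genes are unmasked. Pairs with fewer than `min_n` complete
#' samples, and pairs involving a zero-variance gene, are omitted (with a
#' message / warning).
#'
#' @param X Gene-by-sample log-ratio matrix (`NA` = missing).
#' @param module Character vector of module gene ids.
#' @param group Character vector of sample ids.
#' @param min_n Minimum number of pairwise-complete samples.
#' @return `data.frame` with columns `gene_i`, `gene_j`, `r`, `r2`, `n`.
#' @export
pairwise_correlations <- function(X, module, group, min_n = 4) {
  genes <- intersect(module, rownames(X))
  sub <- X[genes, intersect(group, colnames(X)), drop = FALSE]
  if (length(genes) < 2L)
    return(data.frame(gene_i = character(0), gene_j = character(0),
                      r = numeric(0), r2 = numeric(0), n = integer(0)))
  const <- apply(sub, 1L, function(v) stats::sd(v, na.rm = TRUE)) == 0
  const[is.na(const)] <- TRUE
  if (any(const))
    warning("zero-variance gene(s) in group, pairs omitted: ",
            paste(genes[const], collapse = ", "))
  pairs <- utils::combn(genes, 2L)
  dropped <- 0L
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    gi <- pairs[1L, p]; gj <- pairs[2L, p]
    if (const[gi] || const[gj]) next
    ok <- !is.na(sub[gi, ]) & !is.na(sub[gj, ])
    n <- sum(ok)
    if (n < min_n) { dropped <- dropped + 1L; next }
    x <- sub[gi, ok]; y <- sub[gj, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    rows[[p]] <- data.frame(gene_i = gi, gene_j = gj, r = r, r2 = r^2,
                            n = n, stringsAsFactors = FALSE)
  }
  if (dropped)
    message(dropped, " pair(s) with fewer than ", min_n,
            " complete samples omitted")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_i = character(0), gene_j = character(0),
                      r = numeric(0), r2 = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Permutation cut-off for relevance-network edges
#'
#' Estimates the squared-correlation threshold above which an edge is
#' unlikely under independence: in each of `B` rounds every gene's values
#' are independently permuted across the group's samples, all pairwise
#' squared correlations are recomputed, and the cut-off is the requested
#' quantile of the pooled permuted r-squared values (default: their
#' maximum, the classical relevance-network convention).
#'
#' @inheritParams pairwise_correlations
#' @param B Number of permutation rounds (>= 1).
#' @param quantile Quantile of the permuted r-squared distribution
#'   (default 1 = maximum).
#' @param seed Seed for the permutations.
#' @return The cut-off value `c` in `[0, 1]`, with attributes `B`,
#'   `quantile` and `seed`.
#' @export
estimate_cutoff <- function(X, module, group, B = 100, quantile = 1.0,
                            seed = 1, min_n = 4) {
  if (B < 1) stop("B must be >= 1")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  genes <- sort(intersect(module, rownames(X)))
  sub <- X[genes, intersect(group, colnames(X)), drop = FALSE]
  ns <- ncol(sub)
  r2s <- numeric(0)
  for (b in seq_len(B)) {
    perm <- t(apply(sub, 1L, function(v) v[sample.int(ns)]))
    dimnames(perm) <- dimnames(sub)
    pc <- suppressWarnings(suppressMessages(
      pairwise_correlations(perm, genes, colnames(sub), min_n = min_n)))
    r2s <- c(r2s, pc$r2)
  }
  if (!length(r2s)) stop("no permuted correlations available")
  c_val <- stats::quantile(r2s, probs = quantile, names = FALSE)
  structure(c_val, B = B, quantile = quantile, seed = seed)
}

#' Relevance network of a module within one sample group
#'
#' Edges are the gene pairs whose squared Pearson correlation exceeds the
#' permutation cut-off.
#'
#' @inheritParams estimate_cutoff
#' @param cutoff Squared-correlation cut-off; computed with
#'   [estimate_cutoff()] when `NULL`.
#' @return `data.frame` of edges (as [pairwise_correlations()]) above the
#'   cut-off, with the cut-off in attribute `cutoff`.
#' @export
relevance_network <- function(X, module, group, cutoff = NULL, B = 100,
                              quantile = 1.0, seed = 1, min_n = 4) {
  if (is.null(cutoff))
    cutoff <- estimate_cutoff(X, module, group, B = B, quantile = quantile,
                              seed = seed, min_n = min_n)
  pc <- pairwise_correlations(X, module, group, min_n = min_n)
  structure(pc[pc$r2 > as.numeric(cutoff), , drop = FALSE],
            cutoff = cutoff)
}

#' Fisher Z-test for the difference of two independent correlations
#'
#' Transforms each correlation with atanh; the difference of the
#' transforms, scaled by `sqrt(1/(n1-3) + 1/(n2-3))`, is approximately
#' standard normal under equality of the population correlations.
#'
#' @param r1,r2 Sample Pearson correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `Z` and the two-sided `p_value`. Vectorized over the
#'   arguments.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (any(n1 <= 3) || any(n2 <= 3)) stop("need n >= 4 in both groups")
  if (any(abs(r1) >= 1) || any(abs(r2) >= 1))
    stop("|r| = 1: Fisher transform infinite")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

.correlation_band <- function(r) {
  a <- abs(r)
  ifelse(a > 0.8, "high",
         ifelse(a > 0.6, "moderate",
                ifelse(a > 0.4, "regular", "none")))
}

#' Differential correlation network between two sample groups
#'
#' For every module gene pair measured with at least `min_n`
#' pairwise-complete samples in both groups, tests the difference of the
#' two group correlations with [fisher_z_diff()] and keeps pairs with
#' p-value below `p_cutoff`. Each retained edge is annotated with the
#' correlation band of each group (`none` |r| <= 0.4, `regular` up to
#' 0.6, `moderate` up to 0.8, `high` above 0.8). Pairs with |r| = 1 in
#' either group are excluded from testing and reported in attribute
#' `flagged`. Optionally, only pairs exceeding the permutation r-squared
#' cut-off in at least one group are tested.
#'
#' @inheritParams pairwise_correlations
#' @param group1,group2 Disjoint sample-id vectors.
#' @param p_cutoff P-value threshold (e.g. `0.05` to screen, `10^-4.3`
#'   to report).
#' @param apply_r2_cutoff If `TRUE`, restrict to pairs above the
#'   permutation cut-off in at least one group.
#' @param B,quantile,seed Permutation parameters when `apply_r2_cutoff`.
#' @return `data.frame` of differential edges: `gene_i`, `gene_j`, `r1`,
#'   `n1`, `r2`, `n2`, `Z`, `p_value`, `band1`, `band2`.
#' @export
differential_network <- function(X, module, group1, group2, p_cutoff = 0.05,
                                 min_n = 4, apply_r2_cutoff = FALSE,
                                 B = 100, quantile = 1.0, seed = 1) {
  if (length(intersect(group1, group2)))
    stop("groups share sample(s): ",
         paste(intersect(group1, group2), collapse = ", "))
  pc1 <- pairwise_correlations(X, module, group1, min_n = min_n)
  pc2 <- pairwise_correlations(X, module, group2, min_n = min_n)
  key1 <- paste(pc1$gene_i, pc1$gene_j)
  key2 <- paste(pc2$gene_i, pc2$gene_j)
  shared <- intersect(key1, key2)
  e <- cbind(pc1[match(shared, key1), c("gene_i", "gene_j", "r", "n")],
             pc2[match(shared, key2), c("r", "n")])
  colnames(e) <- c("gene_i", "gene_j", "r1", "n1", "r2", "n2")
  if (apply_r2_cutoff && nrow(e)) {
    c1 <- estimate_cutoff(X, module, group1, B = B, quantile = quantile,
                          seed = seed, min_n = min_n)
    c2 <- estimate_cutoff(X, module, group2, B = B, quantile = quantile,
                          seed = seed + 1, min_n = min_n)
    e <- e[e$r1^2 > as.numeric(c1) | e$r2^2 > as.numeric(c2), ,
           drop = FALSE]
  }
  perfect <- abs(e$r1) >= 1 | abs(e$r2) >= 1
  flagged <- e[perfect, , drop = FALSE]
  e <- e[!perfect, , drop = FALSE]
  if (nrow(e)) {
    fz <- fisher_z_diff(e$r1, e$n1, e$r2, e$n2)
    e$Z <- fz$Z
    e$p_value <- fz$p_value
    e$band1 <- .correlation_band(e$r1)
    e$band2 <- .correlation_band(e$r2)
    e <- e[e$p_value < p_cutoff, , drop = FALSE]
  } else {
    e$Z <- numeric(0); e$p_value <- numeric(0)
    e$band1 <- character(0); e$band2 <- character(0)
  }
  rownames(e) <- NULL
  structure(e, flagged = flagged)
}

#' Correlation and p-value matrices from a differential edge list
#'
#' Builds symmetric gene-by-gene matrices of the group correlations
#' (zero where untested, ones on the diagonal) and of the difference-test
#' p-values (one where untested).
#'
#' @param edges `data.frame` from [differential_network()] (or any table
#'   with `gene_i`, `gene_j`, `r1`, `r2`, `p_value`).
#' @param genes Ordered character vector of gene ids for the axes.
#' @return List of matrices `r1`, `r2`, `p`.
#' @export
difference_matrix <- function(edges, genes) {
  k <- length(genes)
  r1 <- r2 <- matrix(0, k, k, dimnames = list(genes, genes))
  p <- matrix(1, k, k, dimnames = list(genes, genes))
  diag(r1) <- diag(r2) <- 1
  if (nrow(edges)) {
    i <- match(edges$gene_i, genes)
    j <- match(edges$gene_j, genes)
    ok <- !is.na(i) & !is.na(j)
    i <- i[ok]; j <- j[ok]
    r1[cbind(i, j)] <- r1[cbind(j, i)] <- edges$r1[ok]
    r2[cbind(i, j)] <- r2[cbind(j, i)] <- edges$r2[ok]
    p[cbind(i, j)] <- p[cbind(j, i)] <- edges$p_value[ok]
  }
  list(r1 = r1, r2 = r2, p = p)
}

#' Render a correlation matrix on the green-black-red scale
#'
#' Green is a correlation of -1, red +1, black 0 (absence of
#' correlation), the conventional two-channel palette.
#'
#' @param R Symmetric correlation matrix in `[-1, 1]`.
#' @param main Plot title.
#' @param file Optional PNG path; when given the plot is written there.
#' @export
plot_correlation_matrix <- function(R, main = "", file = NULL) {
  pal <- grDevices::colorRampPalette(c("green", "black", "red"))(255)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  k <- nrow(R)
  graphics::image(seq_len(k), seq_len(k), t(R[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(k), colnames(R), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(R)), las = 2, cex.axis = 0.7)
  invisible(R)
}
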