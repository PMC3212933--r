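#' Self-organizing-map discrimination of samples into two groups
#'
#' Trains an online SOM on the samples (as observation vectors over the
#' selected genes) with a 1-dimensional grid of `k_units` units, a
#' Gaussian neighborhood shrinking to a single unit and a linearly
#' decaying learning rate, then assigns each sample to its best-matching
#' unit. Missing expression values are imputed to 0, the neutral value on
#' the gene-centered scale. With the default two units this splits the
#' cohort into two main groups.
#'
#' @param X Gene-by-sample matrix restricted to the discriminating genes
#'   (rows); typically the [top_genes()] list.
#' @param k_units Number of map units (default 2).
#' @param seed Seed controlling initialization and presentation order.
#' @param n_epochs Training epochs (full passes over the samples).
#' @param alpha0 Initial learning rate, decaying linearly to ~0.
#' @param sigma0 Initial neighborhood radius in grid units, decaying to
#'   0.01 (single-unit updates late in training).
#' @return List of class `comod_som`: `cluster` (named character vector
#'   with labels `A`, `B`, ... per sample), `prototypes` (units x genes)
#'   and the training parameters.
#' @export
som_cluster <- function(X, k_units = 2, seed = 1, n_epochs = 1000,
                        alpha0 = 0.5, sigma0 = 1) {
  obs <- t(X)
  obs[is.na(obs)] <- 0
  ns <- nrow(obs)
  if (ns < k_units) stop("fewer samples than map units")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  proto <- t(obs[sample.int(ns, k_units), , drop = FALSE]) # genes x units
  pos <- seq_len(k_units)
  total <- n_epochs * ns
  t_step <- 0L
  tobs <- t(obs)
  for (ep in seq_len(n_epochs)) {
    for (i in sample.int(ns)) {
      t_step <- t_step + 1L
      frac <- (t_step - 1L) / total
      alpha <- alpha0 * (1 - frac)
      sigma <- max(sigma0 * (1 - frac), 0.01)
      delta <- tobs[, i] - proto               # recycles over units
      bmu <- which.min(colSums(delta^2))
      h <- alpha * exp(-((pos - pos[bmu])^2) / (2 * sigma^2))
      for (u in pos) proto[, u] <- proto[, u] + h[u] * delta[, u]
    }
  }
  bmus <- vapply(seq_len(ns), function(i)
    which.min(colSums((tobs[, i] - proto)^2)), 1L)
  cluster <- stats::setNames(LETTERS[bmus], rownames(obs))
  structure(list(cluster = cluster, prototypes = t(proto),
                 params = list(k_units = k_units, seed = seed,
                               n_epochs = n_epochs, alpha0 = alpha0,
                               sigma0 = sigma0)),
            class = "comod_som")
}

#' @export
print.comod_som <- function(x, ...) {
  cat("SOM sample clustering:", length(x$cluster), "samples,",
      x$params$k_units, "units\n")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Hierarchical ordering of samples within SOM clusters
#'
#' Within each cluster, samples are ordered by average-linkage
#' hierarchical clustering on correlation distance (1 - Pearson r between
#' sample vectors, pairwise-complete); cluster blocks are then
#' concatenated, so the ordering never mixes clusters. A sample whose
#' correlations are undefined (constant vector) is placed last in its
#' block with a warning.
#'
#' @param X Gene-by-sample matrix (same samples as the assignment).
#' @param assignment Named cluster labels from [som_cluster()] (the
#'   `cluster` element, or the `comod_som` object itself).
#' @return Character vector: all sample ids in heatmap display order.
#' @export
order_within_clusters <- function(X, assignment) {
  if (inherits(assignment, "comod_som")) assignment <- assignment$cluster
  blocks <- split(names(assignment), assignment)
  out <- lapply(blocks, function(ids) {
    if (length(ids) <= 2L) return(ids)
    cm <- suppressWarnings(stats::cor(X[, ids, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    bad <- colnames(cm)[apply(is.na(cm), 2L, any)]
    if (length(bad)) {
      warning("sample(s) with undefined correlations placed last: ",
              paste(bad, collapse = ", "))
      good <- setdiff(ids, bad)
      if (length(good) <= 2L) return(c(good, bad))
      cm <- cm[good, good]
      hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
      return(c(good[hc$order], bad))
    }
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    ids[hc$order]
  })
  unlist(out, use.names = FALSE)
}

#' Association of SOM clusters with clinical variables
#'
#' Tests each clinical variable against the cluster labels: categorical
#' variables (subtype, T class, stage, metastasis site, vital status) by
#' chi-square on the contingency table (Yates-corrected for 2x2),
#' continuous variables (Breslow thickness, follow-up) by two-sided
#' Mann-Whitney between the two clusters. Constant variables are skipped
#' with a note. P-values are invariant to relabeling of the clusters.
#'
#' @param assignment Named cluster labels (or a `comod_som` object).
#' @param ann Validated annotation `data.frame`.
#' @return `data.frame`: one row per tested variable with `test`,
#'   `statistic`, `p_value` and per-cluster summaries.
#' @export
cluster_association <- function(assignment, ann) {
  if (inherits(assignment, "comod_som")) assignment <- assignment$cluster
  ann <- ann[match(names(assignment), ann$sample_id), , drop = FALSE]
  cl <- assignment
  categorical <- c("subtype", "t_class", "stage", "met_site",
                   "vital_status")
  continuous <- c("breslow_mm", "followup_years")
  rows <- list()
  for (v in intersect(categorical, colnames(ann))) {
    x <- ann[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L || length(unique(cl[ok])) < 2L) {
      message("variable '", v, "' constant; skipped")
      next
    }
    tab <- table(cl[ok], x[ok])
    res <- chi_square(tab)
    rows[[v]] <- data.frame(variable = v, test = "chi_square",
                            statistic = res$statistic,
                            p_value = res$p_value,
                            summary = paste(colnames(tab), collapse = "/"),
                            stringsAsFactors = FALSE)
  }
  labs <- sort(unique(cl))
  for (v in intersect(continuous, colnames(ann))) {
    x <- ann[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L || length(unique(cl[ok])) < 2L) {
      message("variable '", v, "' constant; skipped")
      next
    }
    if (length(labs) == 2L) {
      res <- mann_whitney(x[ok & cl == labs[1L]], x[ok & cl == labs[2L]])
      means <- tapply(x[ok], cl[ok], mean)
      rows[[v]] <- data.frame(variable = v, test = "mann_whitney",
                              statistic = res$statistic,
                              p_value = res$p_value,
                              summary = paste(sprintf("%s: %.2f", labs,
                                                      means[labs]),
                                              collapse = ", "),
                              stringsAsFactors = FALSE)
    } else {
      res <- kruskal_wallis(split(x[ok], cl[ok]))
      rows[[v]] <- data.frame(variable = v, test = "kruskal_wallis",
                              statistic = res$statistic,
                              p_value = res$p_value, summary = "",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an ordered expression heatmap
#'
#' Writes the matrix in display order as TSV and optionally renders a PNG
#' on the two-channel palette: red = expression above the reference,
#' green = below, black = no change.
#'
#' @param X Gene-by-sample matrix.
#' @param sample_order Display order from [order_within_clusters()].
#' @param tsv Path of the TSV export.
#' @param png Optional PNG path.
#' @param zmax Saturation of the color scale in log2 units.
#' @return The reordered matrix, invisibly.
#' @export
export_heatmap <- function(X, sample_order, tsv, png = NULL, zmax = 2) {
  Xo <- X[, sample_order, drop = FALSE]
  write_expression(Xo, tsv)
  if (!is.null(png)) {
    pal <- grDevices::colorRampPalette(c("green", "black", "red"))(255)
    grDevices::png(png, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    Z <- pmin(pmax(Xo, -zmax), zmax)
    Z[is.na(Z)] <- 0
    graphics::image(seq_len(ncol(Z)), seq_len(nrow(Z)), t(Z)[, nrow(Z):1],
                    zlim = c(-zmax, zmax), col = pal, axes = FALSE,
                    xlab = "samples", ylab = "genes")
  }
  invisible(Xo)
}
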