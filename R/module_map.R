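#' Discretize centered expression into induction / repression calls
#'
#' A gene in a sample is called induced (+1) when its centered log2 ratio
#' is at least `log2_threshold` above the gene's average (i.e. at least
#' 2-fold for the default threshold of 1), repressed (-1) when at least
#' that far below, and 0 otherwise. The comparison is inclusive at the
#' threshold. Missing entries stay missing.
#'
#' @param X Gene-centered numeric matrix on the log2 scale (see
#'   [center_genes()]).
#' @param log2_threshold Fold-change threshold in log2 units (default 1 =
#'   2-fold).
#' @return Integer matrix with values in `{-1, 0, 1, NA}`.
#' @export
discretize <- function(X, log2_threshold = 1.0) {
  D <- array(0L, dim = dim(X), dimnames = dimnames(X))
  D[X >= log2_threshold] <- 1L
  D[X <= -log2_threshold] <- -1L
  D[is.na(X)] <- NA_integer_
  D
}

.hyper_upper_tail <- function(k, N, K, n) {
  # inclusive upper tail P(X >= k), X ~ Hypergeometric(N, K, n)
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Module status of one sample by hypergeometric enrichment
#'
#' Counts induced and repressed genes of a module within one sample and
#' tests whether either count is larger than expected by chance given the
#' sample's genome-wide counts. With N unmasked genes in the sample, K of
#' them induced, n unmasked module genes and k induced module genes, the
#' induction p-value is the inclusive hypergeometric upper tail
#' P(X >= k); repression analogously. The module is called `induced` or
#' `repressed` when the corresponding p-value is below `alpha` (ties
#' between directions broken by the smaller p-value), else `none`.
#'
#' @param D Discretized matrix from [discretize()].
#' @param module Character vector of module gene ids.
#' @param sample Sample (column) identifier.
#' @param alpha Per-sample significance level.
#' @return A one-row `data.frame` with `status`, `p_induced`,
#'   `p_repressed` and the counts `N`, `K_ind`, `K_rep`, `n`, `k_ind`,
#'   `k_rep`.
#' @export
sample_module_status <- function(D, module, sample, alpha = 0.05) {
  d <- D[, sample]
  obs <- !is.na(d)
  N <- sum(obs)
  K_ind <- sum(d == 1L, na.rm = TRUE)
  K_rep <- sum(d == -1L, na.rm = TRUE)
  in_mod <- rownames(D) %in% module & obs
  n <- sum(in_mod)
  k_ind <- sum(d[in_mod] == 1L)
  k_rep <- sum(d[in_mod] == -1L)
  if (n == 0L) {
    warning("module has no unmasked gene in sample ", sample)
    p_i <- p_r <- 1
  } else {
    p_i <- .hyper_upper_tail(k_ind, N, K_ind, n)
    p_r <- .hyper_upper_tail(k_rep, N, K_rep, n)
  }
  status <- "none"
  if (p_i < alpha && (p_i <= p_r || p_r >= alpha)) status <- "induced"
  else if (p_r < alpha) status <- "repressed"
  data.frame(sample = sample, status = status, p_induced = p_i,
             p_repressed = p_r, N = N, K_ind = K_ind, K_rep = K_rep,
             n = n, k_ind = k_ind, k_rep = k_rep,
             stringsAsFactors = FALSE)
}

#' Module status for every (module, sample) pair
#'
#' @param D Discretized matrix from [discretize()].
#' @param modules Named list of gene-id vectors (see [read_modules_gmt()]).
#' @param alpha Per-sample significance level.
#' @return A `data.frame` with one row per (module, sample), columns as in
#'   [sample_module_status()] plus `module`.
#' @export
module_status_table <- function(D, modules, alpha = 0.05) {
  obs <- !is.na(D)
  N <- colSums(obs)
  K_ind <- colSums(D == 1L, na.rm = TRUE)
  K_rep <- colSums(D == -1L, na.rm = TRUE)
  res <- lapply(names(modules), function(mod) {
    rows <- rownames(D) %in% modules[[mod]]
    n <- colSums(obs[rows, , drop = FALSE])
    k_ind <- colSums(D[rows, , drop = FALSE] == 1L, na.rm = TRUE)
    k_rep <- colSums(D[rows, , drop = FALSE] == -1L, na.rm = TRUE)
    p_i <- ifelse(n == 0L, 1, ifelse(
      k_ind == 0L, 1,
      stats::phyper(k_ind - 1, K_ind, N - K_ind, n, lower.tail = FALSE)))
    p_r <- ifelse(n == 0L, 1, ifelse(
      k_rep == 0L, 1,
      stats::phyper(k_rep - 1, K_rep, N - K_rep, n, lower.tail = FALSE)))
    status <- rep("none", ncol(D))
    status[p_i < alpha & (p_i <= p_r | p_r >= alpha)] <- "induced"
    status[p_r < alpha & status == "none"] <- "repressed"
    data.frame(module = mod, sample = colnames(D), status = status,
               p_induced = p_i, p_repressed = p_r, N = N, K_ind = K_ind,
               K_rep = K_rep, n = n, k_ind = k_ind, k_rep = k_rep,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Group-level module classification across a clinical partition
#'
#' For each module and sample group, tests whether the group is enriched
#' in samples where the module is induced (and, separately, repressed),
#' again with inclusive hypergeometric upper tails: N = cohort size, K =
#' samples with the module induced cohort-wide, n = group size, k =
#' induced samples inside the group. A significant direction is reported
#' as a signed fraction f: `+k_ind/n` for induction, `-k_rep/n` for
#' repression (the smaller p-value wins when both directions are
#' significant), and 0 when neither direction reaches `alpha`.
#'
#' @param statuses Output of [module_status_table()] for the whole cohort.
#' @param partition Named list of sample-id groups from
#'   [build_partition()].
#' @param alpha Group-level significance level.
#' @return A `data.frame` with one row per (module, group): `f`,
#'   `p_induced`, `p_repressed`, `p_value` (the winning direction's
#'   p-value, or the smaller one when not significant) and counts.
#' @export
group_module_summary <- function(statuses, partition, alpha = 0.05) {
  category <- attr(partition, "category")
  if (is.null(category)) category <- "custom"
  empty <- !vapply(partition, length, 1L)
  if (any(empty)) {
    warning("skipping empty group(s): ",
            paste(names(partition)[empty], collapse = ", "))
    partition <- partition[!empty]
  }
  cohort <- unique(statuses$sample)
  N <- length(cohort)
  res <- lapply(split(statuses, statuses$module), function(st) {
    K_ind <- sum(st$status == "induced")
    K_rep <- sum(st$status == "repressed")
    rows <- lapply(names(partition), function(grp) {
      ids <- partition[[grp]]
      n <- length(ids)
      k_ind <- sum(st$status == "induced" & st$sample %in% ids)
      k_rep <- sum(st$status == "repressed" & st$sample %in% ids)
      p_i <- .hyper_upper_tail(k_ind, N, K_ind, n)
      p_r <- .hyper_upper_tail(k_rep, N, K_rep, n)
      f <- 0
      if (p_i < alpha && (p_i <= p_r || p_r >= alpha)) f <- k_ind / n
      else if (p_r < alpha) f <- -k_rep / n
      data.frame(module = st$module[1L], category = category, group = grp,
                 f = f, p_induced = p_i, p_repressed = p_r,
                 p_value = min(p_i, p_r), N = N, K_ind = K_ind,
                 K_rep = K_rep, n = n, k_ind = k_ind, k_rep = k_rep,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Select significantly altered, non-redundant modules
#'
#' Keeps modules whose signed fraction is non-zero in at least
#' `min_significant_groups` groups over the supplied summaries (typically
#' concatenated over all clinical categories), then removes redundancy:
#' among any pair of modules whose gene sets have Jaccard similarity at
#' least `redundancy_jaccard`, the module significant in more groups wins
#' (ties broken by the smaller best p-value).
#'
#' @param summary `data.frame` from [group_module_summary()], possibly
#'   rbind-ed over categories.
#' @param modules Named list of module gene sets (for the redundancy
#'   test).
#' @param min_significant_groups Minimum number of significant groups.
#' @param redundancy_jaccard Jaccard threshold above which two modules
#'   are considered redundant.
#' @return Character vector of retained module names.
#' @export
select_modules <- function(summary, modules, min_significant_groups = 1,
                           redundancy_jaccard = 0.8) {
  sig <- tapply(summary$f != 0, summary$module, sum)
  best_p <- tapply(summary$p_value, summary$module, min)
  keep <- names(sig)[sig >= min_significant_groups]
  if (!length(keep)) return(character(0))
  # order so that better modules are considered first
  keep <- keep[order(-sig[keep], best_p[keep])]
  retained <- character(0)
  for (mod in keep) {
    redundant <- FALSE
    for (r in retained) {
      a <- modules[[mod]]; b <- modules[[r]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= redundancy_jaccard) { redundant <- TRUE; break }
    }
    if (!redundant) retained <- c(retained, mod)
  }
  retained
}

#' Render group summaries as a module-by-group table of signed fractions
#'
#' One row per module, one column per (category, group). Cells of
#' (module, category) pairs absent from `summary` are rendered as `"---"`
#' (not evaluated), evaluated but non-significant cells as `"0.0"`,
#' matching the two distinct null marks of module-map summary tables.
#'
#' @param summary Combined `data.frame` of [group_module_summary()] rows
#'   over one or more categories.
#' @param digits Number of decimal places for the fractions.
#' @return Character matrix (modules x groups) ready for export.
#' @export
format_module_table <- function(summary, digits = 1) {
  mods <- unique(summary$module)
  cols <- unique(paste(summary$category, summary$group, sep = ":"))
  out <- matrix("---", length(mods), length(cols),
                dimnames = list(mods, cols))
  key <- paste(summary$category, summary$group, sep = ":")
  out[cbind(match(summary$module, mods), match(key, cols))] <-
    formatC(round(summary$f, digits), format = "f", digits = digits)
  out
}
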