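#' Remove spots whose signal does not exceed background
#'
#' A spot is excluded when the foreground intensity is lower than or equal
#' to the local background in either channel; such spots carry no usable
#' ratio information.
#'
#' @param spots Spot table: a `data.frame` with columns `spot_id`,
#'   `gene_id`, `ch1_fg`, `ch1_bg`, `ch2_fg`, `ch2_bg` and optionally
#'   `dye_orientation` (`"forward"` or `"swapped"`).
#' @return The filtered spot table; the number of removed spots is
#'   reported with a message.
#' @export
background_filter <- function(spots) {
  .check_spot_table(spots)
  bad <- spots$ch1_fg <= spots$ch1_bg | spots$ch2_fg <= spots$ch2_bg
  if (any(bad))
    message(sum(bad), " spot(s) with signal <= background removed")
  spots[!bad, , drop = FALSE]
}

.check_spot_table <- function(spots) {
  need <- c("spot_id", "gene_id", "ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")
  miss <- setdiff(need, colnames(spots))
  if (length(miss))
    stop("spot table lacks column(s): ", paste(miss, collapse = ", "))
  ints <- as.matrix(spots[, need[-(1:2)]])
  if (any(ints < 0, na.rm = TRUE)) stop("negative intensities in spot table")
  invisible(spots)
}

#' Compute M (log-ratio) and A (mean log-intensity) for filtered spots
#'
#' Intensities are background-subtracted before the log2 transform, with a
#' small positive floor so that near-zero differences after subtraction do
#' not produce infinite ratios.
#'
#' @inheritParams background_filter
#' @param floor Minimum background-subtracted intensity before log2.
#' @return The spot table with columns `M` and `A` appended.
#' @export
spot_ma <- function(spots, floor = 0.5) {
  .check_spot_table(spots)
  s1 <- pmax(spots$ch1_fg - spots$ch1_bg, floor)
  s2 <- pmax(spots$ch2_fg - spots$ch2_bg, floor)
  spots$M <- log2(s1) - log2(s2)
  spots$A <- (log2(s1) + log2(s2)) / 2
  spots
}

#' LOWESS normalization of intensity-dependent dye bias
#'
#' Fits a locally weighted polynomial regression of M on A (tricube
#' weights, 3 robustness iterations) and subtracts the fitted trend, so
#' that the normalized log-ratio is centred on zero at every intensity.
#' Degree 1 uses [stats::lowess()]; degree 2 uses a robust
#' [stats::loess()] fit.
#'
#' @param spots Spot table carrying `M` and `A` columns (see [spot_ma()]);
#'   a raw spot table is accepted and converted.
#' @param span LOWESS span (fraction of spots in each local window).
#' @param degree Local polynomial degree, 1 or 2.
#' @return The spot table with `M` replaced by the normalized value and
#'   the raw log-ratio kept in `M_raw`.
#' @export
lowess_normalize <- function(spots, span = 0.4, degree = 1) {
  if (!all(c("M", "A") %in% colnames(spots))) spots <- spot_ma(spots)
  ok <- is.finite(spots$M) & is.finite(spots$A)
  if (sum(ok) < 10L)
    stop("fewer than 10 usable spots; LOWESS fit underdetermined")
  if (degree == 1) {
    fit <- stats::lowess(spots$A[ok], spots$M[ok], f = span, iter = 3)
    trend <- stats::approx(fit$x, fit$y, xout = spots$A, rule = 2,
                           ties = mean)$y
  } else if (degree == 2) {
    lo <- stats::loess(M ~ A, data = spots[ok, ], span = span, degree = 2,
                       family = "symmetric")
    trend <- stats::predict(lo, newdata = spots)
  } else stop("degree must be 1 or 2")
  spots$M_raw <- spots$M
  spots$M <- spots$M - trend
  spots
}

#' Summarize normalized spots to one log-ratio per gene
#'
#' Replicate spots of the same gene on one hybridization are averaged.
#'
#' @param spots Normalized spot table with columns `gene_id` and `M`.
#' @return Named numeric vector of per-gene log2 ratios.
#' @export
gene_ratios <- function(spots) {
  tapply(spots$M, spots$gene_id, mean, na.rm = TRUE)
}

#' Merge dye-swap replicate hybridizations
#'
#' The swapped hybridization measures the negated log-ratio, so the merged
#' value per gene is `(M_fwd - M_swp) / 2`. A gene measured in only one
#' orientation keeps that single value; a gene measured in neither is
#' `NA`.
#'
#' @param fwd,swp Named numeric vectors of per-gene normalized log2
#'   ratios from the forward and dye-swapped hybridizations.
#' @return Named numeric vector over the union of gene names.
#' @export
merge_dye_swap <- function(fwd, swp) {
  genes <- union(names(fwd), names(swp))
  f <- fwd[match(genes, names(fwd))]
  s <- -swp[match(genes, names(swp))]
  merged <- rowMeans(cbind(f, s), na.rm = TRUE)
  merged[is.nan(merged)] <- NA_real_
  stats::setNames(merged, genes)
}

#' Replicate agreement between dye-swap hybridizations
#'
#' Pearson correlation between the forward log-ratios and the negated
#' swapped log-ratios over genes measured in both, as a replicate QC
#' metric (a good dye-swap pair correlates near 1).
#'
#' @inheritParams merge_dye_swap
#' @return Pearson correlation coefficient; `NA` with a warning when
#'   either vector is constant over the shared genes.
#' @export
replicate_correlation <- function(fwd, swp) {
  genes <- intersect(names(fwd), names(swp))
  f <- fwd[genes]
  s <- -swp[genes]
  ok <- is.finite(f) & is.finite(s)
  if (sum(ok) < 3L) stop("fewer than 3 shared unmasked genes")
  if (stats::sd(f[ok]) == 0 || stats::sd(s[ok]) == 0) {
    warning("constant replicate vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(f[ok], s[ok])
}

#' Center each gene to mean zero across samples
#'
#' Subtracts the gene-wise mean computed over unmasked (non-`NA`) entries,
#' the standardization step preceding expression discretization. Missing
#' entries are preserved. A gene with every entry missing is left fully
#' masked with a warning.
#'
#' @param X Numeric gene-by-sample matrix (`NA` = missing).
#' @return Matrix of the same shape with every gene row at mean zero over
#'   its observed entries.
#' @export
center_genes <- function(X) {
  all_na <- rowSums(!is.na(X)) == 0L
  if (any(all_na))
    warning(sum(all_na), " gene(s) fully masked; left unchanged")
  mu <- rowMeans(X, na.rm = TRUE)
  mu[all_na] <- 0
  X - mu
}
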