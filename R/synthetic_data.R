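#' Generate a synthetic melanoma-style expression cohort with planted
#' structure
#'
#' Emulates the statistical structure the module-map pipeline assumes: a
#' cohort of primary (PCM) and metastatic (MM) tumors measured as
#' gene-wise log2 ratios, with designated modules induced or repressed in
#' target clinical groups, designated gene pairs correlated only within a
#' target group, and a known missing-entry mask. Baseline values are
#' independent Normal(0, `noise_sd`); a planted module shifts its genes
#' by `effect` log2 units (sign by direction) in the target samples; a
#' planted pair is drawn from a latent bivariate normal with the target
#' correlation inside its group and independent noise elsewhere. The
#' answer key for every planted element is returned as `truth`.
#'
#' @param n_genes Number of genes on the simulated platform.
#' @param n_pcm,n_mm Number of primary and metastatic samples (defaults
#'   20 and 40, a 60-sample cohort).
#' @param planted_modules List of planted modules; each a list with
#'   `name`, `size` (or explicit `genes`), `target` (`"PCM"`, `"MM"` or a
#'   vector of sample ids), `effect` (log2 shift, >= 1 corresponds to a
#'   2-fold change) and `direction` (`"induced"` or `"repressed"`).
#' @param planted_pairs List of planted correlated pairs; each a list
#'   with `genes` (length-2 vector, or omitted for auto-assignment),
#'   `target` as above and `rho` (|rho| < 1).
#' @param noise_sd Baseline standard deviation in log2 units.
#' @param missing_rate Fraction of entries masked at random.
#' @param n_decoy_modules,decoy_size Unplanted modules of background
#'   genes added to the module collection, so that selection has
#'   negatives to reject.
#' @param seed Seed; the generator is a pure function of its arguments
#'   and the seed.
#' @return List: `expr` (matrix), `annotations` (`data.frame`),
#'   `modules` (named list), `truth` (answer key).
#' @export
generate_cohort <- function(n_genes = 500, n_pcm = 20, n_mm = 40,
                            planted_modules = list(),
                            planted_pairs = list(),
                            noise_sd = 0.5, missing_rate = 0,
                            n_decoy_modules = 10, decoy_size = 15,
                            seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  ns <- n_pcm + n_mm
  samples <- sprintf("S%03d", seq_len(ns))
  genes <- sprintf("G%04d", seq_len(n_genes))
  subtype <- rep(c("PCM", "MM"), c(n_pcm, n_mm))
  ann <- .simulate_annotations(samples, subtype)

  resolve_target <- function(target) {
    if (all(target %in% c("PCM", "MM"))) samples[subtype %in% target]
    else {
      if (!all(target %in% samples)) stop("unknown target sample id(s)")
      target
    }
  }

  X <- matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns,
              dimnames = list(genes, samples))
  free <- genes
  truth_modules <- list()
  for (i in seq_along(planted_modules)) {
    pm <- planted_modules[[i]]
    if (is.null(pm$genes)) {
      pm$genes <- free[seq_len(pm$size)]
    }
    free <- setdiff(free, pm$genes)
    tgt <- resolve_target(pm$target)
    sgn <- if (identical(pm$direction, "repressed")) -1 else 1
    X[pm$genes, tgt] <- X[pm$genes, tgt] + sgn * pm$effect
    if (is.null(pm$name)) pm$name <- sprintf("planted_module_%d", i)
    truth_modules[[pm$name]] <- list(genes = pm$genes,
                                     target = pm$target,
                                     effect = pm$effect,
                                     direction = if (sgn > 0) "induced"
                                     else "repressed")
  }
  planted_mod_genes <- unlist(lapply(truth_modules, `[[`, "genes"))
  truth_pairs <- list()
  for (i in seq_along(planted_pairs)) {
    pp <- planted_pairs[[i]]
    if (is.null(pp$genes)) {
      pp$genes <- free[1:2]
    }
    if (any(pp$genes %in% planted_mod_genes))
      stop("planted pair overlaps a planted module: conflicting covariance")
    free <- setdiff(free, pp$genes)
    tgt <- resolve_target(pp$target)
    k <- length(tgt)
    z1 <- stats::rnorm(k)
    z2 <- pp$rho * z1 + sqrt(1 - pp$rho^2) * stats::rnorm(k)
    X[pp$genes[1L], tgt] <- noise_sd * z1
    X[pp$genes[2L], tgt] <- noise_sd * z2
    truth_pairs[[i]] <- list(genes = pp$genes, target = pp$target,
                             rho = pp$rho)
  }

  modules <- lapply(truth_modules, `[[`, "genes")
  for (d in seq_len(n_decoy_modules)) {
    modules[[sprintf("decoy_module_%02d", d)]] <-
      sample(free, min(decoy_size, length(free)))
  }
  attr(modules, "source") <-
    stats::setNames(c(rep("planted", length(truth_modules)),
                      rep("decoy", n_decoy_modules)), names(modules))

  if (missing_rate > 0) {
    mask <- stats::runif(length(X)) < missing_rate
    X[mask] <- NA_real_
  }
  list(expr = X, annotations = ann, modules = modules,
       truth = list(modules = truth_modules, pairs = truth_pairs,
                    noise_sd = noise_sd, missing_rate = missing_rate,
                    seed = seed))
}

.simulate_annotations <- function(samples, subtype) {
  n <- length(samples)
  pcm <- subtype == "PCM"
  breslow <- rep(NA_real_, n)
  # vertical-growth-phase primaries: intermediate-to-thick Breslow depths
  breslow[pcm] <- round(stats::rlnorm(sum(pcm), log(3), 0.8), 2)
  t_class <- rep(NA_character_, n)
  t_class[pcm] <- as.character(.t_class_from_breslow(breslow[pcm]))
  stage <- ifelse(pcm,
                  ifelse(breslow <= 2, "I", "II"),
                  sample(c("III", "IV"), n, TRUE, prob = c(0.4, 0.6)))
  met_site <- rep(NA_character_, n)
  met_site[!pcm] <- sample(c("LN", "CUT", "VISC"), sum(!pcm), TRUE,
                           prob = c(0.45, 0.3, 0.25))
  vital <- sample(c("alive", "dead_melanoma", "dead_other"), n, TRUE,
                  prob = c(0.45, 0.48, 0.07))
  followup <- round(ifelse(vital == "alive", stats::runif(n, 0.5, 10),
                           stats::runif(n, 0.2, 8)), 2)
  data.frame(sample_id = samples, subtype = subtype,
             breslow_mm = breslow, t_class = t_class, stage = stage,
             met_site = met_site, vital_status = vital,
             followup_years = followup, stringsAsFactors = FALSE)
}

#' Generate a raw two-channel spot table with intensity-dependent dye
#' bias
#'
#' Back-computes foreground/background channel intensities from true
#' log2 ratios, a chosen dye-bias curve over mean log-intensity A, and
#' additive noise on the log scale, so that the full preprocessing path
#' (background filter, M/A computation, LOWESS) can be validated against
#' an answer key. A stated fraction of spots is generated with
#' foreground <= background in channel 1 to exercise the filter.
#'
#' @param n_spots Number of spots.
#' @param bias Bias shape over A: `"constant"`, `"linear"` (proportional
#'   to centered A) or `"curved"` (quadratic in centered A).
#' @param bias_magnitude Bias scale in log2 units.
#' @param true_m_sd Standard deviation of the true log2 ratios.
#' @param noise_sd Additive log2 measurement noise.
#' @param frac_below_bg Fraction of spots planted with signal <=
#'   background.
#' @param seed Seed.
#' @return List: `spots` (a spot table `data.frame` with
#'   `dye_orientation = "forward"`), `truth` (`data.frame` with
#'   `spot_id`, `true_M`, `A`, `bias`, `below_bg`).
#' @export
generate_spot_table <- function(n_spots = 2000,
                                bias = c("constant", "linear", "curved"),
                                bias_magnitude = 0.7, true_m_sd = 0.3,
                                noise_sd = 0.1, frac_below_bg = 0,
                                seed = 1) {
  bias <- match.arg(bias)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  A <- stats::runif(n_spots, 6, 14)
  Ac <- A - mean(A)
  b <- switch(bias,
              constant = rep(bias_magnitude, n_spots),
              linear = bias_magnitude * Ac,
              curved = bias_magnitude * (Ac / stats::sd(A))^2 / 2)
  true_M <- stats::rnorm(n_spots, 0, true_m_sd)
  M_obs <- true_M + b + stats::rnorm(n_spots, 0, noise_sd)
  bg1 <- stats::rgamma(n_spots, shape = 20, rate = 0.4)
  bg2 <- stats::rgamma(n_spots, shape = 20, rate = 0.4)
  fg1 <- 2^(A + M_obs / 2) + bg1
  fg2 <- 2^(A - M_obs / 2) + bg2
  below <- rep(FALSE, n_spots)
  if (frac_below_bg > 0) {
    idx <- sample.int(n_spots, round(frac_below_bg * n_spots))
    fg1[idx] <- bg1[idx] * stats::runif(length(idx), 0.2, 1)
    below[idx] <- TRUE
  }
  ids <- sprintf("SP%05d", seq_len(n_spots))
  spots <- data.frame(spot_id = ids,
                      gene_id = sprintf("G%05d", seq_len(n_spots)),
                      ch1_fg = fg1, ch1_bg = bg1, ch2_fg = fg2,
                      ch2_bg = bg2, dye_orientation = "forward",
                      stringsAsFactors = FALSE)
  truth <- data.frame(spot_id = ids, true_M = true_M, A = A, bias = b,
                      below_bg = below, stringsAsFactors = FALSE)
  list(spots = spots, truth = truth)
}

#' Generate paired nonnegative protein-score vectors with a target rank
#' correlation
#'
#' Draws a bivariate standard normal with the target correlation and
#' pushes each margin through a Gaussian copula onto a right-skewed
#' nonnegative gamma scale, emulating immunohistochemistry intensity
#' scores. Because rank correlation is invariant to the monotone margin
#' transform, the empirical Spearman rho concentrates near the target.
#'
#' @param n Number of pairs.
#' @param target_rho Target correlation of the latent normal
#'   (|target_rho| < 1).
#' @param seed Seed.
#' @param shape,rate Gamma margin parameters.
#' @return A `data.frame` with columns `marker1`, `marker2`.
#' @export
generate_tma_scores <- function(n, target_rho, seed = 1, shape = 2,
                                rate = 0.5) {
  if (abs(target_rho) >= 1) stop("|target_rho| must be < 1")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- target_rho * z1 + sqrt(1 - target_rho^2) * stats::rnorm(n)
  data.frame(marker1 = stats::qgamma(stats::pnorm(z1), shape, rate),
             marker2 = stats::qgamma(stats::pnorm(z2), shape, rate))
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Expression as TSV, annotations as CSV, modules as GMT and the ground
#' truth as JSON (when the jsonlite package is available).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  write_modules_gmt(cohort$modules, file.path(dir, "modules.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
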