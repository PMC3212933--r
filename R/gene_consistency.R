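#' Per-sample induction and repression fractions
#'
#' For each sample, the fraction of unmasked genes called induced
#' (`p_i`) and repressed (`p_r`). These fractions are both the per-sample
#' weights of the consistency score and the match probabilities of its
#' Bernoulli-sum null.
#'
#' @param D Discretized matrix from [discretize()].
#' @return `data.frame` with columns `sample`, `p_i`, `p_r`.
#' @export
sample_weights <- function(D) {
  obs <- colSums(!is.na(D))
  data.frame(sample = colnames(D),
             p_i = colSums(D == 1L, na.rm = TRUE) / obs,
             p_r = colSums(D == -1L, na.rm = TRUE) / obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

.consistency_terms <- function(D, statuses, module, gene) {
  # one row per status-bearing sample: null match probability q and
  # weight w = -ln(q); `match` marks samples where the gene agrees
  st <- statuses[statuses$module == module & statuses$status != "none", ,
                 drop = FALSE]
  if (!nrow(st))
    return(data.frame(sample = character(0), status = character(0),
                      q = numeric(0), w = numeric(0), match = logical(0)))
  sw <- sample_weights(D)
  q <- ifelse(st$status == "induced",
              sw$p_i[match(st$sample, sw$sample)],
              sw$p_r[match(st$sample, sw$sample)])
  d <- D[gene, st$sample]
  match_dir <- ifelse(st$status == "induced", 1L, -1L)
  matched <- !is.na(d) & d == match_dir
  if (any(matched & q <= 0))
    stop("zero match probability in a sample where the gene matches")
  data.frame(sample = st$sample, status = st$status, q = q, w = -log(q),
             match = matched, row.names = NULL, stringsAsFactors = FALSE)
}

#' Consistency score of a gene with its module's status
#'
#' Sums, over samples where the module is induced and the gene itself is
#' induced, the weight `-ln(p_i)` of that sample, plus the analogous
#' `-ln(p_r)` terms over repressed samples where the gene is repressed.
#' Samples where the module has no status, or where the gene disagrees,
#' contribute zero. Weights use the natural log; the log base rescales
#' scores uniformly and leaves p-values unchanged.
#'
#' @param D Discretized matrix from [discretize()].
#' @param statuses [module_status_table()] output covering `module`.
#' @param module Module name.
#' @param gene Gene id (must belong to the module).
#' @return List with `score` (non-negative, in nats) and `terms`, the
#'   per-sample weight table used (columns `sample`, `status`, `q`, `w`,
#'   `match`).
#' @export
consistency_score <- function(D, statuses, module, gene) {
  terms <- .consistency_terms(D, statuses, module, gene)
  list(score = sum(terms$w[terms$match]), terms = terms)
}

#' P-value of a consistency score under the Bernoulli-sum null
#'
#' Under the null, each status-bearing sample independently contributes
#' its weight with the sample's own match probability (`p_i` for induced
#' samples, `p_r` for repressed) and zero otherwise; the p-value is the
#' probability that this random sum reaches the observed score. The exact
#' method enumerates all 2^m outcomes (feasible for m <= 20 samples);
#' otherwise a seeded Monte-Carlo estimate with `n_mc` draws is used.
#'
#' @param terms Weight table as produced by [consistency_score()]:
#'   columns `q` (match probability) and `w` (weight) over status-bearing
#'   samples.
#' @param observed Observed score.
#' @param method `"auto"` (exact when m <= `exact_limit`), `"exact"` or
#'   `"monte_carlo"`.
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Seed for the Monte-Carlo draw (required for that method).
#' @param exact_limit Largest m enumerated exactly under `"auto"`.
#' @return List with `p_value`, `method` used, and `n_mc`/`seed` when
#'   Monte-Carlo.
#' @export
consistency_pvalue <- function(terms, observed, method = "auto",
                               n_mc = 1e5, seed = NULL, exact_limit = 20) {
  m <- nrow(terms)
  if (m == 0L || observed <= 0)
    return(list(p_value = 1, method = "exact"))
  method <- match.arg(method, c("auto", "exact", "monte_carlo"))
  if (method == "auto")
    method <- if (m <= exact_limit) "exact" else "monte_carlo"
  tol <- 1e-9
  if (method == "exact") {
    if (m > 22L) stop("exact enumeration infeasible for m = ", m)
    sums <- 0
    probs <- 1
    for (j in seq_len(m)) {
      sums <- c(sums, sums + terms$w[j])
      probs <- c(probs * (1 - terms$q[j]), probs * terms$q[j])
    }
    list(p_value = min(1, sum(probs[sums >= observed - tol])),
         method = "exact")
  } else {
    if (is.null(seed)) stop("Monte-Carlo method requires a seed")
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    hits <- 0L
    chunk <- 1e4L
    done <- 0L
    while (done < n_mc) {
      nb <- min(chunk, n_mc - done)
      draws <- matrix(stats::runif(nb * m) < rep(terms$q, each = nb),
                      nrow = nb)
      null_scores <- drop(draws %*% terms$w)
      hits <- hits + sum(null_scores >= observed - tol)
      done <- done + nb
    }
    list(p_value = (hits + 1) / (n_mc + 1), method = "monte_carlo",
         n_mc = n_mc, seed = seed)
  }
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Consistency scores and p-values for every gene of given modules
#'
#' @param D Discretized matrix from [discretize()].
#' @param statuses [module_status_table()] output.
#' @param modules Named list of module gene sets; restricted to the
#'   modules named in `statuses`.
#' @param method,n_mc,seed Passed to [consistency_pvalue()] (the seed is
#'   advanced per gene so draws are independent but reproducible).
#' @return `data.frame` with columns `gene`, `module`, `score`,
#'   `p_value`, `method`.
#' @export
consistency_table <- function(D, statuses, modules, method = "auto",
                              n_mc = 1e5, seed = 1) {
  rows <- list()
  i <- 0L
  for (mod in intersect(names(modules), unique(statuses$module))) {
    genes <- intersect(modules[[mod]], rownames(D))
    for (g in genes) {
      i <- i + 1L
      sc <- consistency_score(D, statuses, mod, g)
      pv <- consistency_pvalue(sc$terms, sc$score, method = method,
                               n_mc = n_mc, seed = seed + i)
      rows[[i]] <- data.frame(gene = g, module = mod, score = sc$score,
                              p_value = pv$p_value, method = pv$method,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), module = character(0),
                      score = numeric(0), p_value = numeric(0),
                      method = character(0)))
  do.call(rbind, rows)
}

#' Non-redundant top genes by consistency p-value
#'
#' Keeps genes whose consistency p-value reaches `p_cutoff` in any
#' module, deduplicated by gene id with the best (smallest) p-value
#' retained.
#'
#' @param results `data.frame` from [consistency_table()].
#' @param p_cutoff Significance cutoff (e.g. `10^-3.3` or `10^-5`).
#' @return `data.frame` of unique genes sorted by p-value.
#' @export
top_genes <- function(results, p_cutoff) {
  hit <- results[results$p_value <= p_cutoff, , drop = FALSE]
  if (!nrow(hit)) return(hit)
  hit <- hit[order(hit$p_value, -hit$score), , drop = FALSE]
  hit <- hit[!duplicated(hit$gene), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}
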