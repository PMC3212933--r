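#' Module-map summaries across all clinical categories
#'
#' Convenience wrapper: builds the five clinical partitions (tumor
#' subtype, melanoma progression, cancer stage, metastasis site, clinical
#' outcome) from the annotations and computes [group_module_summary()]
#' for each, returning the concatenated table.
#'
#' @param statuses [module_status_table()] output for the whole cohort.
#' @param ann Validated annotation `data.frame`.
#' @param alpha Group-level significance level.
#' @param horizon_years Survival horizon for the clinical-outcome
#'   category.
#' @return Combined `data.frame` of group summaries over all categories.
#' @export
all_category_summaries <- function(statuses, ann, alpha = 0.05,
                                   horizon_years = 4) {
  res <- lapply(.category_names, function(cat) {
    part <- suppressMessages(build_partition(ann, cat, horizon_years))
    suppressWarnings(group_module_summary(statuses, part, alpha = alpha))
  })
  do.call(rbind, res)
}

#' End-to-end module map from expression to selected modules
#'
#' Centers the expression matrix per gene, discretizes at the fold-change
#' threshold, calls per-sample module statuses, summarizes them over all
#' clinical categories and selects the significant non-redundant modules.
#'
#' @param X Gene-by-sample log2-ratio matrix.
#' @param modules Named list of module gene sets.
#' @param ann Validated annotation `data.frame`.
#' @param log2_threshold Discretization threshold ([discretize()]).
#' @param alpha Significance level for sample- and group-level calls.
#' @param min_significant_groups,redundancy_jaccard Passed to
#'   [select_modules()].
#' @return List: `discrete`, `statuses`, `summaries`, `selected`.
#' @export
run_module_map <- function(X, modules, ann, log2_threshold = 1.0,
                           alpha = 0.05, min_significant_groups = 1,
                           redundancy_jaccard = 0.8) {
  D <- discretize(center_genes(X), log2_threshold)
  statuses <- module_status_table(D, modules, alpha = alpha)
  summaries <- all_category_summaries(statuses, ann, alpha = alpha)
  selected <- select_modules(summaries, modules,
                             min_significant_groups =
                               min_significant_groups,
                             redundancy_jaccard = redundancy_jaccard)
  list(discrete = D, statuses = statuses, summaries = summaries,
       selected = selected)
}
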