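#' Read a gene-by-sample log2-ratio expression matrix
#'
#' Reads a tab-delimited table with gene identifiers in the first column and
#' sample identifiers in the header row. Empty cells and literal `NA` are
#' treated as missing measurements and stored as `NA` in the returned matrix;
#' every downstream statistic in the package excludes `NA` entries.
#'
#' @param path Path to a tab-delimited text file.
#' @param na_strings Character values interpreted as missing.
#' @return A numeric matrix with gene row names and sample column names.
#'   Missing entries are `NA`.
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(path, na_strings = c("", "NA")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = na_strings, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression file must have a gene-id column and at least one sample")
  genes <- tab[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write an expression matrix to tab-delimited text
#'
#' @param X Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param id_column Name used for the gene-id column header.
#' @export
write_expression <- function(X, path, id_column = "gene_id") {
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection restricted to a gene universe
#'
#' Parses the standard GMT format (module name, description, then gene ids,
#' tab-separated) and intersects each module with the genes actually present
#' on the platform (`universe`). Modules emptied by the intersection are
#' dropped with a warning so that every retained module is testable.
#'
#' @param path Path to a GMT file.
#' @param universe Character vector of platform gene identifiers.
#' @return A named list of character vectors (one per retained module), with
#'   a `source` attribute holding each module's description field.
#' @export
read_modules_gmt <- function(path, universe) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], ": fewer than 3 fields")
  names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names))
    stop("duplicated module name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  src <- vapply(fields, `[[`, "", 2L)
  mods <- lapply(fields, function(f) intersect(unique(f[-(1:2)]), universe))
  names(mods) <- names
  empty <- !vapply(mods, length, 1L)
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " module(s) with no gene in the universe: ",
            paste(names[empty], collapse = ", "))
    mods <- mods[!empty]
    src <- src[!empty]
  }
  attr(mods, "source") <- stats::setNames(src, names(mods))
  mods
}

#' Write a module collection to GMT
#'
#' @param modules Named list of character vectors.
#' @param path Output path.
#' @export
write_modules_gmt <- function(modules, path) {
  src <- attr(modules, "source")
  if (is.null(src)) src <- stats::setNames(rep("na", length(modules)),
                                           names(modules))
  lines <- vapply(names(modules), function(nm) {
    paste(c(nm, src[[nm]], modules[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.t_class_from_breslow <- function(breslow_mm) {
  # AJCC cut points: T1 <= 1.0, T2 <= 2.0, T3 <= 4.0, T4 > 4.0 mm
  cut(breslow_mm, breaks = c(-Inf, 1, 2, 4, Inf),
      labels = c("T1", "T2", "T3", "T4"))
}

#' Read and validate per-sample clinical annotations
#'
#' Expects a CSV with columns `sample_id`, `subtype` (PCM or MM),
#' `breslow_mm`, `t_class`, `stage`, `met_site`, `vital_status`,
#' `followup_years`. Breslow thickness applies to primaries; where both
#' `t_class` and `breslow_mm` are present and disagree, the class is
#' recomputed from thickness (AJCC thresholds) with a warning.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of validated annotations, one row per sample.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann Annotation `data.frame` built in code rather than read from CSV.
#' @export
validate_annotations <- function(ann) {
  need <- c("sample_id", "subtype", "vital_status", "followup_years")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  for (opt in c("breslow_mm", "t_class", "stage", "met_site"))
    if (!opt %in% colnames(ann)) ann[[opt]] <- NA
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotations")
  if (!all(ann$subtype %in% c("PCM", "MM")))
    stop("subtype must be PCM or MM")
  if (!all(is.na(ann$stage) | ann$stage %in% c("I", "II", "III", "IV")))
    stop("stage must be I, II, III or IV")
  if (!all(is.na(ann$met_site) | ann$met_site %in% c("LN", "CUT", "VISC")))
    stop("met_site must be LN, CUT or VISC")
  if (!all(ann$vital_status %in% c("alive", "dead_melanoma", "dead_other")))
    stop("vital_status must be alive, dead_melanoma or dead_other")
  if (any(ann$followup_years < 0, na.rm = TRUE))
    stop("negative follow-up time")
  if (any(ann$breslow_mm < 0, na.rm = TRUE))
    stop("negative Breslow thickness")
  if (any(ann$subtype == "MM" & is.na(ann$met_site)))
    stop("MM sample(s) without metastasis site: ",
         paste(ann$sample_id[ann$subtype == "MM" & is.na(ann$met_site)],
               collapse = ", "))
  both <- !is.na(ann$breslow_mm) & !is.na(ann$t_class)
  if (any(both)) {
    recomputed <- as.character(.t_class_from_breslow(ann$breslow_mm[both]))
    clash <- recomputed != ann$t_class[both]
    if (any(clash)) {
      warning("t_class inconsistent with breslow_mm for ",
              sum(clash), " sample(s); recomputed from thickness")
      ann$t_class[both][clash] <- recomputed[clash]
    }
  }
  fill <- is.na(ann$t_class) & !is.na(ann$breslow_mm)
  ann$t_class[fill] <- as.character(.t_class_from_breslow(ann$breslow_mm[fill]))
  ann
}

.category_names <- c("tumor_subtype", "melanoma_progression", "cancer_stage",
                     "metastasis_site", "clinical_outcome")

#' Partition a cohort into the groups of a clinical category
#'
#' The five categories follow the study design of melanoma module maps:
#' tumor subtype (PCM, MM), melanoma progression (T1+T2 pooled, T3, T4, MM),
#' cancer stage (I-IV), metastasis site (LN, CUT, VISC; metastatic samples
#' only) and clinical outcome (Surviving, Death under the survival-horizon
#' rule of [survival_groups()]). Samples lacking the category's attribute
#' are omitted from the partition (with a message), because several
#' categories apply only to subsets of the cohort.
#'
#' @param ann Validated annotation `data.frame` (see [read_annotations()]).
#' @param category One of `"tumor_subtype"`, `"melanoma_progression"`,
#'   `"cancer_stage"`, `"metastasis_site"`, `"clinical_outcome"`.
#' @param horizon_years Survival horizon passed to [survival_groups()] for
#'   the clinical-outcome category.
#' @return A named list of sample-id vectors (one per group), with the
#'   category name stored in attribute `category`. Groups are disjoint.
#' @export
build_partition <- function(ann, category, horizon_years = 4) {
  category <- gsub("[ -]", "_", tolower(category))
  if (!category %in% .category_names)
    stop("unknown category '", category, "'; must be one of: ",
         paste(.category_names, collapse = ", "))
  groups <- switch(category,
    tumor_subtype = split(ann$sample_id, factor(ann$subtype,
                                                c("PCM", "MM"))),
    melanoma_progression = {
      lab <- ifelse(ann$subtype == "MM", "MM",
                    ifelse(ann$t_class %in% c("T1", "T2"), "T1+T2",
                           ann$t_class))
      split(ann$sample_id, factor(lab, c("T1+T2", "T3", "T4", "MM")))
    },
    cancer_stage = split(ann$sample_id,
                         factor(ann$stage, c("I", "II", "III", "IV"))),
    metastasis_site = {
      mm <- ann[ann$subtype == "MM", , drop = FALSE]
      split(mm$sample_id, factor(mm$met_site, c("LN", "CUT", "VISC")))
    },
    clinical_outcome = {
      grp <- survival_groups(ann, horizon_years)
      keep <- grp %in% c("Surviving", "Death")
      split(names(grp)[keep], factor(grp[keep], c("Surviving", "Death")))
    })
  n_dropped <- nrow(ann) - length(unlist(groups))
  if (n_dropped > 0L)
    message(n_dropped, " sample(s) lack the '", category,
            "' attribute and were omitted")
  attr(groups, "category") <- category
  groups
}

#' Survival grouping at a fixed follow-up horizon
#'
#' Classifies each patient as `Surviving` (alive at, or dead of melanoma
#' after, `horizon_years` of follow-up), `Death` (died of melanoma within
#' the horizon) or `excluded` (death unrelated to melanoma, or alive with
#' follow-up shorter than the horizon). The rule mirrors the common
#' outcome grouping of melanoma cohorts: a 4-year horizon splitting
#' patients who survived at least 4 years from those who died within 4
#' years, with unrelated deaths and short censored follow-up removed.
#'
#' @inheritParams build_partition
#' @param horizon_years Horizon in years (default 4).
#' @return Named character vector, one of `"Surviving"`, `"Death"`,
#'   `"excluded"` per sample id.
#' @export
survival_groups <- function(ann, horizon_years = 4) {
  if (any(is.na(ann$followup_years)))
    stop("follow-up time missing for sample(s): ",
         paste(ann$sample_id[is.na(ann$followup_years)], collapse = ", "))
  if (any(ann$followup_years < 0)) stop("negative follow-up time")
  out <- character(nrow(ann))
  long <- ann$followup_years >= horizon_years
  out[ann$vital_status == "dead_other"] <- "excluded"
  out[ann$vital_status == "alive" & !long] <- "excluded"
  out[ann$vital_status == "alive" & long] <- "Surviving"
  out[ann$vital_status == "dead_melanoma" & !long] <- "Death"
  out[ann$vital_status == "dead_melanoma" & long] <- "Surviving"
  stats::setNames(out, ann$sample_id)
}
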