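# direction of a phenotype call from the sign convention:
# growth scores follow the measurement itself (positive = more growth);
# for differentiation and outgrowth a positive standardized deviation means
# the point lies below the control regression, i.e. a decrease of the
# measure (fewer neurons / shorter neurites)
score_direction <- function(measure, mean) {
  ifelse(measure == "growth",
         ifelse(mean > 0, "increase", "decrease"),
         ifelse(mean > 0, "decrease", "increase"))
}

#' Call phenotype hits from standardized scores
#'
#' The criterion for phenotype classification is modulation of the
#' standardized measure by more than `threshold` (default 3) control
#' standard deviations, applied to the replicate mean. Hits are graded
#' stringent when `|mean| - SEM` still exceeds the threshold and marginal
#' otherwise.
#'
#' @param scores data.frame from [phenotype_scores()] (columns `gene`,
#'   `oligo`, `dose`, `measure`, `mean`, `sem`).
#' @param threshold hit threshold in control-SD units.
#' @return the input with columns `direction`, `hit`, `stringency`
#'   (`"stringent"`, `"marginal"` or `"none"`), `excluded` and
#'   `exclusion_reason` appended.
#' @export
call_phenotype <- function(scores, threshold = 3) {
  stopifnot(is.data.frame(scores), all(c("measure", "mean") %in% names(scores)))
  if (any(!is.finite(scores$mean)))
    stop("call_phenotype(): non-finite score mean", call. = FALSE)
  sem_ <- if ("sem" %in% names(scores)) scores$sem else NA_real_
  hit <- abs(scores$mean) > threshold
  stringent <- hit & !is.na(sem_) & (abs(scores$mean) - sem_ > threshold)
  out <- scores
  out$direction <- score_direction(scores$measure, scores$mean)
  out$hit <- hit
  out$stringency <- ifelse(!hit, "none", ifelse(stringent, "stringent", "marginal"))
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  out
}

#' Exclude growth-impaired genes from differentiation/outgrowth calls
#'
#' Genes whose mean growth score shows more than a `threshold`-SD reduction
#' in proliferation efficiency are flagged excluded for the differentiation
#' and outgrowth categories: too few measurable cells remain for those
#' measures to be reliable. The growth call itself is retained.
#'
#' @param calls data.frame from [call_phenotype()] containing growth rows
#'   for every gene present.
#' @param threshold exclusion threshold in control-SD units.
#' @return `calls` with updated `excluded` / `exclusion_reason`.
#' @export
apply_exclusions <- function(calls, threshold = 3) {
  stopifnot(is.data.frame(calls), all(c("gene", "measure", "mean") %in% names(calls)))
  growth <- calls[calls$measure == "growth", , drop = FALSE]
  other <- unique(calls$gene[calls$measure != "growth"])
  missing <- setdiff(other, growth$gene)
  if (length(missing))
    stop("apply_exclusions(): no growth score for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  # a gene is excluded if its growth reduction exceeds the threshold at any
  # scored dose (strongest dose governs under the max-dose policy upstream)
  gmean <- tapply(growth$mean, growth$gene, min)
  excl_genes <- names(gmean)[gmean < -threshold]
  sel <- calls$measure != "growth" & calls$gene %in% excl_genes
  calls$excluded[sel] <- TRUE
  calls$exclusion_reason[sel] <-
    sprintf("growth reduced by more than %g SD", threshold)
  calls
}

#' Call phenotypes for a whole score table
#'
#' Applies the dose policy (default: call at the maximal dose, the full
#' titration stays available upstream), thresholds the replicate means,
#' grades stringency and applies the growth exclusion rule.
#'
#' @param scores data.frame from [phenotype_scores()].
#' @param threshold hit threshold in control-SD units.
#' @param dose_policy `"max"` to call at the maximal dose only, `"all"` to
#'   call every dose.
#' @return hit table (data.frame).
#' @export
call_phenotypes <- function(scores, threshold = 3, dose_policy = c("max", "all")) {
  dose_policy <- match.arg(dose_policy)
  if (dose_policy == "max")
    scores <- scores[scores$dose == max(scores$dose), , drop = FALSE]
  apply_exclusions(call_phenotype(scores, threshold), threshold)
}

#' Secondary-screen reproduction status of primary hits
#'
#' A secondary screen re-tests primary (pooled-siRNA) hits with the
#' individual oligonucleotides. An oligo is concordant when it passes the
#' threshold criterion in the primary direction; the phenotype is
#' `reproduced_multiple` with at least two concordant oligos,
#' `reproduced_single` with exactly one, `not_reproduced` otherwise. An
#' oligo significant in the opposite direction sets `opposite_flag`
#' independently of the status.
#'
#' @param primary_calls hit table from [call_phenotypes()] restricted to the
#'   genes and measure being re-tested (one row per gene).
#' @param oligo_scores per-oligo score table from [phenotype_scores()] on
#'   the secondary screen (same measure).
#' @param threshold hit threshold in control-SD units.
#' @return data.frame with one row per gene: `n_oligos`, `n_concordant`,
#'   `n_opposite`, `status`, `opposite_flag`.
#' @export
secondary_reproduction <- function(primary_calls, oligo_scores, threshold = 3) {
  stopifnot(is.data.frame(primary_calls), is.data.frame(oligo_scores))
  genes <- unique(oligo_scores$gene)
  missing <- setdiff(genes, primary_calls$gene)
  if (length(missing))
    stop("secondary_reproduction(): no primary call for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  oc <- call_phenotype(oligo_scores, threshold)
  rows <- lapply(genes, function(g) {
    prim <- primary_calls[primary_calls$gene == g, , drop = FALSE][1, ]
    og <- oc[oc$gene == g, , drop = FALSE]
    conc <- og$hit & og$direction == prim$direction
    oppo <- og$hit & og$direction != prim$direction
    status <- if (sum(conc) >= 2) "reproduced_multiple"
              else if (sum(conc) == 1) "reproduced_single"
              else "not_reproduced"
    data.frame(gene = g, measure = prim$measure, n_oligos = nrow(og),
               n_concordant = sum(conc), n_opposite = sum(oppo),
               status = status, opposite_flag = any(oppo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize secondary-screen reproduction rates
#'
#' @param statuses data.frame from [secondary_reproduction()] (or any
#'   data.frame with a `status` column).
#' @return list with `n_total`, `n_any`, `n_multiple`, `pct_any`,
#'   `pct_multiple` (percentages of genes reproduced by at least one /
#'   by multiple oligos).
#' @examples
#' st <- data.frame(status = rep(c("reproduced_multiple", "reproduced_single",
#'                                 "not_reproduced"), c(11, 11, 8)))
#' reproduction_summary(st)  # ~73% any, ~37% multiple
#' @export
reproduction_summary <- function(statuses) {
  if (!is.data.frame(statuses) || nrow(statuses) == 0L || !"status" %in% names(statuses))
    stop("reproduction_summary(): need a non-empty data.frame with a 'status' column",
         call. = FALSE)
  n <- nrow(statuses)
  n_multi <- sum(statuses$status == "reproduced_multiple")
  n_any <- n_multi + sum(statuses$status == "reproduced_single")
  list(n_total = n, n_any = n_any, n_multiple = n_multi,
       pct_any = 100 * n_any / n, pct_multiple = 100 * n_multi / n)
}

#' Functional-class composition of hits versus the screened library
#'
#' For each functional class, reports the percentage of hit genes in that
#' class next to the percentage of library genes in that class (raw
#' proportions, mirroring how over-representation is reported for the
#' mitosis and dynein/dynactin classes).
#'
#' @param hit_genes character vector of hit gene identifiers.
#' @param annotation data.frame with columns `gene` and `class` covering the
#'   whole screened library.
#' @return data.frame with one row per class: `n_hits`, `n_library`,
#'   `pct_in_hits`, `pct_in_library`.
#' @export
class_enrichment <- function(hit_genes, annotation) {
  stopifnot(is.data.frame(annotation), all(c("gene", "class") %in% names(annotation)))
  hit_genes <- unique(hit_genes)
  missing <- setdiff(hit_genes, annotation$gene)
  if (length(missing))
    stop("class_enrichment(): unannotated hit gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  classes <- sort(unique(annotation$class))
  hits <- annotation[annotation$gene %in% hit_genes, , drop = FALSE]
  out <- data.frame(
    class = classes,
    n_hits = vapply(classes, function(cl) sum(hits$class == cl), numeric(1)),
    n_library = vapply(classes, function(cl) sum(annotation$class == cl), numeric(1)),
    stringsAsFactors = FALSE)
  out$pct_in_hits <- if (nrow(hits)) 100 * out$n_hits / nrow(hits) else NA_real_
  out$pct_in_library <- 100 * out$n_library / nrow(annotation)
  rownames(out) <- NULL
  out
}
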