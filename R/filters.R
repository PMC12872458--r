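# Soft-core pangenome filtering, core-set selection with the late-HGT
# guard, aELW aggregation by functional category, and the strict subset
# used for single-gene claims.

#' Soft-core pangenome filter
#'
#' A cluster is retained for a taxonomic class when it contains sequences
#' from at least the stated fraction of that class's species (inclusive
#' `>=`). Prokaryotic classes use `prok_frac` (default 50%), eukaryotes
#' `euk_frac` (default 20%); alternates such as 10/25/50/67% are plain
#' arguments.
#'
#' @param membership data frame with columns `cluster_id`, `species_id`,
#'   `class_label`, `domain`.
#' @param prok_frac,euk_frac presence thresholds in (0, 1].
#' @return list with `table` (cluster x class presence fractions and kept
#'   flags) and `retained` (cluster ids kept for at least one class).
#' @export
soft_core_pangenome <- function(membership, prok_frac = 0.5, euk_frac = 0.2) {
  stopifnot(prok_frac > 0, prok_frac <= 1, euk_frac > 0, euk_frac <= 1)
  need <- c("cluster_id", "species_id", "class_label", "domain")
  if (!all(need %in% names(membership)))
    input_error("membership table must have cluster_id, species_id, class_label, domain")
  if (!all(membership$domain %in% c("prokaryote", "eukaryote")))
    input_error("unknown domain in membership table")
  class_dom <- unique(membership[, c("class_label", "domain")])
  if (anyDuplicated(class_dom$class_label))
    input_error("class label maps to more than one domain")
  totals <- tapply(membership$species_id, membership$class_label,
                   function(x) length(unique(x)))
  pairs <- unique(membership[, c("cluster_id", "class_label", "species_id")])
  cnt <- stats::aggregate(species_id ~ cluster_id + class_label, pairs,
                          FUN = function(x) length(unique(x)))
  names(cnt)[3L] <- "n_species"
  cnt$total <- as.integer(totals[cnt$class_label])
  cnt$frac <- cnt$n_species / cnt$total
  dom <- class_dom$domain[match(cnt$class_label, class_dom$class_label)]
  thr <- ifelse(dom == "eukaryote", euk_frac, prok_frac)
  cnt$kept <- cnt$frac >= thr
  retained <- sort(unique(cnt$cluster_id[cnt$kept]))
  list(table = cnt, retained = retained)
}

#' Core-set filter with the late-HGT guard
#'
#' Keeps candidate sister associations that satisfy all of: (1) a
#' non-empty functional category (stand-in for an external profile
#' annotation); (2) a eukaryotic clade with more than five distinct
#' taxonomic labels including at least one Amorphea and one
#' Diaphoretickes; (3) candidate ELW strictly inside `(elw_min, elw_max)`
#' -- ELW at or above the upper bound indicates likely post-LECA
#' horizontal transfer -- except that ELW of 1 is admitted for the stated
#' exception pair (by default Alphaproteobacteria with oxidative
#' phosphorylation). Families whose maximum candidate ELW falls below
#' `elw_min` are dropped whole (low-quality), logged at EPOC scope.
#'
#' @param records data frame with columns `epoc_id`, `euk_clade_id`,
#'   `candidate_label`, `elw`, `n_euk_labels`, `has_amorphea`,
#'   `has_diaphoretickes`, `category`, and optionally `pathway`.
#' @param elw_min,elw_max open ELW window.
#' @param exception_taxon,exception_pathway the high-ELW exception.
#' @return list with `core` (kept rows) and `rejected` (rows with a
#'   `reason` code among `no_annotation`, `too_few_labels`,
#'   `missing_supergroup`, `low_elw`, `high_elw`, and a `scope` column
#'   distinguishing candidate-level from EPOC-level drops).
#' @export
core_set_filter <- function(records, elw_min = 0.4, elw_max = 0.99,
                            exception_taxon = "Alphaproteobacteria",
                            exception_pathway = "oxidative_phosphorylation") {
  records <- as.data.frame(records)
  if (is.null(records$pathway)) records$pathway <- records$category
  reason <- rep(NA_character_, nrow(records))
  scope <- rep("candidate", nrow(records))
  no_cat <- is.na(records$category) | !nzchar(records$category)
  reason[no_cat] <- "no_annotation"
  few <- is.na(reason) & records$n_euk_labels <= 5L
  reason[few] <- "too_few_labels"
  sg <- is.na(reason) & !(records$has_amorphea & records$has_diaphoretickes)
  reason[sg] <- "missing_supergroup"
  # EPOC-level low-quality drop: max candidate ELW below the window
  fam_max <- tapply(records$elw, records$epoc_id, max)
  low_fam <- is.na(reason) & fam_max[as.character(records$epoc_id)] < elw_min
  reason[low_fam] <- "low_elw"
  scope[low_fam] <- "epoc"
  low <- is.na(reason) & records$elw <= elw_min
  reason[low] <- "low_elw"
  exception <- records$elw >= 1 - 1e-12 &
    records$candidate_label == exception_taxon &
    records$pathway == exception_pathway
  high <- is.na(reason) & records$elw >= elw_max & !exception
  reason[high] <- "high_elw"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rejected$scope <- scope[!keep]
  list(core = records[keep, , drop = FALSE], rejected = rejected)
}

#' Average ELW by functional category
#'
#' Each cell of the category x taxon table is the arithmetic mean of the
#' contributing records' ELW for that taxon, with the contributing record
#' count kept alongside. Taxa whose global aELW stays below `other_below`
#' can be grouped into an `"other"` margin for reporting.
#'
#' @param records data frame with `epoc_id`, `candidate_label`, `elw`,
#'   `category`.
#' @param other_below optional grouping threshold (NULL to disable).
#' @return data frame (category, taxon, aelw, n).
#' @export
aelw_by_category <- function(records, other_below = NULL) {
  records <- records[!is.na(records$category) & nzchar(records$category), ,
                     drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(category = character(0), taxon = character(0),
                      aelw = numeric(0), n = integer(0)))
  key <- interaction(records$category, records$candidate_label, drop = TRUE)
  agg <- data.frame(category = tapply(records$category, key, `[`, 1L),
                    taxon = tapply(records$candidate_label, key, `[`, 1L),
                    aelw = as.numeric(tapply(records$elw, key, mean)),
                    n = as.integer(tapply(records$elw, key, length)))
  rownames(agg) <- NULL
  if (!is.null(other_below)) {
    glob <- tapply(agg$aelw * agg$n, agg$taxon, sum) /
      tapply(agg$n, agg$taxon, sum)
    small <- names(glob)[glob < other_below]
    agg$taxon[agg$taxon %in% small] <- "other"
    return(aelw_regroup(agg))
  }
  agg[order(agg$category, agg$taxon), , drop = FALSE]
}

aelw_regroup <- function(agg) {
  key <- interaction(agg$category, agg$taxon, drop = TRUE)
  out <- data.frame(category = tapply(agg$category, key, `[`, 1L),
                    taxon = tapply(agg$taxon, key, `[`, 1L),
                    aelw = as.numeric(tapply(agg$aelw * agg$n, key, sum) /
                                        tapply(agg$n, key, sum)),
                    n = as.integer(tapply(agg$n, key, sum)))
  rownames(out) <- NULL
  out[order(out$category, out$taxon), , drop = FALSE]
}

#' Best pathway aELW per taxon relative to a reference taxon
#'
#' For each non-reference taxon, among pathways (categories) supported by
#' at least `min_epocs` records, selects the pathway with the taxon's
#' highest aELW and reports it together with the reference taxon's aELW
#' on the same pathway and their ratio. Taxa with no qualifying pathway
#' are omitted (listed in the `"omitted"` attribute).
#'
#' @param table output of [aelw_by_category()].
#' @param reference reference taxon (default `"Asgard"`).
#' @param min_epocs minimum records per pathway (inclusive).
#' @return data frame (taxon, pathway, aelw, ref_aelw, ratio).
#' @export
relative_aelw_vs_reference <- function(table, reference = "Asgard",
                                       min_epocs = 20L) {
  if (!reference %in% table$taxon)
    input_error("reference taxon absent from the table")
  path_n <- tapply(table$n, table$category, sum)
  ok_paths <- names(path_n)[path_n >= min_epocs]
  taxa <- setdiff(unique(table$taxon), reference)
  rows <- list()
  omitted <- character(0)
  for (tx in taxa) {
    sub <- table[table$taxon == tx & table$category %in% ok_paths, ,
                 drop = FALSE]
    if (nrow(sub) == 0L) { omitted <- c(omitted, tx); next }
    i <- order(-sub$aelw, sub$category)[1L]
    ref <- table$aelw[table$taxon == reference &
                        table$category == sub$category[i]]
    ref <- if (length(ref)) ref[1L] else 0
    rows[[length(rows) + 1L]] <-
      data.frame(taxon = tx, pathway = sub$category[i], aelw = sub$aelw[i],
                 ref_aelw = ref,
                 ratio = if (ref > 0) sub$aelw[i] / ref else Inf)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), pathway = character(0),
               aelw = numeric(0), ref_aelw = numeric(0), ratio = numeric(0))
  attr(out, "omitted") <- omitted
  out
}

#' Strict subset filter for single-gene ancestry claims
#'
#' Keeps records with a eukaryotic clade of at least 15 distinct
#' taxonomic labels, a prokaryotic sister clade of at least 20 sequences,
#' and ELW strictly greater than 0.7.
#'
#' @param records data frame with `n_euk_labels`, `sister_size`, `elw`.
#' @param min_labels,min_sister_seqs inclusive thresholds.
#' @param min_elw strict lower ELW bound.
#' @return the kept rows.
#' @export
strict_subset_filter <- function(records, min_labels = 15L,
                                 min_sister_seqs = 20L, min_elw = 0.7) {
  keep <- records$n_euk_labels >= min_labels &
    records$sister_size >= min_sister_seqs &
    records$elw > min_elw
  records[keep, , drop = FALSE]
}
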