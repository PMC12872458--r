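# Taxonomy tables: sequence id -> (class label, domain, eukaryotic
# supergroup). The supergroup column drives the LECA coverage filter.

#' Construct and validate a taxonomy table
#'
#' @param id character vector of unique sequence ids.
#' @param class_label taxonomic class label per sequence.
#' @param domain `"prokaryote"` or `"eukaryote"` per sequence.
#' @param supergroup eukaryotic supergroup: `"Amorphea"`,
#'   `"Diaphoretickes"`, `"other"`, or `"not_applicable"` (required for,
#'   and only for, prokaryotes).
#' @return a data frame of class `"taxonomy_table"`.
#' @export
taxonomy_table <- function(id, class_label, domain, supergroup) {
  id <- as.character(id)
  if (anyDuplicated(id)) input_error("taxonomy ids must be unique")
  if (!all(domain %in% c("prokaryote", "eukaryote")))
    input_error("domain must be prokaryote or eukaryote")
  stopifnot(length(class_label) == length(id), length(domain) == length(id),
            length(supergroup) == length(id))
  ok <- supergroup %in% c("Amorphea", "Diaphoretickes", "other",
                          "not_applicable")
  if (!all(ok)) input_error("unknown supergroup value")
  mism <- (supergroup == "not_applicable") != (domain == "prokaryote")
  if (any(mism))
    input_error("supergroup must be not_applicable iff domain is prokaryote")
  out <- data.frame(id = id, class_label = as.character(class_label),
                    domain = domain, supergroup = supergroup,
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

taxonomy_labels <- function(taxonomy, ids) {
  setNames(taxonomy$class_label[match(ids, taxonomy$id)], ids)
}

taxonomy_domains <- function(taxonomy, ids) {
  setNames(taxonomy$domain[match(ids, taxonomy$id)], ids)
}

#' Read / write taxonomy tables as TSV
#'
#' Columns: `id`, `class_label`, `domain`, `supergroup`.
#'
#' @param path file path.
#' @return for `read_taxonomy`, a validated [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  taxonomy_table(d$id, d$class_label, d$domain, d$supergroup)
}

#' @rdname read_taxonomy
#' @param taxonomy a [taxonomy_table()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write aligned amino-acid FASTA
#'
#' Alignments are plain character matrices (one row per sequence, rownames
#' are sequence ids, gap character `-`).
#'
#' @param path file path.
#' @return for `read_alignment`, a character matrix.
#' @export
read_alignment <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  m <- toupper(do.call(rbind, as.character(x)))
  rownames(m) <- names(x)
  m
}

#' @rdname read_alignment
#' @param alignment character matrix of aligned residues.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(paste0(">", rownames(alignment)[i]), con)
    writeLines(paste(alignment[i, ], collapse = ""), con)
  }
  invisible(path)
}
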