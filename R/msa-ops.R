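# Alignment column statistics, information-content trimming and
# taxonomy-aware prune-and-align data reduction.

#' Shannon information content of one alignment column
#'
#' Information is `log2(20)` minus the Shannon entropy of the amino-acid
#' frequency distribution of the column. Gaps and ambiguity characters are
#' excluded from the distribution; an all-gap column carries 0 bits.
#'
#' @param column character vector of single residues (may include `-`).
#' @return information in bits, in `[0, log2(20)]`.
#' @export
column_information <- function(column) {
  stopifnot(length(column) >= 1L)
  up <- toupper(column)
  keep <- !(up %in% c("-", ".", "X", "?", "*"))
  res <- up[keep]
  if (!all(res %in% aa_alphabet()))
    input_error(paste0("non-amino-acid characters in column: ",
                       paste(setdiff(res, aa_alphabet()), collapse = " ")))
  if (length(res) == 0L) return(0)
  p <- table(res)
  p <- as.numeric(p) / sum(p)
  H <- -sum(p * log2(p))
  log2(20) - H
}

#' Trim alignment columns by information content
#'
#' Keeps exactly the columns whose information content is strictly greater
#' than `threshold_bits`; row order is preserved. The default matches the
#' tree-reconstruction setting (0.15 bits); profile construction uses 0.2.
#'
#' @param alignment character matrix (rows = sequences).
#' @param threshold_bits keep columns with information `>` this value.
#' @return trimmed character matrix, with attribute `"report"`: a data
#'   frame of (site, information, kept).
#' @export
trim_alignment <- function(alignment, threshold_bits = 0.15) {
  stopifnot(is.matrix(alignment), threshold_bits >= 0)
  info <- apply(alignment, 2L, column_information)
  keep <- info > threshold_bits
  out <- alignment[, keep, drop = FALSE]
  attr(out, "report") <- data.frame(site = seq_along(info),
                                    information = info, kept = keep)
  out
}

#' Reduce a gene family to a target size by taxonomy-aware pruning
#'
#' Iteratively collapses the closest pair of leaves (smallest patristic
#' distance) when the pair is a same-label monophyletic cherry, keeping the
#' leaf closest to the root and crediting the survivor with the pruned
#' leaf's relatives. If no same-label cherry remains above the target, the
#' leaves with the fewest pruned relatives are deleted until the target is
#' reached (retaining the largest collapsed groups). All ties break
#' lexicographically by leaf id, so the result is deterministic.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param taxonomy a [taxonomy_table()] or data frame covering all leaves.
#' @param target_n number of leaves to retain (`>= 1`).
#' @return character vector of retained leaf ids, of length
#'   `min(target_n, n_leaves)`.
#' @export
prune_and_align_reduce <- function(tree, taxonomy, target_n) {
  stopifnot(target_n >= 1L)
  lab <- taxonomy_labels(taxonomy, tree$tip.label)
  if (anyNA(lab)) input_error("all leaves must carry a taxonomic label")
  pruned <- setNames(integer(length(tree$tip.label)), tree$tip.label)
  phy <- tree
  while (ape::Ntip(phy) > target_n) {
    ch <- children_list(phy)
    bl <- node_branch_lengths(phy)
    depth <- node_depths(phy)
    nt <- ape::Ntip(phy)
    # same-label cherries: internal nodes with two leaf children, one label
    best <- NULL
    for (v in (nt + 1L):(nt + phy$Nnode)) {
      kids <- ch[[v]]
      if (length(kids) == 2L && all(kids <= nt)) {
        l1 <- phy$tip.label[kids[1L]]; l2 <- phy$tip.label[kids[2L]]
        if (lab[[l1]] == lab[[l2]]) {
          d <- bl[kids[1L]] + bl[kids[2L]]
          key <- sort(c(l1, l2))
          if (is.null(best) || d < best$d - 1e-15 ||
              (abs(d - best$d) <= 1e-15 &&
               paste(key, collapse = "\r") < paste(best$key, collapse = "\r"))) {
            best <- list(d = d, kids = kids, key = key, v = v)
          }
        }
      }
    }
    if (is.null(best)) break
    ids <- phy$tip.label[best$kids]
    dep <- depth[best$kids]
    drop_i <- if (abs(dep[1L] - dep[2L]) <= 1e-15) {
      # equal depth: keep the lexicographically smaller id
      if (ids[1L] < ids[2L]) 2L else 1L
    } else which.max(dep)
    keep_id <- ids[-drop_i]; drop_id <- ids[drop_i]
    pruned[keep_id] <- pruned[keep_id] + 1L + pruned[drop_id]
    if (ape::Ntip(phy) == 2L) {
      retained <- keep_id
      attr(retained, "pruned_relatives") <- pruned[retained]
      return(retained)
    }
    phy <- ape::drop.tip(phy, drop_id, collapse.singles = TRUE)
  }
  retained <- phy$tip.label
  if (length(retained) > target_n) {
    # fallback: delete leaves with the fewest pruned relatives
    ord <- retained[order(pruned[retained], retained)]
    drop_ids <- ord[seq_len(length(retained) - target_n)]
    retained <- retained[!(retained %in% drop_ids)]
  }
  attr(retained, "pruned_relatives") <- pruned[retained]
  retained
}
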