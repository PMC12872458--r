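# Tree curation and taxonomic clade detection: log-normal long-branch
# pruning, weighted midpoint rooting, the soft-LCA purity x scope score,
# clade validity rules and the topological distance used for candidate
# enumeration.

#' Remove long-branch outliers under a log-normal branch-length model
#'
#' Fits a log-normal distribution by maximum likelihood to all positive
#' branch lengths (terminal and internal) and removes every subtree whose
#' subtending branch is strictly longer than the 99.5% quantile. Zero
#' length branches never enter the fit and are never removed. With fewer
#' than 10 positive branch lengths the tree is returned unchanged.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param taxonomy optional [taxonomy_table()]; when given, the family is
#'   discarded (condition `"epoc_discarded"`, reason `outlier_overprune`)
#'   if pruning would delete a whole maximal eukaryotic clade or more than
#'   30% of all leaves.
#' @param q upper quantile of the fitted distribution (default 0.995).
#' @param max_removed_frac leaf-fraction guard (default 0.3).
#' @return list with `tree` (pruned), `removed` (list of character vectors
#'   of removed leaf ids, one per removed subtree) and `model`
#'   (`mu`, `sigma`, `upper_cut`).
#' @export
fit_lognormal_prune <- function(tree, taxonomy = NULL, q = 0.995,
                                max_removed_frac = 0.3) {
  bl_all <- tree$edge.length
  pos <- bl_all[bl_all > 0]
  if (length(pos) < 10L) {
    return(list(tree = tree, removed = list(),
                model = list(mu = NA_real_, sigma = NA_real_,
                             upper_cut = Inf)))
  }
  lx <- log(pos)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))  # ML estimate
  upper_cut <- exp(mu + sigma * qnorm(q))
  bl <- node_branch_lengths(tree)
  over <- which(!is.na(bl) & bl > upper_cut)
  if (length(over) == 0L) {
    return(list(tree = tree, removed = list(),
                model = list(mu = mu, sigma = sigma, upper_cut = upper_cut)))
  }
  tips <- node_tip_sets(tree)
  # keep only maximal flagged subtrees (drop flagged nodes nested in others)
  covered <- logical(ape::Ntip(tree) + tree$Nnode)
  over <- over[order(-lengths(tips[over]))]
  keep_nodes <- integer(0)
  removed_tips <- logical(ape::Ntip(tree))
  for (v in over) {
    tv <- tips[[v]]
    if (!any(removed_tips[tv])) {
      keep_nodes <- c(keep_nodes, v)
      removed_tips[tv] <- TRUE
    } else if (!all(removed_tips[tv])) {
      keep_nodes <- c(keep_nodes, v)
      removed_tips[tv] <- TRUE
    }
  }
  removed <- lapply(keep_nodes, function(v) tree$tip.label[tips[[v]]])
  drop_ids <- tree$tip.label[removed_tips]
  n_left <- ape::Ntip(tree) - length(drop_ids)
  if (length(drop_ids) / ape::Ntip(tree) > max_removed_frac)
    epoc_discard("outlier_overprune",
                 sprintf("%d of %d leaves over the cut", length(drop_ids),
                         ape::Ntip(tree)))
  if (!is.null(taxonomy)) {
    dom <- taxonomy_domains(taxonomy, tree$tip.label)
    euk_blocks <- maximal_domain_clades(tree, dom, "eukaryote")
    gone <- vapply(euk_blocks, function(ids) all(ids %in% drop_ids), TRUE)
    if (length(euk_blocks) && any(gone))
      epoc_discard("outlier_overprune", "pruning removes a whole eukaryotic clade")
  }
  if (n_left < 2L)
    epoc_discard("outlier_overprune", "fewer than two leaves would remain")
  pruned <- ape::drop.tip(tree, drop_ids, collapse.singles = TRUE)
  list(tree = pruned, removed = removed,
       model = list(mu = mu, sigma = sigma, upper_cut = upper_cut))
}

# maximal subtrees whose leaves are all of `domain`; returns leaf-id sets
maximal_domain_clades <- function(tree, dom, domain) {
  nt <- ape::Ntip(tree)
  tips <- node_tip_sets(tree)
  pure <- vapply(seq_len(nt + tree$Nnode), function(v)
    all(dom[tree$tip.label[tips[[v]]]] == domain), TRUE)
  par <- parent_vec(tree)
  maximal <- which(pure & (is.na(par[seq_along(pure)]) | !pure[ifelse(is.na(par), 1L, par)]))
  lapply(maximal, function(v) tree$tip.label[tips[[v]]])
}

#' Re-root a tree so total branch length balances across the root
#'
#' Places the root at the point on an edge that minimizes the absolute
#' difference between the summed branch lengths of the two resulting
#' sides (each side including its share of the split edge). The optimum
#' is found exactly: the imbalance is linear in the offset along each
#' edge. Ties break toward the lexicographically smallest candidate, so
#' re-rooting an already balanced tree is a fixed point.
#'
#' @param tree `phylo` with branch lengths (>= 2 leaves).
#' @return re-rooted `phylo`; attribute `"balance"` holds the achieved
#'   `|T_left - T_right|`.
#' @export
weighted_midpoint_root <- function(tree) {
  stopifnot(ape::Ntip(tree) >= 2L)
  bl <- node_branch_lengths(tree)
  tips <- node_tip_sets(tree)
  total <- sum(tree$edge.length)
  # subtree interior sums (excluding the node's own stem)
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  sub <- numeric(n)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; v <- po[i, 2L]
    sub[p] <- sub[p] + sub[v] + bl[v]
  }
  best <- NULL
  for (v in seq_len(n)) {
    if (is.na(bl[v])) next  # root has no stem
    len <- bl[v]
    # root at offset x above node v: child side total = sub[v] + x
    xstar <- total / 2 - sub[v]
    x <- min(max(xstar, 0), len)
    imb <- abs(2 * (sub[v] + x) - total)
    key <- min(tree$tip.label[tips[[v]]])
    if (is.null(best) || imb < best$imb - 1e-12 ||
        (imb <= best$imb + 1e-12 && key < best$key)) {
      best <- list(v = v, x = x, imb = imb, key = key)
    }
  }
  out <- reroot_at_edge(tree, best$v, best$x)
  attr(out, "balance") <- best$imb
  out
}

#' Soft-LCA scores for one taxonomic label
#'
#' For every node on a path from the root of a maximal monophyletic clade
#' of the label to the tree root, computes
#' `(n_label_in_clade / clade_size) * (n_label_in_clade / n_label_total)`
#' -- a product of taxonomic purity and scope. The ranked list tolerates
#' limited label contamination in an otherwise monophyletic clade.
#'
#' @param tree rooted `phylo`.
#' @param taxonomy [taxonomy_table()] covering the leaves.
#' @param label class label to score; a `domain` value may be scored by
#'   passing `label = "eukaryote"` or `"prokaryote"` with
#'   `by_domain = TRUE`.
#' @param by_domain score leaves by domain instead of class label.
#' @return data frame (node, size, n_label, purity, score) sorted by
#'   descending score, ties broken by smaller clade then node id; empty if
#'   the label does not occur.
#' @export
soft_lca_scan <- function(tree, taxonomy, label, by_domain = FALSE) {
  lab <- if (by_domain) taxonomy_domains(taxonomy, tree$tip.label)
         else taxonomy_labels(taxonomy, tree$tip.label)
  is_x <- lab[tree$tip.label] == label
  empty <- data.frame(node = integer(0), size = integer(0),
                      n_label = integer(0), purity = numeric(0),
                      score = numeric(0))
  if (!any(is_x)) return(empty)
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  tips <- node_tip_sets(tree)
  size <- lengths(tips)
  nx <- vapply(tips, function(tv) sum(is_x[tv]), 0L)
  total_x <- sum(is_x)
  par <- parent_vec(tree)
  pure <- nx == size
  # maximal monophyletic label clades: pure, parent not pure
  maximal <- which(pure & nx > 0L &
                   (is.na(par) | !pure[ifelse(is.na(par), 1L, par)]))
  visit <- logical(n)
  for (v in maximal) {
    u <- v
    while (!is.na(u) && !visit[u]) { visit[u] <- TRUE; u <- par[u] }
  }
  nodes <- which(visit)
  out <- data.frame(node = nodes, size = size[nodes], n_label = nx[nodes],
                    purity = nx[nodes] / size[nodes],
                    score = (nx[nodes] / size[nodes]) * (nx[nodes] / total_x))
  out[order(-out$score, out$size, out$node), , drop = FALSE]
}

#' Detect taxonomic clades with the soft-LCA score
#'
#' Scores every prokaryotic class label and the eukaryotic domain with
#' [soft_lca_scan()], then greedily selects the best-scoring,
#' leaf-disjoint clades per label among the nodes whose purity passes the
#' threshold (nodes at or below it are skipped, so pure clades nested
#' under an impure ancestor are still found). A prokaryotic clade is valid with at
#' least 3 sequences and purity strictly above 0.8; a eukaryotic clade
#' needs at least 5 sequences at the same purity. Families with no valid
#' eukaryotic or no valid prokaryotic clade are discarded, as are families
#' with more than three valid eukaryotic clades (high paraphyly).
#'
#' @param tree rooted `phylo`.
#' @param taxonomy [taxonomy_table()] covering all leaves.
#' @param min_prok,min_euk minimum clade sizes.
#' @param min_purity validity requires purity strictly greater than this.
#' @param check should the discard rules be enforced?
#' @return data frame of clade calls: (node, label, domain, size, n_label,
#'   purity, score, valid, representative) where the representative is the
#'   lowest-branching leaf of the clade.
#' @export
detect_clades <- function(tree, taxonomy, min_prok = 3L, min_euk = 5L,
                          min_purity = 0.8, check = TRUE) {
  lab <- taxonomy_labels(taxonomy, tree$tip.label)
  dom <- taxonomy_domains(taxonomy, tree$tip.label)
  if (anyNA(lab) || anyNA(dom))
    input_error("taxonomy must cover all leaves")
  tips <- node_tip_sets(tree)
  tdep <- node_topo_depths(tree)
  calls <- list()
  scan_one <- function(label, by_domain, domain) {
    sc <- soft_lca_scan(tree, taxonomy, label, by_domain = by_domain)
    if (nrow(sc) == 0L) return(NULL)
    # greedy disjoint selection, skipping nodes that fail the purity
    # gate so that pure clades nested under an impure ancestor are found
    chosen <- integer(0)
    used <- logical(ape::Ntip(tree))
    for (i in seq_len(nrow(sc))) {
      if (sc$purity[i] <= min_purity) next
      tv <- tips[[sc$node[i]]]
      if (!any(used[tv])) {
        chosen <- c(chosen, i)
        used[tv] <- TRUE
      }
    }
    sel <- sc[chosen, , drop = FALSE]
    sel$label <- label
    sel$domain <- domain
    min_size <- if (domain == "eukaryote") min_euk else min_prok
    sel$valid <- sel$size >= min_size & sel$purity > min_purity
    sel$representative <- vapply(sel$node, function(v) {
      tv <- tips[[v]]
      d <- tdep[tv]
      ids <- tree$tip.label[tv]
      ids[order(d, ids)][1L]  # lowest branching leaf, ties lexicographic
    }, "")
    sel
  }
  for (l in sort(unique(lab[dom == "prokaryote"])))
    calls[[length(calls) + 1L]] <- scan_one(l, FALSE, "prokaryote")
  calls[[length(calls) + 1L]] <- scan_one("eukaryote", TRUE, "eukaryote")
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out <- out[, c("node", "label", "domain", "size", "n_label", "purity",
                 "score", "valid", "representative")]
  if (check) {
    n_euk <- sum(out$valid & out$domain == "eukaryote")
    n_prok <- sum(out$valid & out$domain == "prokaryote")
    if (n_euk == 0L) epoc_discard("no_euk_clade")
    if (n_prok == 0L) epoc_discard("no_prok_clade")
    if (n_euk > 3L)
      epoc_discard("paraphyly", sprintf("%d valid eukaryotic clades", n_euk))
  }
  out
}

#' Topological distance between two nodes
#'
#' The number of internal bifurcation nodes strictly between the two nodes
#' on the path connecting them, excluding the tree root and both
#' endpoints. Sister clades whose shared parent is not the root are at
#' distance 1; a node to itself is at distance 0.
#'
#' @param tree rooted `phylo`.
#' @param node_a,node_b node numbers (tips or internal).
#' @return non-negative integer count.
#' @export
topological_distance <- function(tree, node_a, node_b) {
  if (node_a == node_b) return(0L)
  path <- ape::nodepath(tree, node_a, node_b)
  inner <- path[-c(1L, length(path))]
  root <- ape::Ntip(tree) + 1L
  inner <- inner[inner != root]
  sum(inner > ape::Ntip(tree))
}
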