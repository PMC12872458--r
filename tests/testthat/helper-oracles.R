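# Independent oracles used across the suite. Each one recomputes a
# quantity by direct enumeration or first principles, without touching
# the implementation path it checks.

# Likelihood by exhaustive summation over all internal-state assignments
# (vectorized over the 20^k internal combinations). Equal-rate models only.
brute_force_loglik <- function(tree, aln, model) {
  code <- epocflow:::encode_alignment(aln)[tree$tip.label, , drop = FALSE]
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  bl <- epocflow:::node_branch_lengths(tree)
  par <- epocflow:::parent_vec(tree)
  Pm <- lapply(seq_len(n), function(v)
    if (is.na(bl[v])) NULL else transition_matrix(model, bl[v]))
  internals <- (nt + 1L):n
  root <- nt + 1L
  combos <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  icol <- function(v) combos[, match(v, internals)]
  S <- ncol(code)
  out <- numeric(S)
  for (s in seq_len(S)) {
    p <- model$pi[icol(root)]
    for (v in seq_len(n)) {
      if (v == root) next
      child_state <- if (v <= nt) rep(code[v, s], nrow(combos)) else icol(v)
      p <- p * Pm[[v]][cbind(icol(par[v]), child_state)]
    }
    out[s] <- log(sum(p))
  }
  out
}

# Shannon information of a column by direct entropy computation
brute_force_information <- function(column) {
  res <- column[!(column %in% c("-", ".", "X", "?", "*"))]
  if (length(res) == 0L) return(0)
  p <- as.numeric(table(res)) / length(res)
  log2(20) + sum(p * log2(p))
}

# soft-LCA scores for a label by scoring EVERY node of the tree, then
# keeping the nodes detection should visit (ancestors of maximal pure
# clades of the label, the clade roots included)
brute_force_soft_lca <- function(tree, taxonomy, label, by_domain = FALSE) {
  lab <- if (by_domain) {
    setNames(taxonomy$domain[match(tree$tip.label, taxonomy$id)],
             tree$tip.label)
  } else {
    setNames(taxonomy$class_label[match(tree$tip.label, taxonomy$id)],
             tree$tip.label)
  }
  tipsets <- epocflow:::node_tip_sets(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  total_x <- sum(lab == label)
  score <- vapply(seq_len(n), function(v) {
    ids <- tree$tip.label[tipsets[[v]]]
    nx <- sum(lab[ids] == label)
    (nx / length(ids)) * (nx / total_x)
  }, 0)
  par <- epocflow:::parent_vec(tree)
  pure <- vapply(seq_len(n), function(v) {
    ids <- tree$tip.label[tipsets[[v]]]
    all(lab[ids] == label)
  }, TRUE)
  has <- vapply(seq_len(n), function(v)
    any(lab[tree$tip.label[tipsets[[v]]]] == label), TRUE)
  maximal <- which(pure & has & (is.na(par) | !pure[ifelse(is.na(par), 1L, par)]))
  visit <- logical(n)
  for (v in maximal) {
    u <- v
    while (!is.na(u)) { visit[u] <- TRUE; u <- par[u] }
  }
  data.frame(node = which(visit), score = score[visit])
}

# imbalance of a rooted tree: |total branch length left - right| when the
# root splits the tree into the clade below `child` plus the rest
balance_at <- function(tree, child, x) {
  bl <- epocflow:::node_branch_lengths(tree)
  tipsets <- epocflow:::node_tip_sets(tree)
  total <- sum(tree$edge.length)
  sub <- sum_subtree(tree, child)
  abs(2 * (sub + x) - total)
}

# total branch length strictly inside the subtree below v (v's stem excluded)
sum_subtree <- function(tree, v) {
  bl <- epocflow:::node_branch_lengths(tree)
  par <- epocflow:::parent_vec(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  below <- vapply(seq_len(n), function(u) {
    if (u == v) return(FALSE)
    w <- u
    while (!is.na(w)) { if (w == v) return(TRUE); w <- par[w] }
    FALSE
  }, TRUE)
  sum(bl[below], na.rm = TRUE)
}

# exhaustive weighted-midpoint scan: best achievable imbalance over all
# edges and a fine offset grid (subtree sums precomputed once)
brute_force_min_balance <- function(tree, n_grid = 201L) {
  bl <- epocflow:::node_branch_lengths(tree)
  total <- sum(tree$edge.length)
  n <- ape::Ntip(tree) + tree$Nnode
  sub <- vapply(seq_len(n), function(v) sum_subtree(tree, v), 0)
  best <- Inf
  for (v in which(!is.na(bl))) {
    for (x in seq(0, bl[v], length.out = n_grid)) {
      b <- abs(2 * (sub[v] + x) - total)
      if (b < best) best <- b
    }
  }
  best
}

# Mann-Whitney U two-sided p by enumeration over group-A index subsets
brute_force_mwu <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  idx <- combn(na + nb, na)
  Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  list(U = U,
       p = min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))))
}

# Rand index between two partitions (same element order)
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# deterministic toy taxonomy for hand-built trees: label from the leaf
# name prefix (before the underscore); eukaryotes are labeled "euk*"
toy_taxonomy <- function(ids, euk_prefix = "euk") {
  cls <- sub("_.*$", "", ids)
  is_euk <- startsWith(ids, euk_prefix)
  taxonomy_table(ids, cls,
                 ifelse(is_euk, "eukaryote", "prokaryote"),
                 ifelse(is_euk, "Amorphea", "not_applicable"))
}

# two well separated 10-leaf clades joined by a long connecting path
two_blob_tree <- function(seed, scale = 50) {
  set.seed(seed)
  t1 <- ape::rphylo(10, 1, 0)
  t2 <- ape::rphylo(10, 1, 0)
  t1$edge.length <- rexp(nrow(t1$edge), 10)
  t2$edge.length <- rexp(nrow(t2$edge), 10)
  t1$tip.label <- paste0("A", 1:10)
  t2$tip.label <- paste0("B", 1:10)
  t1$root.edge <- scale * 0.1
  t2$root.edge <- scale * 0.1
  ape::bind.tree(t1, t2, position = scale * 0.1)
}
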