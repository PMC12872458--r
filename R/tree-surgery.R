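# Internal low-level tree manipulation. Trees cross the package boundary as
# ape "phylo" objects; surgery (rerooting at an arbitrary point, regrafting a
# subtree) is done on a parent/children list representation and converted
# back, suppressing any degree-2 nodes that the operation creates.

as_treelist <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  n <- nt + nn
  parent <- rep(NA_integer_, n)
  bl <- rep(NA_real_, n)
  children <- vector("list", n)
  e <- phy$edge
  parent[e[, 2L]] <- e[, 1L]
  if (!is.null(phy$edge.length)) bl[e[, 2L]] <- phy$edge.length
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]
    children[[p]] <- c(children[[p]], e[i, 2L])
  }
  label <- rep(NA_character_, n)
  label[seq_len(nt)] <- phy$tip.label
  list(parent = parent, children = children, bl = bl, label = label,
       root = nt + 1L, n = n)
}

# Rebuild a phylo from a treelist, visiting only nodes reachable from
# tl$root and merging single-child (degree-2) internal nodes.
treelist_to_phylo <- function(tl) {
  # iteratively suppress single-child internals (root included: re-root below)
  repeat {
    changed <- FALSE
    for (v in seq_len(tl$n)) {
      ch <- tl$children[[v]]
      if (length(ch) == 1L && is.na(tl$label[v])) {
        c1 <- ch[[1L]]
        if (v == tl$root) {
          tl$root <- c1
          tl$parent[c1] <- NA_integer_
          tl$bl[c1] <- NA_real_
        } else {
          p <- tl$parent[v]
          tl$children[[p]][tl$children[[p]] == v] <- c1
          tl$parent[c1] <- p
          tl$bl[c1] <- tl$bl[c1] + tl$bl[v]
        }
        tl$children[[v]] <- integer(0)
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  # DFS preorder from root
  n_reach <- 0L
  order <- integer(tl$n)
  stack <- tl$root
  is_tip <- logical(tl$n)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    n_reach <- n_reach + 1L
    order[n_reach] <- v
    ch <- tl$children[[v]]
    if (length(ch) == 0L) is_tip[v] <- TRUE
    # push reversed so first child is visited first
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  order <- order[seq_len(n_reach)]
  tips <- order[is_tip[order]]
  internals <- order[!is_tip[order]]
  ntip <- length(tips)
  new_id <- integer(tl$n)
  new_id[tips] <- seq_len(ntip)
  new_id[internals] <- ntip + seq_along(internals)
  edge <- matrix(0L, n_reach - 1L, 2L)
  elen <- numeric(n_reach - 1L)
  k <- 0L
  for (v in order) {
    for (c1 in tl$children[[v]]) {
      k <- k + 1L
      edge[k, ] <- c(new_id[v], new_id[c1])
      elen[k] <- tl$bl[c1]
    }
  }
  phy <- list(edge = edge, edge.length = elen,
              tip.label = tl$label[tips], Nnode = length(internals))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# branch length indexed by child node
node_branch_lengths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  bl <- rep(NA_real_, n)
  bl[phy$edge[, 2L]] <- phy$edge.length
  bl
}

# path length from the root to every node
node_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  bl <- node_branch_lengths(phy)
  d <- numeric(n)
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(e))) d[e[i, 2L]] <- d[e[i, 1L]] + bl[e[i, 2L]]
  d
}

# number of edges from the root to every node
node_topo_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  d <- integer(n)
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(e))) d[e[i, 2L]] <- d[e[i, 1L]] + 1L
  d
}

# list mapping every node to the tip indices below it (tips map to themselves)
node_tip_sets <- function(phy) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  out <- vector("list", n)
  for (i in seq_len(nt)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  e <- phy$edge
  for (i in seq_len(nrow(e))) ch[[e[i, 1L]]] <- c(ch[[e[i, 1L]]], e[i, 2L])
  ch
}

parent_vec <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  p <- rep(NA_integer_, n)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

# Re-root `phy` on the edge above `child`, at distance `pos` above the child
# end. Returns a phylo whose root has the former child subtree on one side.
reroot_at_edge <- function(phy, child, pos) {
  tl <- as_treelist(phy)
  stopifnot(!is.na(tl$parent[child]))
  len <- tl$bl[child]
  stopifnot(pos >= 0, pos <= len + 1e-12)
  pos <- min(max(pos, 0), len)
  newroot <- tl$n + 1L
  tl$n <- newroot
  tl$parent <- c(tl$parent, NA_integer_)
  tl$bl <- c(tl$bl, NA_real_)
  tl$label <- c(tl$label, NA_character_)
  tl$children <- c(tl$children, list(integer(0)))
  u <- tl$parent[child]
  # path from u up to the old root, to be reversed
  path <- integer(0)
  v <- u
  while (!is.na(v)) { path <- c(path, v); v <- tl$parent[v] }
  old_bl <- tl$bl
  # detach child from u; hang child and u off the new root
  tl$children[[u]] <- setdiff(tl$children[[u]], child)
  tl$children[[newroot]] <- c(child, u)
  tl$parent[child] <- newroot
  tl$bl[child] <- pos
  tl$parent[u] <- newroot
  tl$bl[u] <- len - pos
  # reverse edges along the old root path: parent(path[k+1]) becomes path[k]
  if (length(path) > 1L) {
    for (k in seq_len(length(path) - 1L)) {
      lo <- path[k]; hi <- path[k + 1L]
      tl$children[[hi]] <- setdiff(tl$children[[hi]], lo)
      tl$children[[lo]] <- c(tl$children[[lo]], hi)
      tl$parent[hi] <- lo
      tl$bl[hi] <- old_bl[lo]
    }
  }
  tl$root <- newroot
  treelist_to_phylo(tl)
}

# Prune the clade rooted at `node` (with its stem) and return both parts.
# The remaining tree has the freed degree-2 node suppressed.
split_subtree <- function(phy, node) {
  tips <- node_tip_sets(phy)[[node]]
  sub <- if (length(tips) == 1L) {
    # single-leaf "clade": represent as a one-tip phylo
    one <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = 0,
                tip.label = phy$tip.label[tips], Nnode = 1L)
    class(one) <- "phylo"
    one
  } else ape::extract.clade(phy, node)
  rest <- ape::drop.tip(phy, tips, collapse.singles = TRUE)
  list(clade = sub, rest = rest,
       stem = node_branch_lengths(phy)[node],
       clade_tips = phy$tip.label[tips])
}

# Attach `sub` (a phylo) as the sister of the clade whose tip set is
# `sister_tips` (labels) in `phy`. A new junction node is created above the
# sister clade root: its stem to the old parent gets length `attach_len`,
# the sister keeps its original stem, and `sub` hangs with stem `stem_len`.
attach_sister <- function(phy, sub, sister_tips, stem_len, attach_len) {
  tl <- as_treelist(phy)
  idx <- match(sister_tips, tl$label)
  stopifnot(!anyNA(idx))
  at <- if (length(idx) == 1L) idx else ape::getMRCA(phy, sister_tips)
  if (is.na(tl$parent[at]))
    input_error("cannot attach as sister of the tree root")
  st <- as_treelist(sub)
  off <- tl$n
  # merge node arrays
  tl$parent <- c(tl$parent, ifelse(is.na(st$parent), NA_integer_, st$parent + off))
  tl$bl <- c(tl$bl, st$bl)
  tl$label <- c(tl$label, st$label)
  tl$children <- c(tl$children, lapply(st$children, function(x) x + off))
  subroot <- st$root + off
  n_old <- tl$n
  tl$n <- length(tl$parent)
  # new junction node
  j <- tl$n + 1L
  tl$n <- j
  tl$parent <- c(tl$parent, NA_integer_)
  tl$bl <- c(tl$bl, NA_real_)
  tl$label <- c(tl$label, NA_character_)
  tl$children <- c(tl$children, list(integer(0)))
  p <- tl$parent[at]
  tl$children[[p]][tl$children[[p]] == at] <- j
  tl$parent[j] <- p
  tl$bl[j] <- attach_len
  tl$children[[j]] <- c(at, subroot)
  tl$parent[at] <- j
  tl$parent[subroot] <- j
  tl$bl[subroot] <- stem_len
  treelist_to_phylo(tl)
}
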