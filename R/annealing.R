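# Cluster annealing: greedy set-cover superclustering of a profile
# similarity graph, and partitioning of trees into well separated leaf
# sets via a 2-D embedding of the patristic distance matrix plus
# gap-based density clustering.

#' Greedy set-cover superclustering
#'
#' Edges are filtered by similarity probability and pairwise coverage;
#' the node with the largest uncovered closed neighborhood (ties broken
#' lexicographically) seeds a new supercluster absorbing its uncovered
#' neighbors, until every node is covered.
#'
#' @param graph data frame with columns `a`, `b`, `probability`,
#'   `coverage`; self-edges are ignored.
#' @param p_min,cov_min edge filters in `[0, 1]`.
#' @param nodes optional full node universe (defaults to all edge
#'   endpoints); isolated nodes become singletons.
#' @return data frame (node, cluster, representative); clusters numbered
#'   in creation order.
#' @export
greedy_set_cover <- function(graph, p_min = 0.8, cov_min = 0.5,
                             nodes = NULL) {
  stopifnot(p_min >= 0, p_min <= 1, cov_min >= 0, cov_min <= 1)
  nodes <- sort(unique(c(nodes, as.character(graph$a), as.character(graph$b))))
  keep <- graph$probability >= p_min & graph$coverage >= cov_min &
    as.character(graph$a) != as.character(graph$b)
  g <- graph[keep, , drop = FALSE]
  adj <- lapply(setNames(nodes, nodes), function(x) character(0))
  for (i in seq_len(nrow(g))) {
    a <- as.character(g$a[i]); b <- as.character(g$b[i])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, unique)
  covered <- setNames(logical(length(nodes)), nodes)
  cluster <- setNames(integer(length(nodes)), nodes)
  rep_of <- setNames(character(length(nodes)), nodes)
  k <- 0L
  while (!all(covered)) {
    gain <- vapply(nodes, function(v) {
      if (covered[v]) -1L else sum(!covered[c(v, adj[[v]])])
    }, 0L)
    pick <- nodes[which(gain == max(gain))]
    pick <- sort(pick)[1L]
    members <- c(pick, adj[[pick]])
    members <- members[!covered[members]]
    k <- k + 1L
    covered[members] <- TRUE
    cluster[members] <- k
    rep_of[members] <- pick
  }
  data.frame(node = nodes, cluster = unname(cluster),
             representative = unname(rep_of), row.names = NULL)
}

#' Classical-scaling embedder for tree partitioning
#'
#' Deterministic 2-D embedding of a distance matrix by classical metric
#' multidimensional scaling. The sign of each axis is fixed so the
#' embedding is reproducible.
#'
#' @param D square distance matrix.
#' @param seed ignored (the embedding is deterministic); part of the
#'   strategy contract.
#' @return n x 2 coordinate matrix.
#' @export
embed_cmdscale <- function(D, seed = NULL) {
  n <- nrow(D)
  pts <- cmdscale(stats::as.dist(D), k = min(2L, n - 1L))
  if (ncol(pts) < 2L) pts <- cbind(pts, 0)
  for (j in 1:2) {
    s <- sign(pts[which.max(abs(pts[, j])), j])
    if (s < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  pts
}

#' Gap-based density clusterer for embedded leaves
#'
#' Single-linkage merge heights are scanned for the largest
#' multiplicative jump; if it exceeds `gap_ratio` the dendrogram is cut
#' below the jump, otherwise a single cluster is returned (trees with a
#' uniform distribution of pairwise distances stay whole). Clusters
#' smaller than `min_size` are treated as noise and reassigned to the
#' nearest surviving cluster centroid.
#'
#' @param pts n x 2 coordinates.
#' @param seed ignored (deterministic); part of the strategy contract.
#' @param min_size minimum cluster size.
#' @param gap_ratio jump factor that warrants a split.
#' @return integer vector of cluster labels (1-based).
#' @export
cluster_density_gap <- function(pts, seed = NULL, min_size = 5L,
                                gap_ratio = 8) {
  n <- nrow(pts)
  if (n < 2L) return(rep(1L, n))
  hc <- hclust(dist(pts), method = "single")
  h <- hc$height
  lab <- rep(1L, n)
  if (length(h) >= 2L) {
    floorv <- max(max(h) * 1e-9, 1e-300)
    ratios <- h[-1L] / pmax(h[-length(h)], floorv)
    i <- which.max(ratios)
    if (ratios[i] >= gap_ratio) {
      k <- n - i
      lab <- cutree(hc, k = k)
    }
  }
  sizes <- table(lab)
  big <- as.integer(names(sizes)[sizes >= min_size])
  if (length(big) >= 2L && length(big) < length(sizes)) {
    cent <- t(vapply(big, function(cl)
      colMeans(pts[lab == cl, , drop = FALSE]), numeric(2L)))
    noise <- which(!(lab %in% big))
    for (v in noise) {
      d2 <- rowSums(sweep(cent, 2L, pts[v, ])^2)
      lab[v] <- big[which.min(d2)]
    }
  } else if (length(big) < 2L) {
    lab <- rep(1L, n)
  }
  as.integer(factor(lab, levels = unique(lab)))
}

#' Partition a tree into well separated leaf sets
#'
#' Computes the patristic distance matrix, embeds it in two dimensions and
#' density-clusters the embedding. Single-cluster partitions are allowed
#' and expected for trees with uniform pairwise distances. Each partition
#' is reported with its induced monophyly fraction (partition size over
#' the size of its leaves' MRCA subtree).
#'
#' @param tree `phylo` with at least 3 leaves.
#' @param embedder,clusterer injected strategies with a
#'   determinism-under-seed contract; see [embed_cmdscale()] and
#'   [cluster_density_gap()].
#' @param seed forwarded to the strategies.
#' @param ... forwarded to the clusterer.
#' @return list with `assignment` (named integer vector leaf ->
#'   partition), `n_partitions`, `monophyly` (fraction per partition).
#' @export
partition_tree <- function(tree, embedder = embed_cmdscale,
                           clusterer = cluster_density_gap, seed = NULL,
                           ...) {
  stopifnot(ape::Ntip(tree) >= 3L)
  D <- cophenetic(tree)
  pts <- tryCatch(embedder(D, seed = seed), error = function(e) NULL)
  if (is.null(pts)) {
    warning("embedding failed; returning identity partition")
    lab <- rep(1L, ape::Ntip(tree))
  } else {
    lab <- clusterer(pts, seed = seed, ...)
  }
  names(lab) <- rownames(D) %||% tree$tip.label
  mono <- vapply(sort(unique(lab)), function(cl) {
    tips <- names(lab)[lab == cl]
    if (length(tips) == 1L) return(1)
    node <- ape::getMRCA(tree, tips)
    length(tips) / length(node_tip_sets(tree)[[node]])
  }, 0)
  list(assignment = lab, n_partitions = length(unique(lab)),
       monophyly = mono)
}
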