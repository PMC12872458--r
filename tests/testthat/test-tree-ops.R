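test_that("log-normal pruning skips degenerate and removes seeded outliers", {
  # equal branch lengths: sigma = 0, nothing strictly exceeds the cut
  tr <- ape::rphylo(100, 1, 0)
  tr$edge.length[] <- 0.1
  res <- fit_lognormal_prune(tr)
  expect_identical(ape::Ntip(res$tree), 100L)
  expect_length(res$removed, 0L)
  # 199 log-normal branches plus one branch of length 50
  set.seed(61)
  tr2 <- ape::rphylo(100, 1, 0)  # 198 edges
  tr2$edge.length <- exp(rnorm(nrow(tr2$edge), -2, 0.25))
  leaf_edge <- which(tr2$edge[, 2] == 1L)
  tr2$edge.length[leaf_edge] <- 50
  res2 <- fit_lognormal_prune(tr2)
  expect_identical(res2$removed, list(tr2$tip.label[1L]))
  expect_false(tr2$tip.label[1L] %in% res2$tree$tip.label)
  expect_equal(res2$model$upper_cut,
               exp(res2$model$mu + res2$model$sigma * qnorm(0.995)))
  # fewer than 10 positive branches: skip
  small <- ape::read.tree(text = "((a:1,b:1):1,(c:30,d:1):1);")
  expect_identical(ape::Ntip(fit_lognormal_prune(small)$tree), 4L)
})

test_that("pruning the eukaryotic stem discards the family", {
  sim <- simulate_gene_tree(sim_config(seed = 13L))
  tr <- sim$tree
  en <- ape::getMRCA(tr, sim$truth$euk_clades[[1L]])
  e <- which(tr$edge[, 2] == en)
  tr$edge.length[e] <- 60   # stretch the stem into an outlier
  err <- tryCatch(fit_lognormal_prune(tr, sim$taxonomy),
                  epoc_discarded = identity)
  expect_s3_class(err, "epoc_discarded")
  expect_identical(discard_reason(err), "outlier_overprune")
})

test_that("clean log-normal trees flag about 0.5% of branches", {
  frac <- vapply(1:20, function(seed) {
    set.seed(seed)
    tr <- ape::rphylo(60, 1, 0)
    tr$edge.length <- exp(rnorm(nrow(tr$edge), -2, 0.4))
    res <- fit_lognormal_prune(tr)
    mean(tr$edge.length > res$model$upper_cut)
  }, 0)
  expect_lte(mean(frac), 0.02)
})

test_that("weighted midpoint rooting solves the two-leaf case exactly", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.1);")
  rooted <- weighted_midpoint_root(tr)
  expect_equal(attr(rooted, "balance"), 0)
  d <- epocflow:::node_depths(rooted)
  expect_equal(unname(d[1:2]), c(0.2, 0.2))
})

test_that("midpoint rooting is minimal, symmetric and idempotent", {
  # symmetric balanced tree: zero imbalance at the original midpoint
  sym <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  r1 <- weighted_midpoint_root(sym)
  expect_equal(attr(r1, "balance"), 0)
  # idempotence: re-rooting a balanced tree keeps balance and topology
  r2 <- weighted_midpoint_root(r1)
  expect_equal(attr(r2, "balance"), 0)
  expect_true(ape::all.equal.phylo(r1, r2, use.edge.length = TRUE))
  # minimality versus exhaustive edge/offset scan on random trees
  set.seed(77)
  for (i in 1:8) {
    tr <- ape::rphylo(sample(5:12, 1), 1, 0)
    tr$edge.length <- rexp(nrow(tr$edge), 5)
    got <- attr(weighted_midpoint_root(tr), "balance")
    expect_lte(got, brute_force_min_balance(tr) + 1e-9)
  }
})

test_that("soft-LCA scores reproduce the printed formula", {
  # pure, complete clade: score 1
  tr <- ape::read.tree(
    text = "(((X_1:1,X_2:1):1,(X_3:1,(X_4:1,X_5:1):1):1):1,(Y_1:1,Y_2:1):1);")
  tax <- toy_taxonomy(tr$tip.label)
  sc <- soft_lca_scan(tr, tax, "X")
  expect_equal(max(sc$score), 1)
  top <- sc[1, ]
  expect_identical(top$size, 5L)
  # 3 of label X in a clade of 4, with 6 X total: (3/4)*(3/6) = 0.375
  tr2 <- ape::read.tree(text = paste0(
    "(((X_1:1,X_2:1):1,(X_3:1,Y_1:1):1):1,",
    "((X_4:1,X_5:1):1,(X_6:1,Y_2:1):1):1);"))
  tax2 <- toy_taxonomy(tr2$tip.label)
  sc2 <- soft_lca_scan(tr2, tax2, "X")
  n4 <- ape::getMRCA(tr2, c("X_1", "X_2", "X_3", "Y_1"))
  expect_equal(sc2$score[sc2$node == n4], (3 / 4) * (3 / 6))
  # tree root with 10 leaves, 6 X: (6/10)*(6/6) = 0.6
  tr3 <- ape::read.tree(text = paste0(
    "(((X_1:1,X_2:1):1,(X_3:1,X_4:1):1):1,",
    "((X_5:1,X_6:1):1,((Y_1:1,Y_2:1):1,(Y_3:1,Y_4:1):1):1):1);"))
  sc3 <- soft_lca_scan(tr3, toy_taxonomy(tr3$tip.label), "X")
  root <- ape::Ntip(tr3) + 1L
  expect_equal(sc3$score[sc3$node == root], 0.6)
  # absent label: empty result
  expect_identical(nrow(soft_lca_scan(tr3, toy_taxonomy(tr3$tip.label), "Z")), 0L)
})

test_that("soft-LCA scan equals exhaustive all-node scoring", {
  set.seed(19)
  for (i in 1:20) {
    nt <- sample(6:20, 1)
    tr <- ape::rphylo(nt, 1, 0)
    tr$tip.label <- paste0(sample(c("A", "B", "C"), nt, replace = TRUE),
                           "_", seq_len(nt))
    tax <- toy_taxonomy(tr$tip.label)
    for (lab in c("A", "B")) {
      got <- soft_lca_scan(tr, tax, lab)
      want <- brute_force_soft_lca(tr, tax, lab)
      expect_setequal(got$node, want$node)
      expect_equal(got$score[order(got$node)],
                   want$score[order(want$node)], tolerance = 1e-12)
    }
  }
})

test_that("clade validity follows the size and strict purity rules", {
  # prokaryotic clade of exactly 3, purity 1: valid
  tr <- ape::read.tree(text = paste0(
    "(((P_1:1,P_2:1):1,P_3:1):1,",
    "(((euk_1:1,euk_2:1):1,(euk_3:1,euk_4:1):1):1,(euk_5:1,Q_1:4):1):1);"))
  tax <- toy_taxonomy(tr$tip.label)
  calls <- detect_clades(tr, tax)
  p <- calls[calls$label == "P", ]
  expect_true(p$valid && p$size == 3L)
  # eukaryotic clade: 6 leaves, 5 eukaryote (purity 5/6 > 0.8) valid;
  # a clade at exactly purity 0.8 must be invalid (strict inequality)
  e <- calls[calls$domain == "eukaryote", ]
  expect_true(any(e$valid))
  tr2 <- ape::read.tree(text = paste0(
    "((P_1:1,(P_2:1,P_3:1):1):1,",
    "((((euk_1:1,euk_2:1):1,(euk_3:1,euk_4:1):1):1,Q_1:6):1,Q_2:6):1);"))
  # eukaryote-containing clades have purity 4/5 = 0.8 and 4/6; neither valid
  err <- tryCatch(detect_clades(tr2, toy_taxonomy(tr2$tip.label)),
                  epoc_discarded = identity)
  expect_identical(discard_reason(err), "no_euk_clade")
})

test_that("high eukaryotic paraphyly discards the family", {
  # four valid eukaryotic clades, each isolated by a prokaryotic sibling
  # so that no two of them merge into one pure clade
  blocks <- vapply(1:4, function(k)
    sprintf("(euk%d_1:.1,(euk%d_2:.1,(euk%d_3:.1,(euk%d_4:.1,euk%d_5:.1):.1):.1):.1)",
            k, k, k, k, k), "")
  pg <- vapply(c("P", "Q", "R", "S"), function(p)
    sprintf("(%s_1:.1,(%s_2:.1,%s_3:.1):.1)", p, p, p), "")
  txt <- sprintf("(((%s:1,%s:1):1,(%s:1,%s:1):1):1,((%s:1,%s:1):1,(%s:1,%s:1):1):1);",
                 blocks[1], pg[1], blocks[2], pg[2],
                 blocks[3], pg[3], blocks[4], pg[4])
  tr <- ape::read.tree(text = txt)
  tax <- toy_taxonomy(tr$tip.label)
  err <- tryCatch(detect_clades(tr, tax), epoc_discarded = identity)
  expect_identical(discard_reason(err), "paraphyly")
  # without the check flag the calls are returned and disjoint per label
  calls <- detect_clades(tr, tax, check = FALSE)
  euk <- calls[calls$domain == "eukaryote", ]
  expect_identical(sum(euk$valid), 4L)
  tipsets <- epocflow:::node_tip_sets(tr)
  all_tips <- unlist(lapply(euk$node, function(v) tipsets[[v]]))
  expect_identical(anyDuplicated(all_tips), 0L)
})

test_that("topological distance counts non-root internal nodes between", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  ab <- ape::getMRCA(tr, c("a", "b"))
  cd <- ape::getMRCA(tr, c("c", "d"))
  ef <- ape::getMRCA(tr, c("e", "f"))
  abcd <- ape::getMRCA(tr, c("a", "c"))
  # sister clades sharing a non-root parent
  expect_identical(topological_distance(tr, ab, cd), 1L)
  # across the root: the root itself is excluded
  expect_identical(topological_distance(tr, ab, ef), 1L)
  expect_identical(topological_distance(tr, ab, ab), 0L)
  # four-tip case: a to c crosses two non-root internals in this rooting
  tr4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  na <- which(tr4$tip.label == "a")
  nc <- which(tr4$tip.label == "c")
  expect_identical(topological_distance(tr4, na, nc), 2L)
})
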