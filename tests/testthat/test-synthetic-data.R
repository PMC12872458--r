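test_that("simulate_gene_tree places the donor as the eukaryotic sister", {
  for (seed in c(3L, 17L, 91L)) {
    cfg <- sim_config(n_prok_classes = 10L, donor_label = "Asgard",
                      seed = seed)
    sim <- simulate_gene_tree(cfg)
    tr <- sim$tree
    euk <- sim$truth$euk_clades[[1L]]
    expect_true(all(euk %in% tr$tip.label))
    en <- ape::getMRCA(tr, euk)
    tipsets <- epocflow:::node_tip_sets(tr)
    # the eukaryotic clade is monophyletic in the true tree
    expect_setequal(tr$tip.label[tipsets[[en]]], euk)
    # sister subtree (parent-node identity) carries only the donor class
    par <- epocflow:::parent_vec(tr)
    sib <- setdiff(epocflow:::children_list(tr)[[par[en]]], en)
    sib_classes <- unique(sub("_[0-9]+$", "", tr$tip.label[tipsets[[sib]]]))
    expect_identical(sib_classes, "Asgard")
    # stem branch equals the configured truth
    expect_equal(epocflow:::node_branch_lengths(tr)[en], cfg$stem_length)
    # exactly one clade of the donor label exists
    expect_identical(sim$truth$donor_label, "Asgard")
  }
})

test_that("a zero stem puts the eukaryotic root at its sister's parent", {
  cfg <- sim_config(stem_length = 0, seed = 5L)
  sim <- simulate_gene_tree(cfg)
  en <- ape::getMRCA(sim$tree, sim$truth$euk_clades[[1L]])
  expect_identical(epocflow:::node_branch_lengths(sim$tree)[en], 0)
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 123L, hgt_rate = 0.5, n_outliers = 1L)
  a <- simulate_gene_tree(cfg)
  b <- simulate_gene_tree(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$taxonomy, b$taxonomy)
  ea <- simulate_epoc(cfg, model = poisson_model())
  eb <- simulate_epoc(cfg, model = poisson_model())
  expect_identical(ea$alignment, eb$alignment)
})

test_that("eukaryotic clades of >= 2 leaves cover both deep supergroups", {
  hits <- vapply(1:50, function(seed) {
    sim <- simulate_gene_tree(sim_config(seed = seed, euk_leaves = c(6L, 10L)))
    sg <- sim$taxonomy$supergroup[sim$taxonomy$domain == "eukaryote"]
    any(sg == "Amorphea") && any(sg == "Diaphoretickes")
  }, TRUE)
  expect_true(all(hits))  # guaranteed by construction, prob >= 0.99 contract
})

test_that("an unknown donor label is a configuration error", {
  expect_error(sim_config(donor_label = "Atlantis"), class = "epocflow_error")
})

test_that("evolve_alignment respects degenerate branch lengths and seeds", {
  m <- poisson_model()
  tr <- ape::rphylo(6, 1, 0)
  tr0 <- tr
  tr0$edge.length[] <- 0
  aln <- evolve_alignment(tr0, m, 40, seed = 2)
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) == 1L)))
  a1 <- evolve_alignment(tr, m, 40, seed = 2)
  a2 <- evolve_alignment(tr, m, 40, seed = 2)
  a3 <- evolve_alignment(tr, m, 40, seed = 3)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  trbad <- tr
  trbad$edge.length[1] <- -0.1
  expect_error(evolve_alignment(trbad, m, 5), class = "epocflow_error")
})

test_that("near-saturation pairwise identity approaches sum(pi^2)", {
  m <- lg_model(gamma_alpha = Inf, n_rate_categories = 1L)
  tr <- ape::read.tree(text = "(a:5.0,b:5.0);")
  aln <- evolve_alignment(tr, m, 10000, seed = 9)
  ident <- mean(aln["a", ] == aln["b", ])
  expected <- sum(m$pi^2)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(ident - expected), 4 * se)
})

test_that("HGT injection is recorded and breaks host-clade purity", {
  cfg <- sim_config(seed = 31L, hgt_rate = 0)
  ep <- simulate_epoc(cfg, model = poisson_model())
  ep2 <- inject_hgt_leaf(ep, seed = 7L)
  expect_length(ep2$truth$injected_hgt, 1L)
  leaf <- ep2$truth$injected_hgt
  expect_true(leaf %in% ep2$tree$tip.label)
  expect_true(leaf %in% rownames(ep2$alignment))
  # purity of the eukaryotic host clade drops below 1 as recomputed by
  # the soft-LCA machinery
  host <- ep2$truth$euk_clades[[1L]]
  en <- ape::getMRCA(ep2$tree, c(host, leaf))
  sc <- soft_lca_scan(ep2$tree, ep2$taxonomy, "eukaryote", by_domain = TRUE)
  expect_lt(sc$purity[sc$node == en], 1)
  # hgt_rate = 0 leaves the family unchanged
  ep3 <- simulate_epoc(sim_config(seed = 31L, hgt_rate = 0),
                       model = poisson_model())
  expect_length(ep3$truth$injected_hgt, 0L)
})

test_that("generate_epoc_set writes a deterministic manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(n_prok_classes = 4L, leaves_per_class = c(2L, 3L),
                    euk_leaves = c(3L, 4L), n_sites = 20L)
  m0 <- generate_epoc_set(cfg, 0L, file.path(dir1, "empty"), seed = 1L)
  expect_identical(nrow(read.delim(m0)), 0L)
  m1 <- generate_epoc_set(cfg, 3L, file.path(dir1, "a"), seed = 4L)
  m2 <- generate_epoc_set(cfg, 3L, file.path(dir2, "b"), seed = 4L)
  man1 <- read.delim(m1)
  expect_identical(nrow(man1), 3L)
  expect_identical(unname(tools::md5sum(m1)), unname(tools::md5sum(m2)))
  # serialized family round-trips
  aln <- read_alignment(file.path(dir1, "a", "epoc0001.fasta"))
  tr <- ape::read.tree(file.path(dir1, "a", "epoc0001.nwk"))
  tax <- read_taxonomy(file.path(dir1, "a", "epoc0001.taxonomy.tsv"))
  expect_setequal(rownames(aln), tr$tip.label)
  expect_setequal(tax$id, tr$tip.label)
})
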