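toy_records <- function() {
  read.delim(system.file("extdata", "core_filter_toy.tsv",
                         package = "epocflow"))
}

test_that("soft-core pangenome thresholds are inclusive", {
  mk <- function(n_hit) {
    specs <- sprintf("sp%02d", 1:10)
    rbind(
      data.frame(cluster_id = "c1", species_id = specs[seq_len(n_hit)],
                 class_label = "Alphaproteobacteria", domain = "prokaryote"),
      # a second cluster covering all species defines the class total
      data.frame(cluster_id = "c0", species_id = specs,
                 class_label = "Alphaproteobacteria", domain = "prokaryote"))
  }
  # 5 of 10 species: kept at threshold 0.5 ("at least 50%")
  r5 <- soft_core_pangenome(mk(5L))
  expect_true("c1" %in% r5$retained)
  # 4 of 10: dropped
  r4 <- soft_core_pangenome(mk(4L))
  expect_false("c1" %in% r4$retained)
  # threshold 1.0 with full coverage: kept
  r10 <- soft_core_pangenome(mk(10L), prok_frac = 1)
  expect_true("c1" %in% r10$retained)
  # eukaryotic classes use the eukaryotic fraction
  eu <- data.frame(cluster_id = c("c1", "c1", "c0", "c0", "c0", "c0", "c0"),
                   species_id = c("e1", "e2", "e1", "e2", "e3", "e4", "e5"),
                   class_label = "Metazoa", domain = "eukaryote")
  re <- soft_core_pangenome(eu)   # 2/5 = 0.4 >= 0.2
  expect_true("c1" %in% re$retained)
  expect_error(soft_core_pangenome(mk(5L)[, -3]), class = "epocflow_error")
})

test_that("core_set_filter reproduces the toy fixture exactly", {
  rec <- toy_records()
  res <- core_set_filter(rec)
  expect_identical(nrow(res$core), 17L)
  expect_identical(nrow(res$rejected), 23L)
  expect_identical(nrow(res$core) + nrow(res$rejected), nrow(rec))
  counts <- table(res$rejected$reason)
  expect_identical(as.integer(counts[["no_annotation"]]), 4L)
  expect_identical(as.integer(counts[["too_few_labels"]]), 4L)
  expect_identical(as.integer(counts[["missing_supergroup"]]), 4L)
  expect_identical(as.integer(counts[["low_elw"]]), 10L)
  expect_identical(as.integer(counts[["high_elw"]]), 1L)
  # the whole-family low-quality drop is logged at EPOC scope
  e14 <- res$rejected[res$rejected$epoc_id == "e14", ]
  expect_identical(unique(e14$scope), "epoc")
  expect_identical(unique(e14$reason), "low_elw")
  # exception: ELW = 1 kept for Alphaproteobacteria / oxidative phosphorylation
  expect_true(any(res$core$epoc_id == "e16" &
                    res$core$candidate_label == "Alphaproteobacteria"))
  # near-1 ELW without the exception is rejected as suspected late HGT
  expect_true(any(res$rejected$epoc_id == "e15" &
                    res$rejected$reason == "high_elw"))
})

test_that("the core set is order-independent", {
  rec <- toy_records()
  key <- function(d) sort(paste(d$epoc_id, d$candidate_label))
  got <- key(core_set_filter(rec)$core)
  # independent re-derivation applying the three rules in another order
  fam_max <- tapply(rec$elw, rec$epoc_id, max)
  exc <- rec$elw >= 1 - 1e-12 & rec$candidate_label == "Alphaproteobacteria" &
    rec$pathway == "oxidative_phosphorylation"
  ok_elw <- (rec$elw > 0.4 & rec$elw < 0.99) | exc
  ok_fam <- fam_max[as.character(rec$epoc_id)] >= 0.4
  ok_sg <- rec$has_amorphea & rec$has_diaphoretickes
  ok_lab <- rec$n_euk_labels > 5L
  ok_cat <- !is.na(rec$category) & nzchar(rec$category)
  want <- key(rec[ok_sg & ok_elw & ok_cat & ok_fam & ok_lab, ])
  expect_identical(got, want)
  # shuffling the input rows does not change the kept set
  set.seed(1)
  got2 <- key(core_set_filter(rec[sample(nrow(rec)), ])$core)
  expect_identical(got2, got)
})

test_that("strict subset applies its three thresholds at the boundaries", {
  rec <- toy_records()
  core <- core_set_filter(rec)$core
  strict <- strict_subset_filter(core)
  expect_identical(strict$epoc_id, "e17")  # the only qualifying record
  d <- data.frame(n_euk_labels = c(15L, 15L, 14L, 15L),
                  sister_size = c(20L, 20L, 20L, 19L),
                  elw = c(0.71, 0.70, 0.71, 0.71))
  kept <- strict_subset_filter(d)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$elw, 0.71)
  expect_identical(kept$n_euk_labels, 15L)
})

test_that("aELW aggregation averages per category and taxon", {
  rec <- data.frame(epoc_id = c("a", "b", "c"),
                    candidate_label = c("Asgard", "Asgard", "Myxococcota"),
                    elw = c(0.6, 0.8, 0.9),
                    category = c("ribosome", "ribosome", "nicotinate"))
  tab <- aelw_by_category(rec)
  expect_equal(tab$aelw[tab$category == "ribosome" & tab$taxon == "Asgard"], 0.7)
  expect_identical(tab$n[tab$category == "ribosome" & tab$taxon == "Asgard"], 2L)
  # single-record cell equals that record's ELW
  expect_equal(tab$aelw[tab$taxon == "Myxococcota"], 0.9)
  # empty categories are absent
  rec2 <- rec
  rec2$category[3] <- ""
  expect_false("Myxococcota" %in% aelw_by_category(rec2)$taxon)
  expect_true(all(tab$aelw >= 0 & tab$aelw <= 1))
})

test_that("relative aELW selects the best qualifying pathway per taxon", {
  tab <- data.frame(
    category = c("p1", "p1", "p2", "p2", "p3", "p3"),
    taxon = rep(c("Asgard", "Myxococcota"), 3),
    aelw = c(0.5, 0.5, 0.3, 0.6, 0.2, 0.9),
    n = c(15L, 10L, 30L, 10L, 10L, 9L))
  # pathway totals: p1 = 25, p2 = 40, p3 = 19; p3 never qualifies
  out <- relative_aelw_vs_reference(tab, reference = "Asgard",
                                    min_epocs = 20L)
  expect_identical(out$pathway, "p2")
  expect_equal(out$ratio, 2)
  # ratio 1 when equal on the best pathway
  out1 <- relative_aelw_vs_reference(tab[tab$category == "p1", ],
                                     reference = "Asgard", min_epocs = 20L)
  expect_equal(out1$ratio, 1)
  expect_error(relative_aelw_vs_reference(tab, reference = "Nessie"),
               class = "epocflow_error")
})
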