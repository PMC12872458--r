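# Seeded generator of synthetic gene families with known ground truth:
# a prokaryotic class backbone with Yule within-class subtrees, one to
# three eukaryotic clades attached to a chosen donor class by a stem of
# known length, sequences evolved under the inference model, and optional
# post-hoc HGT / long-branch injection to exercise the filters.

PROK_CLASSES <- c(
  "Asgard", "Alphaproteobacteria", "Betaproteobacteria",
  "Gammaproteobacteria", "Cyanobacteriota", "Actinomycetota", "Bacillota",
  "Bacteroidota", "Myxococcota", "Thermococci", "Halobacteria",
  "Methanomicrobia", "Nitrososphaeria", "Clostridia", "Spirochaetia",
  "Chlamydiia", "Deinococci", "Aquificae", "Thermotogae",
  "Planctomycetia", "Verrucomicrobiae", "Acidobacteriia", "Fusobacteriia",
  "Epsilonproteobacteria", "Chloroflexia", "Mollicutes")

EUK_CLASSES <- c(
  Metazoa = "Amorphea", Fungi = "Amorphea", Amoebozoa = "Amorphea",
  Choanoflagellata = "Amorphea", Streptophyta = "Diaphoretickes",
  Chlorophyta = "Diaphoretickes", Stramenopiles = "Diaphoretickes",
  Alveolata = "Diaphoretickes", Rhizaria = "Diaphoretickes",
  Haptista = "Diaphoretickes", Discoba = "other", Metamonada = "other")

CATEGORY_VOCAB <- c("ribosome", "oxidative_phosphorylation", "dna_replication",
                    "proteasome", "glycolysis", "nicotinate_metabolism")

#' Configuration for the synthetic gene-family generator
#'
#' Defaults describe a desk-scale family: 10 prokaryotic classes with 3-8
#' leaves each, one eukaryotic clade of 6-10 leaves whose true sister is
#' the Asgard class, a stem of 0.3 expected substitutions/site, 150
#' alignment columns under LG with gamma shape 1.
#'
#' @param n_prok_classes number of prokaryotic classes in the tree.
#' @param leaves_per_class integer range (min, max) of leaves per class.
#' @param donor_label class label of the true eukaryotic sister.
#' @param stem_length true stem length (expected substitutions/site).
#' @param n_sites alignment columns to simulate.
#' @param gamma_alpha gamma shape for rate heterogeneity.
#' @param n_euk_clades number of eukaryotic clades (1-3).
#' @param euk_leaves integer range of leaves per eukaryotic clade.
#' @param hgt_rate probability that a family receives one injected HGT leaf.
#' @param n_outliers number of leaf branches stretched into outliers.
#' @param outlier_scale multiplier applied to injected outlier branches.
#' @param category functional category label, or `NA` to draw from a small
#'   fixed vocabulary.
#' @param seed integer seed; fully determines the family.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_prok_classes = 10L, leaves_per_class = c(3L, 8L),
                       donor_label = "Asgard", stem_length = 0.3,
                       n_sites = 150L, gamma_alpha = 1,
                       n_euk_clades = 1L, euk_leaves = c(6L, 10L),
                       hgt_rate = 0, n_outliers = 0L, outlier_scale = 50,
                       category = NA_character_, seed = 1L) {
  stopifnot(stem_length >= 0, n_sites >= 1L,
            n_euk_clades >= 1L, n_euk_clades <= 3L,
            n_prok_classes >= 2L, n_prok_classes <= length(PROK_CLASSES))
  if (!donor_label %in% PROK_CLASSES)
    input_error(paste0("unknown donor class label: ", donor_label))
  out <- list(n_prok_classes = as.integer(n_prok_classes),
              leaves_per_class = as.integer(leaves_per_class),
              donor_label = donor_label, stem_length = stem_length,
              n_sites = as.integer(n_sites), gamma_alpha = gamma_alpha,
              n_euk_clades = as.integer(n_euk_clades),
              euk_leaves = as.integer(euk_leaves),
              hgt_rate = hgt_rate, n_outliers = as.integer(n_outliers),
              outlier_scale = outlier_scale, category = category,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

# Yule subtree with n tips rescaled to the given height (n = 1 allowed)
yule_subtree <- function(n, height, prefix) {
  if (n == 1L) {
    one <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = height,
                tip.label = paste0(prefix, "_1"), Nnode = 1L)
    class(one) <- "phylo"
    return(one)
  }
  phy <- ape::rphylo(n, birth = 1, death = 0)
  d <- max(node_depths(phy)[seq_len(n)])
  phy$edge.length <- phy$edge.length / d * height
  phy$tip.label <- paste0(prefix, "_", seq_len(n))
  phy
}

#' Simulate a gene tree with a known prokaryotic sister of Eukarya
#'
#' Prokaryotic classes hang as Yule subtrees off a Yule backbone; each
#' eukaryotic clade attaches next to the donor class by a stem branch of
#' the configured length. Eukaryotic leaves draw class labels so that both
#' Amorphea and Diaphoretickes occur whenever the clade has at least two
#' leaves.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (rooted `phylo`), `taxonomy`
#'   ([taxonomy_table()]) and `truth` (donor label per eukaryotic clade,
#'   true stem length, leaf-id sets of the eukaryotic clades, injected
#'   outlier branches and HGT leaves).
#' @export
simulate_gene_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    classes <- c(config$donor_label,
                 sample(setdiff(PROK_CLASSES, config$donor_label),
                        config$n_prok_classes - 1L))
    classes <- sample(classes)  # shuffle backbone positions
    backbone <- yule_subtree(config$n_prok_classes, 1, "bb")
    sizes <- sample(seq(config$leaves_per_class[1L],
                        config$leaves_per_class[2L]),
                    config$n_prok_classes, replace = TRUE)
    tree <- backbone
    for (i in seq_along(classes)) {
      sub <- yule_subtree(sizes[i], 0.25, classes[i])
      tip <- which(tree$tip.label == paste0("bb_", i))
      stem <- node_branch_lengths(tree)[tip]
      tl <- as_treelist(tree)
      st <- as_treelist(sub)
      off <- tl$n
      tl$parent <- c(tl$parent,
                     ifelse(is.na(st$parent), NA_integer_, st$parent + off))
      tl$bl <- c(tl$bl, st$bl)
      tl$label <- c(tl$label, st$label)
      tl$children <- c(tl$children, lapply(st$children, function(x) x + off))
      subroot <- st$root + off
      p <- tl$parent[tip]
      tl$children[[p]][tl$children[[p]] == tip] <- subroot
      tl$parent[subroot] <- p
      tl$bl[subroot] <- stem
      tl$label[tip] <- NA_character_
      tl$children[[tip]] <- integer(0)
      tl$n <- length(tl$parent)
      tree <- treelist_to_phylo(tl)
    }
    # attach eukaryotic clades above the donor clade root
    euk_sets <- vector("list", config$n_euk_clades)
    sister_tips <- tree$tip.label[startsWith(tree$tip.label,
                                             paste0(config$donor_label, "_"))]
    for (k in seq_len(config$n_euk_clades)) {
      ne <- sample(seq(config$euk_leaves[1L], config$euk_leaves[2L]), 1L)
      esub <- yule_subtree(ne, 0.3, paste0("euk", k))
      tree <- attach_sister(tree, esub, sister_tips,
                            stem_len = config$stem_length,
                            attach_len = 0.05)
      euk_sets[[k]] <- paste0("euk", k, "_", seq_len(ne))
      sister_tips <- c(sister_tips, euk_sets[[k]])
    }
    # taxonomy: eukaryotic class labels with guaranteed supergroup coverage
    ids <- tree$tip.label
    is_euk <- startsWith(ids, "euk")
    class_label <- sub("_[0-9]+$", "", ids)
    supergroup <- rep("not_applicable", length(ids))
    for (k in seq_len(config$n_euk_clades)) {
      eids <- euk_sets[[k]]
      labs <- sample(names(EUK_CLASSES), length(eids), replace = TRUE)
      if (length(eids) >= 2L) {
        sgs <- EUK_CLASSES[labs]
        if (!any(sgs == "Amorphea"))
          labs[1L] <- sample(names(EUK_CLASSES)[EUK_CLASSES == "Amorphea"], 1L)
        if (!any(EUK_CLASSES[labs] == "Diaphoretickes"))
          labs[2L] <- sample(names(EUK_CLASSES)[EUK_CLASSES == "Diaphoretickes"], 1L)
      }
      idx <- match(eids, ids)
      class_label[idx] <- labs
      supergroup[idx] <- EUK_CLASSES[labs]
    }
    taxonomy <- taxonomy_table(ids, class_label,
                               ifelse(is_euk, "eukaryote", "prokaryote"),
                               supergroup)
    truth <- list(donor_label = rep(config$donor_label, config$n_euk_clades),
                  stem_length = config$stem_length,
                  euk_clades = euk_sets,
                  injected_outliers = character(0),
                  injected_hgt = character(0))
    # optional long-branch outliers on prokaryotic leaf branches
    if (config$n_outliers > 0L) {
      prok_tips <- which(!startsWith(tree$tip.label, "euk"))
      pick <- sample(prok_tips, min(config$n_outliers, length(prok_tips)))
      for (v in pick) {
        e <- which(tree$edge[, 2L] == v)
        tree$edge.length[e] <- tree$edge.length[e] * config$outlier_scale
      }
      truth$injected_outliers <- tree$tip.label[pick]
    }
    list(tree = tree, taxonomy = taxonomy, truth = truth)
  })
}

#' Evolve an aligned set of sequences along a tree
#'
#' Draws the root sequence from the stationary frequencies and evolves it
#' along every branch under the model's transition probabilities, with
#' i.i.d. per-site rate multipliers from the discrete gamma. Alignments
#' are generated gap-free (no indel model).
#'
#' @param tree rooted `phylo` with finite non-negative branch lengths.
#' @param model a [substitution_model()].
#' @param n_sites number of columns.
#' @param seed integer seed.
#' @return character matrix (leaves x sites) with rownames = leaf ids.
#' @export
evolve_alignment <- function(tree, model, n_sites, seed = 1L) {
  bl <- tree$edge.length
  if (any(!is.finite(bl)) || any(bl < 0))
    input_error("branch lengths must be finite and non-negative")
  alph <- aa_alphabet()
  with_seed(seed, {
    ncat <- model$n_rate_categories
    rates <- discrete_gamma_rates(model$gamma_alpha, ncat)
    cat_of_site <- sample.int(ncat, n_sites, replace = TRUE)
    nt <- ape::Ntip(tree)
    n <- nt + tree$Nnode
    state <- matrix(0L, n, n_sites)
    root <- nt + 1L
    state[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
    e <- ape::reorder.phylo(tree, "cladewise")$edge
    ebl <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (i in seq_len(nrow(e))) {
      p <- e[i, 1L]; v <- e[i, 2L]
      for (k in seq_len(ncat)) {
        sel <- which(cat_of_site == k)
        if (!length(sel)) next
        P <- transition_matrix(model, ebl[i] * rates[k])
        ps <- state[p, sel]
        out <- integer(length(sel))
        for (s in 1:20) {
          at <- which(ps == s)
          if (length(at))
            out[at] <- sample.int(20L, length(at), replace = TRUE,
                                  prob = P[s, ])
        }
        state[v, sel] <- out
      }
    }
    m <- matrix(alph[state[seq_len(nt), , drop = FALSE]], nt, n_sites)
    rownames(m) <- tree$tip.label
    m
  })
}

#' Inject one horizontally transferred leaf into a gene family
#'
#' Grafts a prokaryote-labeled leaf inside a eukaryotic clade (exercising
#' the purity handling of clade detection) and records it in the truth
#' metadata. The injected sequence is the host sibling's sequence with a
#' seeded fraction of residues resampled. Families whose eukaryotic
#' clades are too small to host a graft are returned unchanged with a
#' warning.
#'
#' @param epoc a synthetic family as returned by [simulate_epoc()].
#' @param seed integer seed.
#' @param sub_frac fraction of sites resampled on the injected leaf.
#' @return the modified family.
#' @export
inject_hgt_leaf <- function(epoc, seed = 1L, sub_frac = 0.3) {
  with_seed(seed, {
    hosts <- Filter(function(x) length(x) >= 2L, epoc$truth$euk_clades)
    if (!length(hosts)) {
      warning("no eukaryotic clade large enough to host an HGT graft")
      return(epoc)
    }
    host <- hosts[[sample.int(length(hosts), 1L)]]
    sib <- sample(host, 1L)
    donor_class <- sample(setdiff(PROK_CLASSES,
                                  unique(epoc$taxonomy$class_label)), 1L)
    new_id <- paste0(donor_class, "_hgt1")
    sib_node <- which(epoc$tree$tip.label == sib)
    sib_bl <- node_branch_lengths(epoc$tree)[sib_node]
    leaf <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = 0,
                 tip.label = new_id, Nnode = 1L)
    class(leaf) <- "phylo"
    tree <- attach_sister(epoc$tree, leaf, sib,
                          stem_len = max(sib_bl, 0.05),
                          attach_len = sib_bl / 2)
    epoc$tree <- tree
    tax <- epoc$taxonomy
    tax <- rbind(tax, data.frame(id = new_id, class_label = donor_class,
                                 domain = "prokaryote",
                                 supergroup = "not_applicable"))
    class(tax) <- c("taxonomy_table", "data.frame")
    epoc$taxonomy <- tax
    if (!is.null(epoc$alignment)) {
      seq0 <- epoc$alignment[sib, ]
      flip <- runif(length(seq0)) < sub_frac
      seq0[flip] <- sample(aa_alphabet(), sum(flip), replace = TRUE)
      epoc$alignment <- rbind(epoc$alignment,
                              matrix(seq0, 1L,
                                     dimnames = list(new_id, NULL)))
    }
    epoc$truth$injected_hgt <- c(epoc$truth$injected_hgt, new_id)
    epoc
  })
}

#' Simulate one complete synthetic gene family
#'
#' Combines [simulate_gene_tree()], [evolve_alignment()] and the optional
#' HGT injection into a single object carrying alignment, tree, taxonomy,
#' functional category and truth metadata.
#'
#' @param config a [sim_config()].
#' @param model substitution model used for sequence evolution; defaults
#'   to LG with the configured gamma shape.
#' @return a list of class `"epoc"`.
#' @export
simulate_epoc <- function(config, model = NULL) {
  model <- model %||% lg_model(gamma_alpha = config$gamma_alpha)
  sim <- simulate_gene_tree(config)
  aln <- evolve_alignment(sim$tree, model, config$n_sites,
                          seed = config$seed + 1L)
  category <- config$category
  if (is.na(category))
    category <- with_seed(config$seed + 2L, sample(CATEGORY_VOCAB, 1L))
  out <- list(tree = sim$tree, alignment = aln, taxonomy = sim$taxonomy,
              truth = sim$truth, category = category, config = config)
  class(out) <- "epoc"
  if (config$hgt_rate > 0 &&
      with_seed(config$seed + 3L, runif(1L)) < config$hgt_rate)
    out <- inject_hgt_leaf(out, seed = config$seed + 4L)
  out
}

#' @export
print.epoc <- function(x, ...) {
  cat(sprintf("synthetic gene family: %d leaves, %d sites, donor %s, stem %g\n",
              ape::Ntip(x$tree), ncol(x$alignment),
              x$truth$donor_label[1L], x$truth$stem_length))
  invisible(x)
}

#' Generate a directory of synthetic gene families
#'
#' Serializes `n_families` families (FASTA alignment, Newick tree,
#' taxonomy TSV each) plus a manifest TSV of truth records. Per-family
#' seeds are derived deterministically from `seed`.
#'
#' @param config a [sim_config()] used as template.
#' @param n_families number of families.
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @return path of the manifest TSV, invisibly; the manifest data frame as
#'   attribute `"manifest"`.
#' @export
generate_epoc_set <- function(config, n_families, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    ep <- simulate_epoc(cfg)
    id <- sprintf("epoc%04d", i)
    write_alignment(ep$alignment, file.path(out_dir, paste0(id, ".fasta")))
    ape::write.tree(ep$tree, file.path(out_dir, paste0(id, ".nwk")))
    write_taxonomy(ep$taxonomy, file.path(out_dir, paste0(id, ".taxonomy.tsv")))
    rows[[i]] <- data.frame(epoc_id = id,
                            donor_label = ep$truth$donor_label[1L],
                            stem_length = ep$truth$stem_length,
                            category = ep$category, seed = cfg$seed)
  }
  manifest <- if (n_families > 0L) do.call(rbind, rows) else
    data.frame(epoc_id = character(0), donor_label = character(0),
               stem_length = numeric(0), category = character(0),
               seed = integer(0))
  mpath <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(mpath, "manifest") <- manifest
  invisible(mpath)
}
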