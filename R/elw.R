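# Constrained-topology hypothesis testing: enumerate candidate prokaryotic
# sisters by topological distance, regraft the eukaryotic clade next to
# each candidate, re-optimize branch lengths, and summarize support with
# expected likelihood weights estimated by RELL site resampling.

#' Enumerate candidate prokaryotic sister clades
#'
#' Candidates are ordered by increasing topological distance between the
#' eukaryotic clade root and the candidate clade root, ties broken by
#' label, and truncated to the `k` closest (default 12).
#'
#' @param tree rooted `phylo`.
#' @param euk_node node of the eukaryotic clade root.
#' @param prok_clades data frame of valid prokaryotic clade calls
#'   (columns `node`, `label`), as from [detect_clades()].
#' @param k maximum number of candidates.
#' @return the clade-call rows of the selected candidates, ordered, with a
#'   `topo_dist` column.
#' @export
enumerate_candidates <- function(tree, euk_node, prok_clades, k = 12L) {
  stopifnot(nrow(prok_clades) >= 1L)
  d <- vapply(prok_clades$node, function(v)
    topological_distance(tree, euk_node, v), 0L)
  out <- prok_clades
  out$topo_dist <- d
  out <- out[order(out$topo_dist, out$label), , drop = FALSE]
  head(out, k)
}

#' Build one constrained topology
#'
#' Prunes the eukaryotic clade from the master tree and re-attaches it as
#' the sister of the candidate clade root. The new stem and the branch
#' created at the attachment point are initialized to the pruned stem
#' length (floored at 0.01); all other branch lengths carry over. The
#' three constraint groups (eukaryotic clade, candidate, all remaining
#' prokaryotes) are each monophyletic in the result.
#'
#' @param master rooted `phylo`.
#' @param euk_tips leaf ids of the eukaryotic clade.
#' @param candidate_tips leaf ids of the candidate sister clade.
#' @return `phylo` with the same leaf set as `master`.
#' @export
build_constraint_topology <- function(master, euk_tips, candidate_tips) {
  if (any(candidate_tips %in% euk_tips))
    input_error("candidate clade overlaps the eukaryotic clade")
  euk_node <- if (length(euk_tips) == 1L)
    which(master$tip.label == euk_tips) else ape::getMRCA(master, euk_tips)
  below <- master$tip.label[node_tip_sets(master)[[euk_node]]]
  if (!setequal(below, euk_tips))
    input_error("eukaryotic clade is not monophyletic in the master tree")
  parts <- split_subtree(master, euk_node)
  stem0 <- max(parts$stem, 0.01, na.rm = TRUE)
  attach_sister(parts$rest, parts$clade, candidate_tips,
                stem_len = stem0, attach_len = stem0)
}

#' Expected likelihood weights by RELL resampling
#'
#' For each of `B` bootstrap replicates, site indices are resampled with
#' replacement (the same indices for every topology), replicate
#' log-likelihoods are computed by summation, and normalized likelihood
#' weights `exp(l_i - logsumexp(l))` are averaged over replicates.
#'
#' @param site_logliks matrix of per-site log-likelihoods, one row per
#'   topology, columns aligned across topologies.
#' @param B number of RELL replicates.
#' @param seed integer seed (mandatory for reproducible pipelines).
#' @return numeric vector of ELW values (rows of `site_logliks`), summing
#'   to one.
#' @export
rell_elw <- function(site_logliks, B = 1000L, seed = 1L) {
  stopifnot(is.matrix(site_logliks), nrow(site_logliks) >= 2L,
            ncol(site_logliks) >= 1L)
  if (B < 1L) input_error("B must be >= 1")
  S <- ncol(site_logliks)
  with_seed(seed, {
    w <- numeric(nrow(site_logliks))
    for (b in seq_len(B)) {
      counts <- tabulate(sample.int(S, S, replace = TRUE), nbins = S)
      ll <- as.numeric(site_logliks %*% counts)
      mx <- max(ll)
      z <- exp(ll - mx)
      w <- w + z / sum(z)
    }
    w / B
  })
}

#' Assign prokaryotic sisters to every eukaryotic clade of a family
#'
#' Full hypothesis-testing stage for one curated gene family: per valid
#' eukaryotic clade, candidate sisters are enumerated, a constrained
#' topology is built and branch-length-optimized for each, per-site
#' log-likelihoods are computed on the full trimmed alignment, and the
#' candidate ELW vector is estimated by RELL.
#'
#' @param tree curated, rooted master tree.
#' @param alignment trimmed character matrix.
#' @param taxonomy [taxonomy_table()].
#' @param model a [substitution_model()].
#' @param clades optional precomputed [detect_clades()] result.
#' @param k maximum number of candidate sisters per eukaryotic clade.
#' @param B RELL replicates.
#' @param seed integer seed.
#' @param opt_rounds branch-length optimization rounds per candidate
#'   topology (lengths carry over from the master tree, so one round
#'   typically suffices for ranking).
#' @param alpha gamma shape; when `NULL`, estimated on the master tree
#'   with [estimate_gamma_alpha()] and reused for all topologies.
#' @return list of per-eukaryotic-clade results, each with `euk_node`,
#'   `euk_tips`, `elw` (data frame: candidate label, elw, rank,
#'   topo_dist), `best` (label), `best_tree` (optimized topology of the
#'   best candidate), `alpha`, `n_sites`.
#' @export
assign_sisters <- function(tree, alignment, taxonomy, model,
                           clades = NULL, k = 12L, B = 1000L, seed = 1L,
                           opt_rounds = 1L, alpha = NULL) {
  clades <- clades %||% detect_clades(tree, taxonomy)
  prok <- clades[clades$valid & clades$domain == "prokaryote", , drop = FALSE]
  euk <- clades[clades$valid & clades$domain == "eukaryote", , drop = FALSE]
  if (nrow(prok) == 0L) epoc_discard("no_prok_clade")
  if (nrow(euk) == 0L) epoc_discard("no_euk_clade")
  if (is.null(alpha))
    alpha <- as.numeric(estimate_gamma_alpha(tree, alignment, model))
  tipsets <- node_tip_sets(tree)
  results <- vector("list", nrow(euk))
  for (i in seq_len(nrow(euk))) {
    cand <- enumerate_candidates(tree, euk$node[i], prok, k = k)
    euk_tips <- tree$tip.label[tipsets[[euk$node[i]]]]
    sll <- matrix(0, nrow(cand), ncol(alignment))
    topos <- vector("list", nrow(cand))
    for (j in seq_len(nrow(cand))) {
      cand_tips <- tree$tip.label[tipsets[[cand$node[j]]]]
      topo <- build_constraint_topology(tree, euk_tips, cand_tips)
      fit <- suppressWarnings(
        optimize_branch_lengths(topo, alignment, model, alpha = alpha,
                                max_rounds = opt_rounds))
      topos[[j]] <- fit$tree
      sll[j, ] <- site_loglik(fit$tree, alignment, model, alpha = alpha)
    }
    elw <- if (nrow(cand) == 1L) 1 else rell_elw(sll, B = B, seed = seed + i)
    tab <- data.frame(candidate_label = cand$label, elw = elw,
                      topo_dist = cand$topo_dist)
    tab <- tab[order(-tab$elw, tab$candidate_label), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    best_j <- which(cand$label == tab$candidate_label[1L])[1L]
    results[[i]] <- list(euk_node = euk$node[i], euk_tips = euk_tips,
                         elw = tab, best = tab$candidate_label[1L],
                         best_elw = tab$elw[1L],
                         best_tree = topos[[best_j]],
                         alpha = alpha, n_sites = ncol(alignment))
  }
  results
}

#' Run the full per-family pipeline
#'
#' Alignment trimming, long-branch pruning, weighted midpoint rooting,
#' clade detection, sister assignment by constrained-topology ELW, and
#' stem-length extraction for the best-supported sister. Families that
#' fail a quality-control rule are returned as a discard record rather
#' than raising.
#'
#' @param epoc a list with `tree`, `alignment`, `taxonomy` and optionally
#'   `category` (e.g. from [simulate_epoc()]).
#' @param model a [substitution_model()].
#' @param trim_bits information-content trimming threshold.
#' @param k,B,seed,opt_rounds passed to [assign_sisters()].
#' @return list of class `"epoc_result"`: `ok`, `reason` (when
#'   discarded), `clades`, `sisters`, `stems` (data frame of
#'   [StemRecord][stem_length()] rows).
#' @export
run_epoc_pipeline <- function(epoc, model = lg_model(), trim_bits = 0.15,
                              k = 12L, B = 1000L, seed = 1L,
                              opt_rounds = 1L) {
  out <- tryCatch({
    aln <- trim_alignment(epoc$alignment, trim_bits)
    if (ncol(aln) == 0L)
      input_error("no informative columns after trimming")
    pruned <- fit_lognormal_prune(epoc$tree, epoc$taxonomy)
    tree <- weighted_midpoint_root(pruned$tree)
    aln <- aln[tree$tip.label, , drop = FALSE]
    clades <- detect_clades(tree, epoc$taxonomy)
    sisters <- assign_sisters(tree, aln, epoc$taxonomy, model,
                              clades = clades, k = k, B = B, seed = seed,
                              opt_rounds = opt_rounds)
    stems <- do.call(rbind, lapply(seq_along(sisters), function(i) {
      s <- sisters[[i]]
      rec <- stem_record(s$best_tree, s$euk_tips)
      data.frame(euk_clade_id = i, sister_label = s$best,
                 SL = rec$SL, med_bl = rec$med_bl, NSL = rec$NSL,
                 best_elw = s$best_elw,
                 category = epoc$category %||% NA_character_)
    }))
    list(ok = TRUE, reason = NA_character_, tree = tree, clades = clades,
         sisters = sisters, stems = stems)
  }, epoc_discarded = function(e) {
    list(ok = FALSE, reason = discard_reason(e), clades = NULL,
         sisters = NULL, stems = NULL)
  })
  class(out) <- "epoc_result"
  out
}

#' @export
print.epoc_result <- function(x, ...) {
  if (!x$ok) {
    cat("gene family discarded:", x$reason, "\n")
  } else {
    for (i in seq_along(x$sisters)) {
      s <- x$sisters[[i]]
      cat(sprintf("eukaryotic clade %d: best sister %s (ELW %.3f)\n",
                  i, s$best, s$best_elw))
    }
  }
  invisible(x)
}
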