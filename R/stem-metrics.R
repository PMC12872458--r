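# FECA-to-LECA stem-length metrics: raw stem length (SL), rate
# normalization by the median eukaryotic root-to-leaf distance (NSL),
# bootstrap empirical CDFs, and Mann-Whitney comparisons across taxa.

#' Stem length between a eukaryotic clade and its sister
#'
#' The branch length from the common parent of the two clades (the FECA
#' proxy) to the eukaryotic clade root (the LECA proxy). The clades must
#' be sisters in the evaluated topology.
#'
#' @param tree rooted `phylo`.
#' @param euk_tips leaf ids of the eukaryotic clade.
#' @param sister_tips leaf ids of the sister clade.
#' @return stem length (substitutions/site).
#' @export
stem_length <- function(tree, euk_tips, sister_tips) {
  en <- clade_node(tree, euk_tips)
  sn <- clade_node(tree, sister_tips)
  par <- parent_vec(tree)
  if (is.na(par[en]) || is.na(par[sn]) || par[en] != par[sn])
    input_error("clades are not sisters in this topology")
  node_branch_lengths(tree)[en]
}

clade_node <- function(tree, tips) {
  if (length(tips) == 1L) which(tree$tip.label == tips)
  else ape::getMRCA(tree, tips)
}

#' Normalized stem length
#'
#' Divides the stem length by the median of the root-to-leaf path
#' distances within the eukaryotic clade (even counts take the mean of the
#' central pair). Invariant under uniform rescaling of all branch
#' lengths.
#'
#' @inheritParams stem_length
#' @return list with `SL`, `med_bl`, `NSL`; `NSL` is `NA` (with reason
#'   `"zero_depth"`) when all leaf depths are zero and the stem is
#'   positive.
#' @export
stem_record <- function(tree, euk_tips, sister_tips = NULL) {
  en <- clade_node(tree, euk_tips)
  SL <- if (is.null(sister_tips)) node_branch_lengths(tree)[en]
        else stem_length(tree, euk_tips, sister_tips)
  depths <- node_depths(tree)
  tipsets <- node_tip_sets(tree)
  leafs <- tipsets[[en]]
  med_bl <- median(depths[leafs] - depths[en])
  if (med_bl <= 0) {
    if (SL == 0) return(list(SL = 0, med_bl = med_bl, NSL = 0))
    return(list(SL = SL, med_bl = med_bl, NSL = NA_real_,
                reason = "zero_depth"))
  }
  list(SL = SL, med_bl = med_bl, NSL = SL / med_bl)
}

#' @rdname stem_record
#' @export
normalized_stem_length <- function(tree, euk_tips, sister_tips = NULL) {
  stem_record(tree, euk_tips, sister_tips)$NSL
}

#' Bootstrap empirical CDFs of normalized stem lengths
#'
#' Resamples the records with replacement `B` times and evaluates each
#' replicate's empirical CDF on a shared grid (by default 200 points from
#' 0 to the 99th percentile of the pooled values).
#'
#' @param nsl_values numeric vector (one NSL per gene family record).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param grid optional shared evaluation grid.
#' @return list with `grid`, `cdf` (point estimate on the grid) and
#'   `boot` (`B` x `length(grid)` matrix of replicate CDFs).
#' @export
bootstrap_cdf <- function(nsl_values, B = 200L, seed = 1L, grid = NULL) {
  x <- nsl_values[is.finite(nsl_values)]
  stopifnot(length(x) >= 2L)
  if (is.null(grid))
    grid <- seq(0, quantile(x, 0.99, names = FALSE), length.out = 200L)
  point <- ecdf(x)(grid)
  with_seed(seed, {
    boot <- matrix(0, B, length(grid))
    for (b in seq_len(B)) {
      xb <- sample(x, length(x), replace = TRUE)
      boot[b, ] <- ecdf(xb)(grid)
    }
    list(grid = grid, cdf = point, boot = boot)
  })
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' With `n_a + n_b <= exact_limit` the null distribution of U is obtained
#' by enumerating all assignments of the pooled mid-ranks to group A, so
#' ties are handled exactly; the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param exact_limit switch-over total sample size for enumeration.
#' @return list with `U` (statistic of sample A) and `p` (two-sided).
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_limit = 14L) {
  na <- length(sample_a); nb <- length(sample_b)
  stopifnot(na >= 1L, nb >= 1L)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_limit) {
    idx <- combn(na + nb, na)
    ra <- matrix(r[idx], nrow = na)
    Us <- colSums(ra) - na * (na + 1) / 2
    p_le <- mean(Us <= U + 1e-9)
    p_ge <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    n <- na + nb
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    if (abs(U - mu) < 0.5) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Per-grid-point comparison of bootstrap CDFs between two taxa
#'
#' At every grid NSL value, compares the distributions of bootstrap-CDF
#' values of the two taxa with a two-sided Mann-Whitney U test.
#'
#' @param records data frame with columns `sister_label` and `NSL`.
#' @param taxon_a,taxon_b sister labels to compare.
#' @param B bootstrap replicates per taxon.
#' @param seed integer seed.
#' @param grid optional shared grid; defaults to the pooled
#'   [bootstrap_cdf()] grid.
#' @return data frame (grid, cdf_a, cdf_b, p).
#' @export
compare_taxa_nsl <- function(records, taxon_a, taxon_b, B = 200L,
                             seed = 1L, grid = NULL) {
  xa <- records$NSL[records$sister_label == taxon_a]
  xb <- records$NSL[records$sister_label == taxon_b]
  stopifnot(length(xa) >= 2L, length(xb) >= 2L)
  if (is.null(grid)) {
    pooled <- c(xa, xb)
    grid <- seq(0, quantile(pooled[is.finite(pooled)], 0.99, names = FALSE),
                length.out = 200L)
  }
  # the same seed drives both taxa, so identical record sets give
  # identical replicate CDFs and a flat p = 1 profile
  ca <- bootstrap_cdf(xa, B = B, seed = seed, grid = grid)
  cb <- bootstrap_cdf(xb, B = B, seed = seed, grid = grid)
  p <- vapply(seq_along(grid), function(i)
    mann_whitney_u(ca$boot[, i], cb$boot[, i])$p, 0)
  data.frame(grid = grid, cdf_a = ca$cdf, cdf_b = cb$cdf, p = p)
}
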