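# Felsenstein pruning under a reversible amino-acid CTMC with discrete
# gamma rates, with per-node rescaling for numerical stability, plus
# coordinate-wise branch-length optimization that reuses partial
# likelihoods on both sides of each edge.

LOGLIK_SENTINEL <- -1e9

encode_alignment <- function(alignment) {
  if (!is.matrix(alignment)) input_error("alignment must be a character matrix")
  alph <- aa_alphabet()
  up <- toupper(alignment)
  code <- match(up, alph)
  dim(code) <- dim(alignment)
  missing_ok <- up %in% c("-", ".", "X", "?", "*")
  bad <- is.na(code) & !missing_ok
  if (any(bad))
    input_error(paste0("non-amino-acid characters in alignment: ",
                       paste(unique(up[bad]), collapse = " ")))
  rownames(code) <- rownames(alignment)
  code
}

# Build the static data for likelihood computations on one (tree, alignment).
lik_setup <- function(tree, alignment, model, alpha = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(rownames(alignment)))
    input_error("alignment rows must be named with sequence ids")
  if (!all(tree$tip.label %in% rownames(alignment)))
    input_error("tree leaves missing from alignment")
  code <- if (is.integer(alignment)) alignment else encode_alignment(alignment)
  code <- code[tree$tip.label, , drop = FALSE]
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  alpha <- alpha %||% model$gamma_alpha
  ncat <- model$n_rate_categories
  S <- ncol(code)
  tipL <- vector("list", nt)
  for (i in seq_len(nt)) {
    m <- matrix(0, 20L, S)
    obs <- code[i, ]
    m[cbind(obs[!is.na(obs)], which(!is.na(obs)))] <- 1
    m[, is.na(obs)] <- 1
    tipL[[i]] <- m
  }
  po <- ape::reorder.phylo(tree, "postorder")
  # postorder sequence of internal nodes (children before parents)
  int_order <- unique(po$edge[, 1L])
  env <- new.env(parent = emptyenv())
  env$nt <- nt; env$n <- n; env$root <- nt + 1L
  env$children <- children_list(tree)
  env$bl <- node_branch_lengths(tree)
  env$ncat <- ncat
  env$rates <- discrete_gamma_rates(alpha, ncat)
  env$pi <- model$pi
  env$eig <- model$eig
  env$tipL <- tipL
  env$S <- S
  env$int_order <- int_order
  env
}

tpm_cats <- function(env, t) {
  lapply(env$rates, function(r) {
    P <- env$eig$U %*% (exp(env$eig$values * t * r) * env$eig$V)
    P[P < 0] <- 0
    P
  })
}

# partial likelihood of node v seen from above through its branch of length t
flow_up <- function(env, U, v, Pcats) {
  if (v <= env$nt) {
    tv <- env$tipL[[v]]
    lapply(Pcats, function(P) P %*% tv)
  } else {
    val <- U[[v]]$val
    lapply(seq_len(env$ncat), function(k) Pcats[[k]] %*% val[[k]])
  }
}

node_lsc <- function(env, U, v) {
  if (v <= env$nt) matrix(0, env$ncat, env$S) else U[[v]]$lsc
}

# post-order computation of all internal-node partials
compute_partials <- function(env) {
  U <- vector("list", env$n)
  for (v in env$int_order) U <- update_partial(env, U, v)
  U
}

# recompute the partial of internal node v from its children (assumed current)
update_partial <- function(env, U, v) {
  ncat <- env$ncat
  val <- vector("list", ncat)
  lsc <- matrix(0, ncat, env$S)
  first <- TRUE
  for (c1 in env$children[[v]]) {
    Pc <- tpm_cats(env, env$bl[c1])
    A <- flow_up(env, U, c1, Pc)
    if (first) {
      val <- A
      first <- FALSE
    } else {
      for (k in seq_len(ncat)) val[[k]] <- val[[k]] * A[[k]]
    }
    lsc <- lsc + node_lsc(env, U, c1)
  }
  for (k in seq_len(ncat)) {
    mx <- col_max(val[[k]])
    mx[mx <= 0] <- 1
    val[[k]] <- val[[k]] / rep(mx, each = 20L)
    lsc[k, ] <- lsc[k, ] + log(mx)
  }
  U[[v]] <- list(val = val, lsc = lsc)
  U
}

site_ll_from_partials <- function(env, U) {
  root <- U[[env$root]]
  m <- matrix(0, env$ncat, env$S)
  for (k in seq_len(env$ncat))
    m[k, ] <- log(colSums(env$pi * root$val[[k]])) + root$lsc[k, ]
  ll <- col_logsumexp(m) - log(env$ncat)
  pmax(ll, LOGLIK_SENTINEL)
}

#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the given model, averaging over the discrete
#' gamma rate categories with equal weights. Gap and ambiguity characters
#' are treated as missing data (partial likelihood one). Sites with zero
#' likelihood (possible on zero-length branches with conflicting states)
#' are reported at the finite sentinel `-1e9` so that downstream
#' resampling stays finite.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alignment character matrix (rows = sequences, named) or an
#'   integer-encoded alignment.
#' @param model a [substitution_model()].
#' @param alpha optional gamma-shape override.
#' @return numeric vector of per-site log-likelihoods with attribute
#'   `"total"` (their sum).
#' @export
site_loglik <- function(tree, alignment, model, alpha = NULL) {
  if (ape::Ntip(tree) == 1L) {
    # degenerate single-leaf family: likelihood is the stationary draw
    code <- if (is.integer(alignment)) alignment else encode_alignment(alignment)
    obs <- code[tree$tip.label, ]
    ll <- ifelse(is.na(obs), 0, log(model$pi[obs]))
    attr(ll, "total") <- sum(ll)
    return(ll)
  }
  env <- lik_setup(tree, alignment, model, alpha)
  U <- compute_partials(env)
  ll <- site_ll_from_partials(env, U)
  attr(ll, "total") <- sum(ll)
  ll
}

# Bracketed scalar maximization of one branch length. Because lengths
# usually carry over from a previously optimized (or simulated) tree,
# most branches are already near their optimum: a local triple plus one
# parabolic refinement handles those in ~4 evaluations, and a full Brent
# search over the bound interval runs only when the local triple shows
# the optimum lies elsewhere.
optimize_one_branch <- function(f, t0, f0, min_bl, max_bl) {
  l <- max(min_bl, t0 * 0.5)
  r <- min(max_bl, t0 * 2 + 0.05)
  fl <- f(l)
  fr <- f(r)
  if (f0 >= fl && f0 >= fr && l > min_bl * 1.5) {
    ts <- c(l, t0, r); fs <- c(fl, f0, fr)
    denom <- (ts[2L] - ts[1L]) * (fs[2L] - fs[3L]) -
      (ts[2L] - ts[3L]) * (fs[2L] - fs[1L])
    if (is.finite(denom) && abs(denom) > 0) {
      tv <- ts[2L] - 0.5 *
        ((ts[2L] - ts[1L])^2 * (fs[2L] - fs[3L]) -
         (ts[2L] - ts[3L])^2 * (fs[2L] - fs[1L])) / denom
      if (is.finite(tv) && tv > min_bl && tv < max_bl && abs(tv - t0) > 1e-10) {
        ts <- c(ts, tv); fs <- c(fs, f(tv))
      }
    }
    i <- which.max(fs)
    return(list(maximum = ts[i], objective = fs[i]))
  }
  if (fl >= f0 && fl >= fr && l <= min_bl * 1.5) {
    # monotone decreasing toward the bound: snap to it
    fmin <- f(min_bl)
    if (fmin >= fl) return(list(maximum = min_bl, objective = fmin))
  }
  upper <- min(max_bl, max(4 * t0 + 0.2, 4 * r))
  opt <- optimize(f, interval = c(min_bl, upper), maximum = TRUE, tol = 1e-3)
  if (opt$maximum < 1e-2) {
    fmin <- f(min_bl)
    if (fmin >= opt$objective)
      opt <- list(maximum = min_bl, objective = fmin)
  }
  opt
}

# log-likelihood as a function of one branch length, given the partial
# below the edge (node v) and the outer partial w at the parent end
edge_loglik <- function(env, U, v, wval, wlsc, t) {
  Pc <- tpm_cats(env, t)
  A <- flow_up(env, U, v, Pc)
  lscv <- node_lsc(env, U, v)
  m <- matrix(0, env$ncat, env$S)
  for (k in seq_len(env$ncat))
    m[k, ] <- log(colSums(wval[[k]] * A[[k]])) + wlsc[k, ] + lscv[k, ]
  sum(pmax(col_logsumexp(m) - log(env$ncat), LOGLIK_SENTINEL))
}

#' Optimize branch lengths by coordinate-wise Brent search
#'
#' Traverses the tree depth-first, optimizing each branch in turn with a
#' bracketed one-dimensional search while keeping the partial likelihoods
#' on both sides of the branch consistent. A candidate length is accepted
#' only if it improves the log-likelihood, so the trace over rounds is
#' monotone non-decreasing.
#'
#' @param tree rooted `phylo`.
#' @param alignment character matrix of aligned sequences.
#' @param model a [substitution_model()].
#' @param alpha optional gamma-shape override.
#' @param tol stop when a full round improves the total log-likelihood by
#'   less than this.
#' @param max_rounds maximum number of passes over all branches.
#' @param min_bl,max_bl branch-length bounds.
#' @return list with `tree` (updated lengths), `loglik`, `rounds`,
#'   `converged`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, alpha = NULL,
                                    tol = 1e-2, max_rounds = 5L,
                                    min_bl = 1e-8, max_bl = 10) {
  stopifnot(tol > 0)
  env <- lik_setup(tree, alignment, model, alpha)
  env$bl[env$bl < min_bl & !is.na(env$bl)] <- min_bl
  U <- compute_partials(env)
  ll <- sum(site_ll_from_partials(env, U))
  ncat <- env$ncat

  visit <- function(u, Wval, Wlsc) {
    ch <- env$children[[u]]
    A <- vector("list", length(ch))
    for (i in seq_along(ch))
      A[[i]] <- flow_up(env, U, ch[i], tpm_cats(env, env$bl[ch[i]]))
    for (i in seq_along(ch)) {
      v <- ch[i]
      wval <- Wval
      wlsc <- Wlsc
      for (j in seq_along(ch)) {
        if (j == i) next
        for (k in seq_len(ncat)) wval[[k]] <- wval[[k]] * A[[j]][[k]]
        wlsc <- wlsc + node_lsc(env, U, ch[j])
      }
      for (k in seq_len(ncat)) {
        mx <- col_max(wval[[k]])
        mx[mx <= 0] <- 1
        wval[[k]] <- wval[[k]] / rep(mx, each = 20L)
        wlsc[k, ] <- wlsc[k, ] + log(mx)
      }
      f <- function(t) edge_loglik(env, U, v, wval, wlsc, t)
      cur <- f(env$bl[v])
      opt <- optimize_one_branch(f, env$bl[v], cur, min_bl, max_bl)
      if (opt$objective > cur) env$bl[v] <- opt$maximum
      if (v > env$nt) {
        Pv <- tpm_cats(env, env$bl[v])
        Oval <- vector("list", ncat)
        for (k in seq_len(ncat)) Oval[[k]] <- crossprod(Pv[[k]], wval[[k]])
        Olsc <- wlsc
        for (k in seq_len(ncat)) {
          mx <- col_max(Oval[[k]])
          mx[mx <= 0] <- 1
          Oval[[k]] <- Oval[[k]] / rep(mx, each = 20L)
          Olsc[k, ] <- Olsc[k, ] + log(mx)
        }
        visit(v, Oval, Olsc)
        U <<- update_partial(env, U, v)
      }
      A[[i]] <- flow_up(env, U, v, tpm_cats(env, env$bl[v]))
    }
  }

  rounds <- 0L
  converged <- FALSE
  piW <- lapply(seq_len(ncat), function(k)
    matrix(env$pi, 20L, env$S))
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    visit(env$root, piW, matrix(0, ncat, env$S))
    U <- compute_partials(env)
    ll_new <- sum(site_ll_from_partials(env, U))
    if (ll_new < ll - 1e-6)
      warning("branch-length optimization decreased the log-likelihood")
    improved <- ll_new - ll
    ll <- max(ll, ll_new)
    if (improved < tol) { converged <- TRUE; break }
  }
  out <- tree
  out$edge.length <- env$bl[out$edge[, 2L]]
  if (!converged)
    warning("branch-length optimization did not converge; returning best so far")
  list(tree = out, loglik = ll, rounds = rounds, converged = converged)
}

#' Estimate the gamma shape parameter on a fixed tree
#'
#' Evaluates the total log-likelihood on a grid of gamma shapes and
#' returns the best grid point. The estimate is made once on the master
#' tree of a gene family and reused unchanged for all of its constrained
#' topologies.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alignment character matrix of aligned sequences.
#' @param model a [substitution_model()].
#' @param grid candidate shape values.
#' @return the selected shape (numeric scalar) with attribute `"loglik"`,
#'   the per-grid-point total log-likelihoods.
#' @export
estimate_gamma_alpha <- function(tree, alignment, model,
                                 grid = c(0.3, 0.5, 0.75, 1, 1.5, 2, 5)) {
  stopifnot(length(grid) >= 1L)
  ll <- vapply(grid, function(a)
    attr(site_loglik(tree, alignment, model, alpha = a), "total"), 0)
  best <- grid[which.max(ll)]
  attr(best, "loglik") <- setNames(ll, grid)
  best
}
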