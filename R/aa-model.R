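# Amino-acid substitution models: reversible CTMC built from a symmetric
# exchangeability matrix and stationary frequencies, with equal-weight
# discrete gamma rate heterogeneity.

#' @rdname substitution_model
#' @export
aa_alphabet <- function() {
  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
}

#' Construct a reversible amino-acid substitution model
#'
#' Builds the rate matrix `Q = S diag(pi)`, rescaled so that the expected
#' substitution rate at stationarity is one, and caches the eigensystem of
#' its symmetrized form (which is real for reversible models) for fast
#' transition-probability computation. Rate heterogeneity across sites uses
#' an equal-weight discrete gamma with category rates at the category
#' medians, normalized to mean one.
#'
#' @param exchangeability symmetric 20x20 matrix of exchangeabilities
#'   (diagonal ignored), rows/columns in the order of [aa_alphabet()].
#' @param freq stationary amino-acid frequencies, length 20, summing to 1.
#' @param gamma_alpha gamma shape parameter; `Inf` means rate-homogeneous.
#' @param n_rate_categories number of discrete gamma categories.
#' @param name model label.
#' @return an object of class `"substitution_model"`.
#' @export
substitution_model <- function(exchangeability, freq, gamma_alpha = 1,
                               n_rate_categories = 4L, name = "custom") {
  stopifnot(is.matrix(exchangeability), dim(exchangeability) == c(20L, 20L))
  if (max(abs(exchangeability - t(exchangeability))) > 1e-8)
    input_error("exchangeability matrix must be symmetric")
  freq <- as.numeric(freq)
  stopifnot(length(freq) == 20L, all(freq > 0))
  freq <- freq / sum(freq)
  S <- exchangeability
  diag(S) <- 0
  Q <- S %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  sp <- sqrt(freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  obj <- list(name = name, S = S, pi = freq,
              gamma_alpha = gamma_alpha,
              n_rate_categories = as.integer(n_rate_categories),
              Q = Q,
              eig = list(values = eig$values,
                         U = diag(1 / sp) %*% eig$vectors,
                         V = t(eig$vectors) %*% diag(sp)))
  class(obj) <- "substitution_model"
  obj
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution model:", x$name,
      sprintf("(+G%d, alpha=%g)\n", x$n_rate_categories, x$gamma_alpha))
  invisible(x)
}

#' Read exchangeabilities and frequencies from a PAML-style dat file
#'
#' Accepts the common PAML dialect: 19 rows of the lower triangle of the
#' exchangeability matrix followed by 20 stationary frequencies, whitespace
#' separated, blank lines ignored.
#'
#' @param path file path.
#' @return list with `exchangeability` (20x20 symmetric) and `freq`.
#' @export
read_paml_dat <- function(path) {
  tok <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tok) < 190L + 20L)
    input_error("dat file must contain 190 exchangeabilities and 20 frequencies")
  m <- matrix(0, 20L, 20L)
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    k <- k + 1L
    m[i, j] <- tok[k]
  }
  m <- m + t(m)
  freq <- tok[191:210]
  list(exchangeability = m, freq = freq / sum(freq))
}

#' @description `lg_model()` loads the packaged LG matrix (Le & Gascuel 2008);
#'   `poisson_model()` is an equal-frequency, equal-exchangeability model
#'   useful for fast exact tests.
#' @rdname substitution_model
#' @export
lg_model <- function(gamma_alpha = 1, n_rate_categories = 4L) {
  dat <- read_paml_dat(system.file("extdata", "lg.dat", package = "epocflow",
                                   mustWork = TRUE))
  substitution_model(dat$exchangeability, dat$freq, gamma_alpha,
                     n_rate_categories, name = "LG")
}

#' @rdname substitution_model
#' @export
poisson_model <- function(gamma_alpha = Inf, n_rate_categories = 1L) {
  S <- matrix(1, 20L, 20L)
  substitution_model(S, rep(1 / 20, 20L), gamma_alpha, n_rate_categories,
                     name = "Poisson")
}

# category rates: gamma quantiles at category medians, normalized to mean 1
discrete_gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha)) return(rep(1, k))
  r <- qgamma((seq_len(k) - 0.5) / k, shape = alpha, rate = alpha)
  r * k / sum(r)
}

#' Transition probability matrix of a substitution model
#'
#' Computes `P(t) = exp(Qt)` through the cached eigendecomposition of the
#' symmetrized rate matrix.
#'
#' @param model a [substitution_model()].
#' @param t branch length in expected substitutions per site, `>= 0`.
#' @return 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  e <- model$eig
  P <- e$U %*% (exp(e$values * t) * e$V)
  P[P < 0] <- 0
  P
}
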