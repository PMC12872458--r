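# Shared internals: seeded evaluation, condition classes, numeric helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored afterwards, so seeded pipeline
# stages never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Signal that a gene family fails a quality-control rule
#'
#' Curation and clade-detection stages discard whole gene families for a
#' small set of machine-readable reasons. The condition carries the reason
#' code in its `reason` field so that pipeline drivers can log it.
#'
#' @param reason one of `"outlier_overprune"`, `"no_euk_clade"`,
#'   `"no_prok_clade"`, `"paraphyly"`.
#' @param message optional human-readable detail.
#' @return never returns; throws a condition of class `"epoc_discarded"`.
#' @export
epoc_discard <- function(reason, message = NULL) {
  reason <- match.arg(reason,
    c("outlier_overprune", "no_euk_clade", "no_prok_clade", "paraphyly"))
  msg <- if (is.null(message)) paste0("gene family discarded: ", reason)
         else paste0("gene family discarded [", reason, "]: ", message)
  stop(errorCondition(msg, reason = reason,
                      class = c("epoc_discarded", "epocflow_error", "error")))
}

#' Reason code of a discard condition
#' @param cond a condition caught from [epoc_discard()].
#' @return the reason string, or `NA` if not a discard condition.
#' @export
discard_reason <- function(cond) {
  if (inherits(cond, "epoc_discarded")) cond$reason else NA_character_
}

input_error <- function(message) {
  stop(errorCondition(message,
                      class = c("epocflow_input_error", "epocflow_error", "error")))
}

# fast column-wise maximum of a small-row-count matrix
col_max <- function(m) {
  j <- max.col(t(m), ties.method = "first")
  m[cbind(j, seq_len(ncol(m)))]
}

# column-wise log-sum-exp of a (categories x sites) matrix
col_logsumexp <- function(m) {
  mx <- col_max(m)
  out <- mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
  out[!is.finite(mx)] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
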