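# L x K matrix of per-site emission log-probabilities; missing sites
# contribute a factor of 1 (row of zeros), i.e. are marginalized out.
# The binomial coefficient is constant across states, so FFBS callers skip it.
log_emission_matrix <- function(thetas, y, m, missing, include_const = TRUE) {
  L <- length(y)
  K <- length(thetas)
  obs <- !missing
  le <- matrix(0, L, K)
  if (any(obs)) {
    yo <- y[obs]
    mo <- m[obs]
    block <- outer(yo, log(thetas)) + outer(mo - yo, log1p(-thetas))
    if (include_const) block <- block + lchoose(mo, yo)
    le[obs, ] <- block
  }
  le
}

#' Complete-data log-likelihood of the methylation HMM
#'
#' The joint log-probability of counts and a given hidden state path:
#' binomial emissions per observed site (missing sites contribute a factor
#' of 1) plus the initial-state and transition probabilities of the path.
#'
#' @param params An [hmm_params()].
#' @param states Integer path in `1..K`, one entry per position.
#' @param y,m Methylated counts and depths (vectors, one sample).
#' @param missing Logical vector marking missing sites; defaults to `NA`
#'   entries of `y`/`m`.
#' @return A single number, the log-likelihood.
#' @export
complete_data_loglik <- function(params, states, y, m, missing = NULL) {
  K <- params$K
  L <- length(y)
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  if (length(states) != L) stop_validation("`states` must match the data length")
  if (any(states < 1 | states > K))
    stop_validation("states must lie in 1..K")
  obs <- !missing
  ll <- 0
  if (any(obs)) {
    th <- params$thetas[states[obs]]
    yo <- y[obs]
    mo <- m[obs]
    ll <- sum(lchoose(mo, yo) + yo * log(th) + (mo - yo) * log1p(-th))
  }
  ll <- ll + log(params$trans[1, states[1]])
  if (L > 1)
    ll <- ll + sum(log(params$trans[cbind(states[-L] + 1L, states[-1])]))
  unname(ll)
}

#' Marginal log-likelihood of the methylation HMM
#'
#' The forward algorithm in log space, summing the complete-data likelihood
#' over all `K^L` hidden paths. Fully-missing sites pass probability through
#' unchanged, so partially missing samples need not be discarded.
#'
#' @inheritParams complete_data_loglik
#' @return A single number, finite whenever any path has positive
#'   probability.
#' @export
marginal_loglik <- function(params, y, m, missing = NULL) {
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  le <- log_emission_matrix(params$thetas, y, m, missing)
  hmm_forward_loglik(le, log(params$trans[1, ]),
                     log(params$trans[-1, , drop = FALSE]))
}

# transition counts n_{k'k} for a path; row 1 = initial-state indicator
transition_counts <- function(states, K) {
  n <- matrix(0L, K + 1, K)
  n[1, states[1]] <- 1L
  L <- length(states)
  if (L > 1) {
    flat <- tabulate((states[-L] - 1L) * K + states[-1], nbins = K * K)
    n[-1, ] <- matrix(flat, K, K, byrow = TRUE)
  }
  n
}
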