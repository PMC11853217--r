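# sort thetas ascending and relabel states/transition matrix consistently
# (label-switching canon: state 1 = least methylated)
canonicalize_params <- function(params, states) {
  perm <- order(params$thetas)
  if (all(perm == seq_len(params$K)))
    return(list(params = params, states = states))
  pos <- match(seq_len(params$K), perm)
  params$thetas <- params$thetas[perm]
  params$trans <- rbind(params$trans[1, perm],
                        params$trans[perm + 1L, perm, drop = FALSE])
  list(params = params, states = pos[states])
}

#' One Gibbs sweep of the fixed-order sampler
#'
#' Updates, in order: each methylation propensity from its conjugate Beta
#' full conditional (states with no observed site draw from the prior),
#' each transition row from its conjugate Dirichlet full conditional, and
#' the hidden state path by forward-filtering backward-sampling. Propensities
#' are then re-sorted ascending with states relabelled.
#'
#' @inheritParams complete_data_loglik
#' @param config An [mcmc_config()] (supplies the Beta/Dirichlet
#'   hyperparameters).
#' @return A list with updated `params` and `states`.
#' @export
gibbs_sweep <- function(params, states, y, m, missing = NULL,
                        config = mcmc_config()) {
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  K <- params$K
  obs <- !missing
  # conjugate Beta updates
  for (k in seq_len(K)) {
    sel <- obs & states == k
    ty <- sum(y[sel])
    tm <- sum(m[sel])
    params$thetas[k] <- rbeta(1, config$alpha + ty, config$beta + tm - ty)
  }
  params$thetas <- clamp_unit(params$thetas)
  # conjugate Dirichlet updates
  cnt <- transition_counts(states, K)
  for (r in seq_len(K + 1)) {
    params$trans[r, ] <- rdirichlet1(config$gamma + cnt[r, ])
  }
  # FFBS path redraw
  states <- draw_states(params, y, m, missing)
  out <- canonicalize_params(params, states)
  out
}

# FFBS with uniforms drawn from the R RNG (reproducible under set.seed)
draw_states <- function(params, y, m, missing) {
  le <- log_emission_matrix(params$thetas, y, m, missing, include_const = FALSE)
  hmm_ffbs(le, log(params$trans[1, ]),
           log(params$trans[-1, , drop = FALSE]), runif(length(y)))
}

# numerical guard: keep thetas strictly inside (0,1); extreme counts can
# push conjugate draws to the boundary at machine precision
clamp_unit <- function(thetas, eps = 1e-12) {
  pmin(pmax(thetas, eps), 1 - eps)
}
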