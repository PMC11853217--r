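# Independent oracles used across test files. These deliberately avoid the
# package's own recursions: likelihoods are computed by brute-force path
# enumeration with stats::dbinom, so they can certify the forward algorithm
# and the complete-data likelihood.

# all K^L state paths as rows
all_paths <- function(K, L) {
  as.matrix(expand.grid(rep(list(seq_len(K)), L)))
}

# complete-data log-likelihood of one path, term by term
oracle_path_loglik <- function(thetas, init, P, path, y, m, missing) {
  ll <- log(init[path[1]])
  L <- length(path)
  if (L > 1) {
    for (l in 2:L) ll <- ll + log(P[path[l - 1], path[l]])
  }
  for (l in seq_len(L)) {
    if (!missing[l]) ll <- ll + dbinom(y[l], m[l], thetas[path[l]], log = TRUE)
  }
  ll
}

# marginal log-likelihood by explicit enumeration over all paths
oracle_marginal_loglik <- function(thetas, init, P, y, m, missing) {
  paths <- all_paths(length(thetas), length(y))
  lls <- apply(paths, 1, function(p) {
    oracle_path_loglik(thetas, init, P, p, y, m, missing)
  })
  mx <- max(lls)
  mx + log(sum(exp(lls - mx)))
}

# posterior state marginals at each site by enumeration
oracle_state_marginals <- function(thetas, init, P, y, m, missing) {
  K <- length(thetas)
  L <- length(y)
  paths <- all_paths(K, L)
  lls <- apply(paths, 1, function(p) {
    oracle_path_loglik(thetas, init, P, p, y, m, missing)
  })
  w <- exp(lls - max(lls))
  w <- w / sum(w)
  out <- matrix(0, L, K)
  for (l in seq_len(L)) {
    for (k in seq_len(K)) out[l, k] <- sum(w[paths[, l] == k])
  }
  out
}

# Dirichlet draw for random stochastic rows in tests
rdir_test <- function(K) {
  g <- rgamma(K, 1)
  g / sum(g)
}

# a small panel with known structure, shared by several files
small_sim <- function(seed = 42, L = 120L, n_per = 4L, dmc_fraction = 0,
                      effect_size = 2, missing_rate = 0.15) {
  simulate_panel(panel_sim_spec(
    n_positions = L, n_samples_per_group = n_per, true_order = 2L,
    true_thetas = c(0.2, 0.8), missing_rate = missing_rate,
    dmc_fraction = dmc_fraction, effect_size = effect_size, seed = seed
  ))
}

# short chain settings for fast tests
fast_chain <- function(seed = 1L, ...) {
  mcmc_config(n_iter = 800L, burn_in = 300L, thin = 2L, seed = seed, ...)
}
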