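# ---- collapsed posterior for the trans-dimensional move -------------------
#
# The split-merge move operates on (K, thetas, state path) with the
# transition matrix integrated out analytically (Dirichlet-multinomial),
# which yields an exact Metropolis-Hastings ratio with no Jacobian and a
# deterministic reverse merge. The transition matrix is refreshed from its
# Dirichlet full conditional immediately after an accepted move.

# log p(y, s, K, thetas) up to terms constant in (K, thetas, s)
collapsed_log_target <- function(thetas, states, y, m, missing, config) {
  K <- length(thetas)
  obs <- !missing
  ll <- 0
  if (any(obs)) {
    th <- thetas[states[obs]]
    ll <- sum(y[obs] * log(th) + (m[obs] - y[obs]) * log1p(-th))
  }
  cnt <- transition_counts(states, K)
  g <- config$gamma
  dm <- sum(lgamma(K * g) - lgamma(K * g + rowSums(cnt))) +
    sum(lgamma(g + cnt) - lgamma(g))
  prior_theta <- sum(stats::dbeta(thetas, config$alpha, config$beta, log = TRUE))
  # ordered (sorted) parameterization of an exchangeable prior: K! factor
  ll + dm + prior_theta + lgamma(K + 1)
}

# split radius bound: one third of the smallest theta gap (including the
# distance of theta_j to the unit-interval boundaries), which guarantees the
# split pair is the unique smallest-gap adjacent pair, so the reverse merge
# is deterministic
split_radius <- function(thetas, j) {
  gaps <- if (length(thetas) > 1) diff(thetas) else numeric(0)
  min(c(gaps, thetas[j], 1 - thetas[j])) / 3
}

move_probs <- function(K, k_max, underfit = FALSE, weight = 1) {
  b <- if (K >= k_max) 0 else if (K == 1) 1 else 0.5
  d <- if (K <= 1) 0 else if (K == k_max) 1 else 0.5
  if (underfit) b <- b * weight
  z <- b + d
  c(split = b / z, merge = d / z)
}

refresh_trans <- function(thetas, states, config) {
  K <- length(thetas)
  cnt <- transition_counts(states, K)
  trans <- matrix(0, K + 1, K)
  for (r in seq_len(K + 1)) trans[r, ] <- rdirichlet1(config$gamma + cnt[r, ])
  trans
}

#' One reversible-jump split-merge move on the HMM order
#'
#' Proposes either a split (a uniformly chosen state's propensity is split
#' into two values `theta_j - u`, `theta_j + u` with
#' `u ~ Uniform(0, min-gap / 3)` and its sites reassigned by fair coin) or a
#' merge (the adjacent pair of propensities with the smallest gap is merged
#' to its midpoint, sites pooled). The move is accepted with the exact
#' Metropolis-Hastings probability on the collapsed posterior (transition
#' matrix integrated out); the transition matrix is then redrawn from its
#' full conditional. A merge at `K = 1` and a split at `K = k_max` have
#' proposal probability 0. Rejected moves return the inputs unchanged.
#'
#' @inheritParams gibbs_sweep
#' @param underfit Logical: is the underfitting penalty currently triggered?
#'   When `TRUE` the split-proposal probability is up-weighted by
#'   `config$underfit_penalty_weight`. See [underfit_flag()].
#' @return A list with `params`, `states`, `accepted`, `move`
#'   (`"split"`/`"merge"`/`"none"`), and `log_ratio` (the log MH ratio of
#'   the proposed move, `NA` if no move was available).
#' @export
split_merge_move <- function(params, states, y, m, missing = NULL,
                             config = mcmc_config(), underfit = FALSE) {
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  K <- params$K
  w <- config$underfit_penalty_weight
  mp <- move_probs(K, config$k_max, underfit, w)
  if (K == 1 && K == config$k_max) {
    return(list(params = params, states = states, accepted = FALSE,
                move = "none", log_ratio = NA_real_))
  }
  do_split <- runif(1) < mp["split"]
  lt_old <- collapsed_log_target(params$thetas, states, y, m, missing, config)

  if (do_split) {
    j <- sample.int(K, 1)
    h <- split_radius(params$thetas, j)
    u <- runif(1, 0, h)
    th_new <- append(params$thetas[-j], c(params$thetas[j] - u,
                                          params$thetas[j] + u),
                     after = j - 1)
    in_j <- states == j
    n_j <- sum(in_j)
    coin <- runif(n_j) < 0.5
    s_new <- states
    s_new[states > j] <- s_new[states > j] + 1L
    s_new[in_j] <- ifelse(coin, j, j + 1L)
    lt_new <- collapsed_log_target(th_new, s_new, y, m, missing, config)
    mp_rev <- move_probs(K + 1, config$k_max, underfit, w)
    log_ratio <- lt_new - lt_old +
      log(mp_rev["merge"]) -
      (log(mp["split"]) - log(K) - log(h) - n_j * log(2))
    accepted <- log(runif(1)) < log_ratio
    if (accepted) {
      params <- hmm_params(th_new, trans = NULL, hyper = params$hyper)
      params$trans <- refresh_trans(th_new, s_new, config)
      return(list(params = params, states = s_new, accepted = TRUE,
                  move = "split", log_ratio = unname(log_ratio)))
    }
    return(list(params = params, states = states, accepted = FALSE,
                move = "split", log_ratio = unname(log_ratio)))
  }

  # merge: deterministic smallest-gap adjacent pair
  gaps <- diff(params$thetas)
  a <- which.min(gaps)
  u_rev <- gaps[a] / 2
  th_new <- params$thetas[-(a + 1)]
  th_new[a] <- params$thetas[a] + u_rev
  s_new <- states
  s_new[states == a + 1L] <- a
  s_new[states > a + 1L] <- s_new[states > a + 1L] - 1L
  n_merged <- sum(s_new == a)
  h_star <- split_radius(th_new, a)
  if (u_rev >= h_star) {
    # reverse split could not have generated this pair: density 0, reject
    return(list(params = params, states = states, accepted = FALSE,
                move = "merge", log_ratio = -Inf))
  }
  lt_new <- collapsed_log_target(th_new, s_new, y, m, missing, config)
  mp_rev <- move_probs(K - 1, config$k_max, underfit, w)
  log_ratio <- lt_new - lt_old +
    (log(mp_rev["split"]) - log(K - 1) - log(h_star) - n_merged * log(2)) -
    log(mp["merge"])
  accepted <- log(runif(1)) < log_ratio
  if (accepted) {
    params <- hmm_params(th_new, trans = NULL, hyper = params$hyper)
    params$trans <- refresh_trans(th_new, s_new, config)
    return(list(params = params, states = s_new, accepted = TRUE,
                move = "merge", log_ratio = unname(log_ratio)))
  }
  list(params = params, states = states, accepted = FALSE,
       move = "merge", log_ratio = unname(log_ratio))
}

#' Within-state binomial deviance and the underfitting trigger
#'
#' When the current order is too small, counts within a state are
#' overdispersed relative to a single binomial propensity. The trigger
#' compares the total within-state binomial deviance to the 95th percentile
#' of its parametric-bootstrap null (counts re-simulated from the fitted
#' binomials); when exceeded, the split-proposal probability is up-weighted.
#'
#' @inheritParams gibbs_sweep
#' @param boot_reps Bootstrap replicates.
#' @return Logical flag, with the observed deviance and the threshold as
#'   attributes.
#' @export
underfit_flag <- function(params, states, y, m, missing = NULL,
                          config = mcmc_config(),
                          boot_reps = config$penalty_boot_reps) {
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  obs <- !missing
  if (!any(obs)) return(structure(FALSE, deviance = 0, threshold = Inf))
  th <- params$thetas[states[obs]]
  yo <- y[obs]
  mo <- m[obs]
  D <- binom_deviance(yo, mo, th)
  nb <- length(yo)
  ystar <- matrix(rbinom(boot_reps * nb, size = rep(mo, each = boot_reps),
                         prob = rep(th, each = boot_reps)),
                  nrow = boot_reps)
  mo_mat <- matrix(mo, boot_reps, nb, byrow = TRUE)
  mu_mat <- matrix(mo * th, boot_reps, nb, byrow = TRUE)
  Dstar <- 2 * rowSums(dev_half(ystar, mu_mat) +
                         dev_half(mo_mat - ystar, mo_mat - mu_mat))
  thr <- unname(quantile(Dstar, 0.95))
  structure(D > thr, deviance = D, threshold = thr)
}

# y * log(y / mu) with the 0 * log(0) = 0 convention, vectorized
dev_half <- function(y, mu) {
  y * (log(pmax(y, 1)) - log(mu))
}

binom_deviance <- function(y, m, th) {
  mu <- m * th
  2 * sum(dev_half(y, mu) + dev_half(m - y, m - mu))
}

#' Apply the state-collapse penalty
#'
#' Adjacent methylation propensities closer than `config$collapse_tol` are
#' deterministically merged (midpoint propensity, sites pooled) until all
#' gaps exceed the tolerance; the transition matrix is redrawn from its full
#' conditional when a collapse occurs. This is the overfitting penalty that
#' prevents near-duplicate states from persisting.
#'
#' @inheritParams gibbs_sweep
#' @return A list with `params`, `states`, and `n_collapsed`.
#' @export
apply_penalties <- function(params, states, config = mcmc_config()) {
  n_collapsed <- 0L
  while (params$K > 1) {
    gaps <- diff(params$thetas)
    a <- which.min(gaps)
    if (gaps[a] >= config$collapse_tol) break
    th_new <- params$thetas[-(a + 1)]
    th_new[a] <- (params$thetas[a] + params$thetas[a + 1]) / 2
    states[states == a + 1L] <- a
    states[states > a + 1L] <- states[states > a + 1L] - 1L
    params <- hmm_params(th_new, trans = NULL, hyper = params$hyper)
    params$trans <- refresh_trans(th_new, states, config)
    n_collapsed <- n_collapsed + 1L
  }
  list(params = params, states = states, n_collapsed = n_collapsed)
}
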