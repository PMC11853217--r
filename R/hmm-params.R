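#' HMM parameter state
#'
#' Order `K`, ascending methylation propensities `thetas`, and a
#' `(K + 1) x K` stochastic matrix `trans` whose first row is the initial
#' state distribution and remaining rows the transition probabilities.
#' Hyperparameters: flat `Beta(alpha, beta)` on each propensity, flat
#' `Dirichlet(gamma)` on each row, uniform prior on `K` up to `k_max`.
#'
#' @param thetas Ascending vector in `(0, 1)`.
#' @param trans `(K + 1) x K` matrix with rows summing to 1; default
#'   uniform rows.
#' @param hyper List with `alpha`, `beta`, `gamma`, `k_max`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(thetas, trans = NULL,
                       hyper = list(alpha = 1, beta = 1, gamma = 1, k_max = 10L)) {
  K <- length(thetas)
  if (K < 1) stop_validation("order K must be >= 1")
  if (any(thetas <= 0) || any(thetas >= 1))
    stop_validation("`thetas` must lie strictly in (0, 1)")
  if (is.unsorted(thetas)) stop_validation("`thetas` must be sorted ascending")
  if (is.null(trans)) trans <- matrix(1 / K, K + 1, K)
  trans <- as.matrix(trans)
  if (!all(dim(trans) == c(K + 1, K)))
    stop_validation("`trans` must be (K + 1) x K")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-10))
    stop_validation("rows of `trans` must sum to 1")
  if (K > hyper$k_max) stop_validation("K exceeds k_max")
  structure(list(K = K, thetas = as.numeric(thetas), trans = trans,
                 hyper = hyper),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> K =", x$K, " thetas:",
      paste(signif(x$thetas, 3), collapse = " "), "\n")
  invisible(x)
}

#' MCMC configuration for the trans-dimensional sampler
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations discarded before averaging.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param collapse_tol State-collapse tolerance `delta` on the theta scale:
#'   adjacent propensities closer than this are deterministically merged
#'   (the overfitting penalty).
#' @param underfit_penalty_weight Multiplicative up-weight (>= 1) of the
#'   split-proposal probability when the within-state binomial deviance
#'   exceeds its parametric-bootstrap null 95th percentile (the
#'   underfitting penalty).
#' @param penalty_check_interval Iterations between re-evaluations of the
#'   bootstrap deviance threshold (it is cached in between).
#' @param penalty_boot_reps Bootstrap replicates for the deviance null.
#' @param k_max Maximum HMM order.
#' @param alpha,beta Beta prior hyperparameters for each propensity.
#' @param gamma Dirichlet concentration for each transition row.
#' @param seed Integer seed (optional; chains derive their own).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000L, burn_in = 2000L, thin = 5L,
                        collapse_tol = 0.02, underfit_penalty_weight = 2,
                        penalty_check_interval = 20L, penalty_boot_reps = 100L,
                        k_max = 10L, alpha = 1, beta = 1, gamma = 1,
                        seed = NULL) {
  if (burn_in >= n_iter) stop_validation("`burn_in` must be < `n_iter`")
  if (collapse_tol <= 0) stop_validation("`collapse_tol` must be > 0")
  if (underfit_penalty_weight < 1)
    stop_validation("`underfit_penalty_weight` must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), collapse_tol = collapse_tol,
                 underfit_penalty_weight = underfit_penalty_weight,
                 penalty_check_interval = as.integer(penalty_check_interval),
                 penalty_boot_reps = as.integer(penalty_boot_reps),
                 k_max = as.integer(k_max), alpha = alpha, beta = beta,
                 gamma = gamma, seed = seed),
            class = "mcmc_config")
}
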