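#' EM configuration for the penalized mixture AFT fit
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative change of the penalized
#'   objective.
#' @param init_iter Iterations of each short exploratory EM run during
#'   multi-start initialization.
#' @param n_init Number of initializations (one k-means start on
#'   `(log time, status)` plus random-posterior starts).
#' @param zero_tol Coefficients below this magnitude are set exactly to 0
#'   after convergence.
#' @param comp_floor A component whose posterior-membership column has
#'   maximum below this floor is declared empty, triggering a restart.
#' @param max_restarts Maximum empty-component restarts before the fit is
#'   flagged.
#' @param scad_a SCAD shape parameter (default 3.7).
#' @param mcp_gamma MCP concavity parameter (default 3).
#' @param sigma_floor_frac Lower bound on each component scale as a fraction
#'   of the marginal log-time standard deviation (default 0.05); keeps the
#'   mixture likelihood bounded (no component may collapse onto a few
#'   subjects with vanishing variance).
#' @return A list of class `aft_em_config`.
#' @export
aft_em_config <- function(max_iter = 200L, tol = 1e-6, init_iter = 15L,
                          n_init = 5L, zero_tol = 1e-5, comp_floor = 1e-3,
                          max_restarts = 5L, scad_a = 3.7, mcp_gamma = 3,
                          sigma_floor_frac = 0.05) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 init_iter = as.integer(init_iter), n_init = as.integer(n_init),
                 zero_tol = zero_tol, comp_floor = comp_floor,
                 max_restarts = as.integer(max_restarts),
                 scad_a = scad_a, mcp_gamma = mcp_gamma,
                 sigma_floor_frac = sigma_floor_frac),
            class = "aft_em_config")
}

aft_design <- function(data) {
  covars <- setdiff(names(data), c("id", "time", "status"))
  X <- as.matrix(data[covars])
  if (any(data$time <= 0)) stop_validation("times must be positive")
  list(X = X, w = log(data$time), delta = as.numeric(data$status),
       covars = covars)
}

#' Observed-data log-likelihood of a mixture AFT model
#'
#' Each subject contributes the log of a mixture over components of the
#' normal density of log time (events) or the normal survival function
#' (right-censored subjects), evaluated at the component's linear predictor.
#' All likelihoods are on the log-time scale; the 1/t change-of-variable
#' Jacobian is constant in the parameters and dropped, so comparisons
#' across orders remain valid.
#'
#' @param params List with `pi` (mixing probabilities), `intercepts`,
#'   `beta` (`d x K` matrix), `sigma` (per-component scales, > 0).
#' @param data Survival tibble (`time`, `status`, covariates).
#' @return The log-likelihood (a single number).
#' @export
mixture_loglik <- function(params, data) {
  if (any(params$sigma <= 0)) stop_validation("sigma must be positive")
  des <- aft_design(data)
  lik <- component_logdens(params, des)
  sum(row_log_sum_exp(lik + rep(log(params$pi), each = nrow(lik))))
}

# n x K matrix of per-component log density / log survival contributions
# (without the mixing weights)
component_logdens <- function(params, des) {
  K <- length(params$pi)
  n <- length(des$w)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    mu <- params$intercepts[k] + drop(des$X %*% params$beta[, k])
    out[, k] <- ifelse(
      des$delta == 1,
      dnorm(des$w, mu, params$sigma[k], log = TRUE),
      pnorm(des$w, mu, params$sigma[k], lower.tail = FALSE, log.p = TRUE)
    )
  }
  out
}

# E-step: posterior memberships and, for censored subjects, the
# truncated-normal conditional mean and variance of the latent log-time
e_step <- function(params, des) {
  K <- length(params$pi)
  n <- length(des$w)
  ld <- component_logdens(params, des) +
    rep(log(params$pi), each = n)
  lz <- row_log_sum_exp(ld)
  tau <- exp(ld - lz)
  z <- matrix(des$w, n, K)
  v <- matrix(0, n, K)
  cens <- des$delta == 0
  if (any(cens)) {
    for (k in seq_len(K)) {
      mu <- params$intercepts[k] + drop(des$X %*% params$beta[, k])
      xi <- (des$w[cens] - mu[cens]) / params$sigma[k]
      lam <- exp(dnorm(xi, log = TRUE) -
                   pnorm(xi, lower.tail = FALSE, log.p = TRUE))
      z[cens, k] <- mu[cens] + params$sigma[k] * lam
      v[cens, k] <- params$sigma[k]^2 * pmax(1 + xi * lam - lam^2, 0)
    }
  }
  list(tau = tau, z = z, v = v, loglik = sum(lz))
}

# penalty derivative for the local linear approximation (per-coefficient
# effective soft-threshold level); `b` is the previous-iteration coefficient
penalty_deriv <- function(b, lambda, penalty, adw, cfg) {
  ab <- abs(b)
  switch(penalty,
    "lasso" = rep(lambda, length(b)),
    "adaptive-lasso" = lambda * adw,
    "scad" = {
      a <- cfg$scad_a
      ifelse(ab <= lambda, lambda,
             ifelse(ab < a * lambda, pmax(a * lambda - ab, 0) / (a - 1), 0))
    },
    "mcp" = pmax(lambda - ab / cfg$mcp_gamma, 0)
  )
}

# penalty value p_lambda(|b|) (enters the objective and the pi update)
penalty_value <- function(b, lambda, penalty, adw, cfg) {
  ab <- abs(b)
  switch(penalty,
    "lasso" = lambda * ab,
    "adaptive-lasso" = lambda * adw * ab,
    "scad" = {
      a <- cfg$scad_a
      ifelse(ab <= lambda, lambda * ab,
        ifelse(ab < a * lambda,
               (2 * a * lambda * ab - ab^2 - lambda^2) / (2 * (a - 1)),
               (a + 1) * lambda^2 / 2))
    },
    "mcp" = {
      g <- cfg$mcp_gamma
      ifelse(ab <= g * lambda, lambda * ab - ab^2 / (2 * g),
             g * lambda^2 / 2)
    }
  )
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Penalized weighted least squares for one component by coordinate descent
# in covariance form: X'WX and X'Wz are computed once, so each coordinate
# update is O(d). Minimizes 0.5 * sum(tau * (z - alpha - X b)^2) +
# sig2 * n * pi_k * sum(thr_j * |b_j|), thr_j being the LLA-linearized
# penalty level; every coordinate step solves its subproblem exactly, so
# the EM ascent property is preserved.
m_step_component <- function(X, z, tau, sig2, n_pi, lambda, penalty, adw,
                             alpha, b, cfg) {
  sw <- sum(tau)
  Xw <- tau * X
  A <- crossprod(X, Xw)            # d x d weighted Gram matrix
  bv <- drop(crossprod(Xw, z))     # X' W z
  sx <- colSums(Xw)                # X' W 1
  sz <- sum(tau * z)
  # soft-threshold level fixed per local-linear round; lasso-type penalties
  # need a single round, concave ones are re-linearized a few times
  n_rounds <- if (penalty %in% c("lasso", "adaptive-lasso")) 1L else 4L
  for (r in seq_len(n_rounds)) {
    thr <- penalty_deriv(b, lambda, penalty, adw, cfg) * sig2 * n_pi
    sol <- cd_penwls(A, bv, sx, sz, sw, thr, b, 200L, 1e-9)
    b <- sol$b
    alpha <- sol$alpha
  }
  list(alpha = alpha, b = b)
}

# Mixing-weight update under the pi-weighted penalty: maximizes
# sum_k T_k log pi_k - n sum_k pi_k P_k subject to sum pi = 1
update_pi <- function(Tk, nP) {
  if (all(nP == 0) || diff(range(nP)) < 1e-12) return(Tk / sum(Tk))
  f <- function(mu) sum(Tk / (mu + nP)) - 1
  lo <- -min(nP) + 1e-9
  hi <- sum(Tk) - min(nP) + 1
  while (f(hi) > 0) hi <- hi * 2
  mu <- uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
  pi_new <- Tk / (mu + nP)
  pi_new / sum(pi_new)
}

penalized_objective <- function(params, des, lambda, penalty, adw, cfg) {
  n <- length(des$w)
  ll <- sum(row_log_sum_exp(component_logdens(params, des) +
                              rep(log(params$pi), each = n)))
  P <- vapply(seq_along(params$pi), function(k) {
    sum(penalty_value(params$beta[, k], lambda, penalty, adw[, k], cfg))
  }, numeric(1))
  ll - n * sum(params$pi * P)
}

# one full EM pass from given parameters; returns trace of the penalized
# objective for the monotonicity contract
run_em <- function(params, des, lambda, penalty, adw, cfg, max_iter) {
  n <- length(des$w)
  obj <- penalized_objective(params, des, lambda, penalty, adw, cfg)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- e_step(params, des)
    K <- length(params$pi)
    # a component is degenerate when no subject belongs to it confidently or
    # when its effective size cannot support the regression scale
    if (any(apply(es$tau, 2, max) < cfg$comp_floor) ||
        any(colSums(es$tau) < 3)) {
      return(list(params = params, trace = trace, converged = FALSE,
                  empty = TRUE))
    }
    # Hathaway-type scale floor: keeps the mixture likelihood bounded by
    # forbidding components from collapsing onto a handful of subjects
    sig_floor <- cfg$sigma_floor_frac * sd(des$w)
    for (k in seq_len(K)) {
      ms <- m_step_component(des$X, es$z[, k], es$tau[, k],
                             params$sigma[k]^2, n * params$pi[k],
                             lambda, penalty, adw[, k],
                             params$intercepts[k], params$beta[, k], cfg)
      params$intercepts[k] <- ms$alpha
      params$beta[, k] <- ms$b
      mu <- ms$alpha + drop(des$X %*% ms$b)
      sw <- sum(es$tau[, k])
      s2 <- sum(es$tau[, k] * ((es$z[, k] - mu)^2 + es$v[, k])) / sw
      params$sigma[k] <- sqrt(max(s2, sig_floor^2))
    }
    P <- vapply(seq_len(K), function(k) {
      sum(penalty_value(params$beta[, k], lambda, penalty, adw[, k], cfg))
    }, numeric(1))
    params$pi <- update_pi(colSums(es$tau), n * P)
    obj_new <- penalized_objective(params, des, lambda, penalty, adw, cfg)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) < cfg$tol * (abs(obj) + 1)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(params = params, trace = trace, converged = converged, empty = FALSE)
}

init_params <- function(des, K, style, cfg) {
  n <- length(des$w)
  d <- ncol(des$X)
  if (style == "kmeans" && K > 1) {
    feat <- cbind(scale(des$w), des$delta)
    km <- kmeans(feat, centers = K, nstart = 5)
    tau <- matrix(0.1 / max(K - 1, 1), n, K)
    tau[cbind(seq_len(n), km$cluster)] <- 0.9
  } else if (K == 1) {
    tau <- matrix(1, n, 1)
  } else {
    tau <- matrix(rgamma(n * K, 1), n, K)
    tau <- tau / rowSums(tau)
  }
  params <- list(pi = pmax(colMeans(tau), 1e-3),
                 intercepts = numeric(K),
                 beta = matrix(0, d, K, dimnames = list(colnames(des$X), NULL)),
                 sigma = rep(sd(des$w) %||% 1, K))
  params$pi <- params$pi / sum(params$pi)
  for (k in seq_len(K)) {
    params$intercepts[k] <- weighted.mean(des$w, tau[, k])
    sk <- sqrt(weighted.mean((des$w - params$intercepts[k])^2, tau[, k]))
    params$sigma[k] <- max(sk, 0.1)
  }
  params
}

# unpenalized weighted LS pilot per component for the adaptive-lasso weights
adaptive_weights <- function(params, des, cfg) {
  K <- length(params$pi)
  d <- ncol(des$X)
  es <- e_step(params, des)
  adw <- matrix(1, d, K)
  for (k in seq_len(K)) {
    ms <- m_step_component(des$X, es$z[, k], es$tau[, k],
                           params$sigma[k]^2, 0, 0, "lasso",
                           rep(1, d), params$intercepts[k],
                           params$beta[, k], cfg)
    adw[, k] <- 1 / (abs(ms$b) + 1e-6)
  }
  # normalize so the lambda scale is comparable to plain lasso
  adw / mean(adw)
}

#' Fit a sparse finite mixture of AFT regressions by penalized EM
#'
#' Maximizes the observed-data log-likelihood minus the mixing-weighted
#' coefficient penalty `n * sum_k pi_k * sum_j p_lambda(|beta_kj|)`.
#' The E-step computes posterior memberships and, for censored subjects,
#' the truncated-normal conditional moments of the latent log-time; the
#' M-step solves a per-component penalized weighted least-squares problem by
#' coordinate descent (soft-thresholding; SCAD and MCP via local linear
#' approximation), with closed-form scale updates and a mixing-weight update
#' that accounts for the penalty's `pi_k` weighting. The penalized objective
#' is non-decreasing across iterations (asserted in tests). When `lambda` is
#' a grid, each value is fitted and the fit with the lowest BIC is returned.
#' Components are canonicalized by ascending intercept, so component 1 is
#' the shortest-survival subpopulation.
#'
#' @param data Survival tibble: `time`, `status` (1 = event), covariates
#'   (all columns except `id`, `time`, `status`).
#' @param K Number of mixture components (>= 1).
#' @param penalty One of `"adaptive-lasso"` (default), `"lasso"`, `"scad"`,
#'   `"mcp"`. Adaptive-lasso weights come from an unpenalized
#'   weighted-least-squares pilot fit.
#' @param lambda Penalty level or grid; default
#'   `exp(seq(log(0.01), log(2), length.out = 8))`.
#' @param em_config An [aft_em_config()].
#' @param seed Integer seed for the multi-start initialization.
#' @return An object of class `fmaft_fit`: `K`, `pi`, `intercepts`, `beta`
#'   (`d x K`, exact zeros), `sigma`, `lambda`, `loglik`, `df`, `bic`,
#'   `tau` (`n x K` posterior memberships), `labels` (hard assignments),
#'   `objective_trace`, `converged`, `n_restarts`, and the `lambda_path`
#'   BIC table.
#' @export
fit_fm_aft <- function(data, K, penalty = c("adaptive-lasso", "lasso",
                                            "scad", "mcp"),
                       lambda = NULL, em_config = aft_em_config(),
                       seed = NULL) {
  penalty <- match.arg(penalty)
  if (K < 1) stop_validation("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) lambda <- exp(seq(log(0.01), log(2), length.out = 8))
  des <- aft_design(data)
  n <- length(des$w)
  d <- ncol(des$X)
  cfg <- em_config

  # multi-start: short EM runs at the smallest lambda, continue the best
  lam0 <- min(lambda)
  adw0 <- matrix(1, d, K)
  starts <- c("kmeans", rep("random", max(cfg$n_init - 1L, 0L)))
  if (K == 1) starts <- "kmeans"
  best <- NULL
  n_restarts <- 0L
  for (st in starts) {
    p0 <- init_params(des, K, st, cfg)
    sh <- run_em(p0, des, lam0, if (penalty == "adaptive-lasso") "lasso"
                 else penalty, adw0, cfg, cfg$init_iter)
    if (sh$empty) {
      n_restarts <- n_restarts + 1L
      next
    }
    score <- sh$trace[length(sh$trace)]
    if (is.null(best) || score > best$score)
      best <- list(params = sh$params, score = score)
  }
  restart_guard <- 0L
  while (is.null(best) && restart_guard < cfg$max_restarts) {
    restart_guard <- restart_guard + 1L
    n_restarts <- n_restarts + 1L
    p0 <- init_params(des, K, "random", cfg)
    sh <- run_em(p0, des, lam0, if (penalty == "adaptive-lasso") "lasso"
                 else penalty, adw0, cfg, cfg$init_iter)
    if (!sh$empty) best <- list(params = sh$params,
                                score = sh$trace[length(sh$trace)])
  }
  if (is.null(best))
    stop_numerical("all initializations collapsed to an empty component")

  adw <- if (penalty == "adaptive-lasso")
    adaptive_weights(best$params, des, cfg) else matrix(1, d, K)

  fits <- vector("list", length(lambda))
  for (li in seq_along(lambda)) {
    em <- run_em(best$params, des, lambda[li], penalty, adw, cfg,
                 cfg$max_iter)
    if (em$empty) {
      n_restarts <- n_restarts + 1L
      em <- run_em(init_params(des, K, "random", cfg), des, lambda[li],
                   penalty, adw, cfg, cfg$max_iter)
    }
    params <- em$params
    params$beta[abs(params$beta) < cfg$zero_tol] <- 0
    ll <- mixture_loglik(params, data)
    df <- sum(params$beta != 0) + K + K + (K - 1)
    fits[[li]] <- list(params = params, loglik = ll, df = df,
                       bic = -2 * ll + df * log(n),
                       trace = em$trace, converged = em$converged && !em$empty,
                       lambda = lambda[li])
  }
  path <- tibble::tibble(
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  pick <- fits[[which.min(path$bic)]]
  params <- canonicalize_components(pick$params)
  es <- e_step(params, des)
  structure(list(
    K = as.integer(K), pi = params$pi, intercepts = params$intercepts,
    beta = params$beta, sigma = params$sigma,
    covariates = des$covars, lambda = pick$lambda, penalty = penalty,
    loglik = pick$loglik, df = pick$df, bic = pick$bic,
    tau = es$tau, labels = max.col(es$tau),
    objective_trace = pick$trace, converged = pick$converged,
    n_restarts = n_restarts, lambda_path = path, n = n
  ), class = "fmaft_fit")
}

# order components by ascending intercept (component 1 = shortest survival)
canonicalize_components <- function(params) {
  ord <- order(params$intercepts)
  list(pi = params$pi[ord], intercepts = params$intercepts[ord],
       beta = params$beta[, ord, drop = FALSE], sigma = params$sigma[ord])
}

#' @export
print.fmaft_fit <- function(x, ...) {
  cat("<fmaft_fit> K =", x$K, " penalty =", x$penalty,
      " lambda =", signif(x$lambda, 3), "\n")
  cat("  pi:", paste(signif(x$pi, 3), collapse = " "),
      " sigma:", paste(signif(x$sigma, 3), collapse = " "), "\n")
  cat("  logLik:", round(x$loglik, 2), " df:", x$df,
      " BIC:", round(x$bic, 2), "\n")
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits the penalized mixture AFT model for each order in `K_range` (each
#' fit does its own multi-start initialization and lambda-grid search) and
#' returns the order with the lowest BIC.
#'
#' @inheritParams fit_fm_aft
#' @param K_range Orders to fit (default `1:7`).
#' @return An object of class `fmaft_selection`: `best_k`, `best_fit`,
#'   `fits` (all fitted objects), and `table` (K, logLik, df, BIC,
#'   converged).
#' @export
select_order <- function(data, K_range = 1:7,
                         penalty = c("adaptive-lasso", "lasso", "scad", "mcp"),
                         lambda = NULL, em_config = aft_em_config(),
                         seed = NULL) {
  penalty <- match.arg(penalty)
  seed <- seed %||% 1L
  fits <- lapply(seq_along(K_range), function(i) {
    fit_fm_aft(data, K_range[i], penalty, lambda, em_config,
               seed = derive_seed(seed, i))
  })
  tab <- tibble::tibble(
    K = K_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  best <- which.min(tab$bic)
  structure(list(best_k = K_range[best], best_fit = fits[[best]],
                 fits = fits, table = tab),
            class = "fmaft_selection")
}

#' @export
print.fmaft_selection <- function(x, ...) {
  cat("<fmaft_selection> best K =", x$best_k, "\n")
  print(x$table)
  invisible(x)
}

#' Posterior component membership of a fitted mixture AFT model
#'
#' Recomputes the final E-step posterior probabilities, hard labels
#' (argmax), and per-status summaries (mean membership among subjects with
#' and without an observed event).
#'
#' @param fit An `fmaft_fit`.
#' @param data The survival tibble the model was fitted to.
#' @return A list with `tau` (n x K, rows sum to 1), `labels`, and
#'   `by_status` (tibble of mean memberships stratified by event status).
#' @export
posterior_membership <- function(fit, data) {
  des <- aft_design(data)
  params <- list(pi = fit$pi, intercepts = fit$intercepts,
                 beta = fit$beta, sigma = fit$sigma)
  es <- e_step(params, des)
  tau_tb <- tibble::as_tibble(es$tau, .name_repair = ~paste0("mean_tau_", seq_len(fit$K)))
  by_status <- dplyr::bind_cols(tibble::tibble(status = des$delta), tau_tb) |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("mean_tau_"), mean),
                     n = dplyr::n())
  list(tau = es$tau, labels = max.col(es$tau), by_status = by_status)
}
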