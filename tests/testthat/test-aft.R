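# small two-component dataset used across blocks
aft_sim <- function(n = 200L, seed = 71, censoring = 0.25) {
  beta <- matrix(0, 4, 2, dimnames = list(paste0("g", 1:4), NULL))
  beta[1, 1] <- -2
  beta[2, 2] <- 1.5
  simulate_survival(survival_sim_spec(
    n_subjects = n, component_probs = c(0.5, 0.5), intercepts = c(1, 6),
    coefficients = beta, sigmas = c(0.5, 0.5), censoring_rate = censoring,
    covariate_correlation = 0.2, seed = seed
  ))
}

test_that("mixture log-likelihood matches term-by-term closed forms", {
  set.seed(72)
  n <- 50L
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  lt <- 1 + X %*% c(0.5, -1) + rnorm(n)
  data <- dplyr::bind_cols(tibble::tibble(id = 1:n, time = exp(drop(lt)),
                                          status = 1L),
                           tibble::as_tibble(X))
  params <- list(pi = 1, intercepts = 1, beta = matrix(c(0.5, -1), 2, 1),
                 sigma = 1.2)
  ours <- mixture_loglik(params, data)
  mu <- 1 + drop(X %*% c(0.5, -1))
  oracle <- sum(dnorm(drop(lt), mu, 1.2, log = TRUE))
  expect_equal(ours, oracle, tolerance = 1e-10)
  expect_error(mixture_loglik(modifyList(params, list(sigma = -1)), data),
               class = "methaft_validation_error")
})

test_that("censored contributions match quadrature of the density tail", {
  params <- list(pi = 1, intercepts = 0.5, beta = matrix(0.8, 1, 1),
                 sigma = 0.9)
  x <- 0.3
  t_obs <- 2.5
  data <- tibble::tibble(id = 1L, time = t_obs, status = 0L, g = x)
  ours <- mixture_loglik(params, data)
  mu <- 0.5 + 0.8 * x
  tail_mass <- stats::integrate(function(w) dnorm(w, mu, 0.9),
                                lower = log(t_obs), upper = Inf,
                                rel.tol = 1e-12)$value
  expect_equal(ours, log(tail_mass), tolerance = 1e-8)
  # near-zero observed time: survival factor tends to 1, contribution to 0
  tiny <- tibble::tibble(id = 1L, time = 1e-12, status = 0L, g = x)
  expect_lt(abs(mixture_loglik(params, tiny)), 1e-6)
})

test_that("K = 1 with lambda = 0 and no censoring reduces to least squares", {
  set.seed(73)
  n <- 120L
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  lt <- 2 + drop(X %*% c(1, 0, -0.5)) + 0.6 * rnorm(n)
  data <- dplyr::bind_cols(tibble::tibble(id = 1:n, time = exp(lt),
                                          status = 1L),
                           tibble::as_tibble(X))
  fit <- fit_fm_aft(data, K = 1, penalty = "lasso", lambda = 0, seed = 73)
  ols <- lm(lt ~ X)
  expect_equal(fit$intercepts, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$beta[, 1]), unname(coef(ols)[-1]), tolerance = 1e-6)
})

test_that("K = 1 with censoring matches the parametric survival oracle", {
  sim <- aft_sim(n = 250L, seed = 74)
  data <- sim$data[, c("id", "time", "status", "g1", "g2")]
  data <- data[sim$truth$component == 1, ]  # single-component subset
  fit <- fit_fm_aft(data, K = 1, penalty = "lasso", lambda = 0, seed = 74)
  oracle <- survival::survreg(
    survival::Surv(time, status) ~ g1 + g2, data = data,
    dist = "lognormal"
  )
  expect_equal(fit$intercepts, unname(coef(oracle)[1]), tolerance = 1e-3)
  expect_equal(unname(fit$beta[, 1]), unname(coef(oracle)[-1]),
               tolerance = 1e-3)
  expect_equal(fit$sigma, oracle$scale, tolerance = 5e-3)
})

test_that("full shrinkage drives every coefficient exactly to zero", {
  sim <- aft_sim(n = 150L, seed = 75)
  fit <- fit_fm_aft(sim$data, K = 1, penalty = "lasso", lambda = 50,
                    seed = 75)
  expect_true(all(fit$beta == 0))
  # intercept equals the weighted mean of the imputed log-times: with K = 1
  # and no covariates this is the censored-normal MLE location, which must
  # be at least the naive mean of observed log-times
  expect_gte(fit$intercepts, mean(log(sim$data$time)))
})

test_that("penalized EM objective is monotone non-decreasing", {
  sim <- aft_sim(n = 180L, seed = 76)
  fit <- fit_fm_aft(sim$data, K = 2, penalty = "adaptive-lasso", seed = 76)
  dtrace <- diff(fit$objective_trace)
  expect_true(all(dtrace > -1e-6 * (abs(fit$objective_trace[-1]) + 1)))
})

test_that("posterior memberships are proper and recover planted components", {
  sim <- aft_sim(n = 250L, seed = 77)
  fit <- fit_fm_aft(sim$data, K = 2, penalty = "adaptive-lasso", seed = 77)
  pm <- posterior_membership(fit, sim$data)
  expect_equal(rowSums(pm$tau), rep(1, nrow(sim$data)), tolerance = 1e-8)
  expect_true(all(pm$tau >= 0))
  # strong separation: confident assignments
  expect_gte(mean(apply(pm$tau, 1, max)), 0.95)
  # Rand-type agreement with the planted memberships
  agree <- mean(pm$labels == sim$truth$component)
  expect_gte(max(agree, 1 - agree), 0.9)
})

test_that("BIC identity holds and order selection finds the truth", {
  sim <- aft_sim(n = 220L, seed = 78)
  sel <- select_order(sim$data, K_range = 1:3, seed = 78)
  expect_identical(sel$best_k, 2L)
  # BIC strictly recomputable from stored logLik and df
  expect_equal(sel$table$bic,
               -2 * sel$table$loglik + sel$table$df * log(nrow(sim$data)),
               tolerance = 1e-10)
  # single-component data selects K = 1
  one <- simulate_survival(survival_sim_spec(
    n_subjects = 200L, component_probs = 1, intercepts = 2,
    coefficients = matrix(c(1, 0, 0), 3, 1), sigmas = 0.8,
    censoring_rate = 0.2, seed = 79
  ))
  sel1 <- select_order(one$data, K_range = 1:3, seed = 79)
  expect_identical(sel1$best_k, 1L)
})

test_that("degenerate one-component mixtures give unit memberships", {
  sim <- aft_sim(n = 100L, seed = 80)
  fit <- fit_fm_aft(sim$data, K = 1, penalty = "lasso", lambda = 0.05,
                    seed = 80)
  pm <- posterior_membership(fit, sim$data)
  expect_true(all(pm$tau[, 1] == 1))
})

test_that("tidiers expose the fit in standard layouts", {
  sim <- aft_sim(n = 120L, seed = 81)
  fit <- fit_fm_aft(sim$data, K = 2, penalty = "lasso", seed = 81)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L * (1L + 4L))
  expect_true(all(c("component", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$K, 2L)
  expect_equal(gl$BIC, fit$bic)
  ct <- coefficient_table(fit)
  expect_identical(names(ct), c("term", "comp1", "comp2"))
  # components canonicalized by ascending intercept
  expect_lte(fit$intercepts[1], fit$intercepts[2])
})
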