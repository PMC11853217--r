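test_that("theta full conditional matches the conjugate Beta closed form", {
  # states held fixed with one state: theta | data ~ Beta(a + Ty, b + Tm - Ty)
  set.seed(11)
  L <- 30L
  m <- rep(12L, L)
  y <- rbinom(L, m, 0.35)
  Ty <- sum(y)
  Tm <- sum(m)
  cfg <- mcmc_config(alpha = 2, beta = 3)
  # with K = 1 the path is fixed, so the sweep's theta draw is exactly the
  # conjugate full conditional; compare its moments to the closed form
  p <- hmm_params(0.5, trans = matrix(1, 2, 1))
  th_draws <- numeric(4000)
  states <- rep(1L, L)
  set.seed(12)
  for (i in seq_along(th_draws)) {
    sw <- gibbs_sweep(p, states, y, m, rep(FALSE, L), cfg)
    th_draws[i] <- sw$params$thetas
  }
  post_mean <- (2 + Ty) / (2 + 3 + Tm)
  post_sd <- sqrt(post_mean * (1 - post_mean) / (2 + 3 + Tm + 1))
  mc_se <- post_sd / sqrt(length(th_draws))
  expect_lt(abs(mean(th_draws) - post_mean), 3 * mc_se * 1.5)
  expect_lt(abs(sd(th_draws) - post_sd), 3 * post_sd / sqrt(2 * length(th_draws)) * 1.5)
})

test_that("with no observed data the sweep reproduces the Beta prior", {
  L <- 25L
  cfg <- mcmc_config(alpha = 2, beta = 5)
  p <- hmm_params(0.5, trans = matrix(1, 2, 1))
  states <- rep(1L, L)
  set.seed(13)
  draws <- replicate(5000, {
    sw <- gibbs_sweep(p, states, rep(NA_integer_, L), rep(NA_integer_, L),
                      rep(TRUE, L), cfg)
    sw$params$thetas
  })
  prior_mean <- 2 / 7
  prior_sd <- sqrt(prior_mean * (1 - prior_mean) / 8)
  expect_lt(abs(mean(draws) - prior_mean), 3 * prior_sd / sqrt(5000))
})

test_that("long-run Gibbs state frequencies match enumeration posteriors", {
  # fixed parameters, tiny instance: FFBS path marginals vs brute force
  set.seed(14)
  th <- c(0.2, 0.8)
  init <- c(0.6, 0.4)
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  p <- hmm_params(th, trans = rbind(init, P))
  y <- c(1L, 7L, NA, 2L)
  m <- c(9L, 9L, NA, 10L)
  missing <- is.na(y)
  oracle <- oracle_state_marginals(th, init, P, y, m, missing)
  n_draw <- 2e4
  freq <- matrix(0, 4, 2)
  for (i in seq_len(n_draw)) {
    s <- methaft:::draw_states(p, y, m, missing)
    freq[cbind(1:4, s)] <- freq[cbind(1:4, s)] + 1
  }
  freq <- freq / n_draw
  se <- sqrt(oracle * (1 - oracle) / n_draw)
  expect_true(all(abs(freq - oracle) < 3 * pmax(se, 1e-3)))
})

test_that("fixed-order sampler preserves the prior (successive-conditional check)", {
  # Geweke-style: alternately redraw data given parameters and parameters
  # given data; the stationary marginal of theta is the prior. With K = 2
  # and flat Beta priors, the sorted propensities have prior means 1/3, 2/3.
  set.seed(16)
  L <- 20L
  m <- rep(3L, L)  # weakly informative data so the joint chain mixes fast
  cfg <- mcmc_config(alpha = 1, beta = 1)
  p <- hmm_params(c(0.3, 0.7))
  states <- rep(1:2, 10)
  n_keep <- 8000L
  th1 <- numeric(n_keep)
  th2 <- numeric(n_keep)
  for (i in seq_len(n_keep)) {
    y <- rbinom(L, m, p$thetas[states])
    sw <- gibbs_sweep(p, states, y, m, rep(FALSE, L), cfg)
    p <- sw$params
    states <- sw$states
    th1[i] <- p$thetas[1]
    th2[i] <- p$thetas[2]
  }
  # Monte-Carlo s.e. by batch means (accounts for chain autocorrelation)
  batch_se <- function(x, n_batch = 40L) {
    bm <- colMeans(matrix(x, ncol = n_batch))
    sd(bm) / sqrt(n_batch)
  }
  expect_lt(abs(mean(th1) - 1 / 3), 3 * batch_se(th1))
  expect_lt(abs(mean(th2) - 2 / 3), 3 * batch_se(th2))
})

test_that("sweep keeps thetas sorted with states relabelled consistently", {
  set.seed(15)
  sim <- small_sim(seed = 15, L = 60L, n_per = 1L)
  y <- sim$panel$counts[, 1]
  m <- sim$panel$depths[, 1]
  mis <- sim$panel$missing[, 1]
  p <- hmm_params(c(0.4, 0.6))
  states <- rep(1:2, length.out = 60)
  for (i in 1:20) {
    sw <- gibbs_sweep(p, states, y, m, mis)
    p <- sw$params
    states <- sw$states
    expect_false(is.unsorted(p$thetas))
    expect_true(all(states >= 1 & states <= p$K))
  }
})
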