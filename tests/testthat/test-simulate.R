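test_that("panel spec validation rejects malformed inputs", {
  expect_error(panel_sim_spec(true_order = 0), class = "methaft_validation_error")
  expect_error(panel_sim_spec(true_thetas = c(0.5, 0.2, 0.9)),
               class = "methaft_validation_error")
  bad_tm <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2)
  expect_error(panel_sim_spec(true_order = 2, true_thetas = c(0.2, 0.8),
                              transition_matrix = bad_tm),
               class = "methaft_validation_error")
  expect_error(survival_sim_spec(censoring_rate = 1.2),
               class = "methaft_validation_error")
})

test_that("simulation is reproducible bit-for-bit given spec and seed", {
  a <- small_sim(seed = 7)
  b <- small_sim(seed = 7)
  expect_identical(a$panel$counts, b$panel$counts)
  expect_identical(a$panel$missing, b$panel$missing)
  expect_identical(a$truth, b$truth)
  s1 <- simulate_survival(survival_sim_spec(seed = 9))
  s2 <- simulate_survival(survival_sim_spec(seed = 9))
  expect_identical(s1$data, s2$data)
})

test_that("zero missing rate yields a complete panel", {
  sim <- simulate_panel(panel_sim_spec(n_positions = 80, missing_rate = 0,
                                       depth_dispersion = 50, seed = 3))
  expect_false(any(sim$panel$missing))
})

test_that("single-state counts are marginally binomial with the right mean", {
  # K* = 1, theta = 0.5, depth fixed at 10 via a near-degenerate NB
  sim <- simulate_panel(panel_sim_spec(
    n_positions = 1e5, n_samples_per_group = 1L, true_order = 1L,
    true_thetas = 0.5, depth_mean = 10, depth_dispersion = 1e9,
    missing_rate = 0, seed = 11
  ))
  ratio <- sim$panel$counts[, 1] / sim$panel$depths[, 1]
  expect_gt(mean(ratio, na.rm = TRUE), 0.495)
  expect_lt(mean(ratio, na.rm = TRUE), 0.505)
})

test_that("null panels are exchangeable across groups (exact-test calibration)", {
  # dmc_fraction = 0: per-position Fisher tests on pooled counts should be
  # FDR-significant for about the nominal share of positions
  n_sig <- 0L
  n_tot <- 0L
  for (seed in 1:5) {
    sim <- simulate_panel(panel_sim_spec(
      n_positions = 150, n_samples_per_group = 6L, dmc_fraction = 0,
      missing_rate = 0.1, seed = seed
    ))
    p <- vapply(seq_along(sim$panel$positions), function(l) {
      ok <- !sim$panel$missing[l, ]
      case <- ok & sim$panel$groups == "case"
      ctrl <- ok & sim$panel$groups == "control"
      if (sum(case) < 2 || sum(ctrl) < 2) return(NA_real_)
      y1 <- sum(sim$panel$counts[l, case]); m1 <- sum(sim$panel$depths[l, case])
      y0 <- sum(sim$panel$counts[l, ctrl]); m0 <- sum(sim$panel$depths[l, ctrl])
      stats::fisher.test(matrix(c(y1, m1 - y1, y0, m0 - y0), 2))$p.value
    }, numeric(1))
    p <- p[!is.na(p)]
    n_sig <- n_sig + sum(p < 0.05)
    n_tot <- n_tot + length(p)
  }
  # pooled counts across samples make Fisher conservative; the share of
  # raw-p significance must stay at or below ~5% plus Monte-Carlo noise
  expect_lt(n_sig / n_tot, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("hidden-path marginals match the stationary distribution", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  statn <- c(2, 1) / 3  # left eigenvector of P
  sim <- simulate_panel(panel_sim_spec(
    n_positions = 20000, n_samples_per_group = 1L, true_order = 2L,
    true_thetas = c(0.2, 0.8), transition_matrix = P,
    initial_probs = statn, missing_rate = 0, seed = 13
  ))
  freq <- mean(sim$truth$state == 1)
  se <- sqrt(statn[1] * statn[2] / 20000) * sqrt((1 + 0.7) / (1 - 0.7))
  expect_lt(abs(freq - statn[1]), 3 * se)
})

test_that("survival generator hits the censoring target and the mixture shape", {
  spec <- survival_sim_spec(n_subjects = 1000L, seed = 21)
  sim <- simulate_survival(spec)
  expect_lt(abs(mean(1 - sim$data$status) - spec$censoring_rate), 0.05)
  # degenerate mixture: all memberships equal 1
  one <- simulate_survival(survival_sim_spec(
    n_subjects = 100L, component_probs = c(1, 0), seed = 22
  ))
  expect_true(all(one$truth$component == 1))
})

test_that("uncensored single-component log-times are standard normal", {
  spec <- survival_sim_spec(
    n_subjects = 2000L, component_probs = 1, intercepts = 0,
    coefficients = matrix(0, 3, 1), sigmas = 1, censoring_rate = 0.01,
    covariate_correlation = 0, seed = 23
  )
  sim <- simulate_survival(spec)
  lt <- log(sim$data$time[sim$data$status == 1])
  expect_gt(stats::ks.test(lt, "pnorm")$p.value, 0.01)
})

test_that("two-component defaults produce a bimodal log-time distribution", {
  sim <- simulate_survival(survival_sim_spec(
    n_subjects = 5000L, coefficients = matrix(0, 19, 2),
    censoring_rate = 0.05, seed = 25
  ))
  lt <- log(sim$data$time[sim$data$status == 1])
  d <- density(lt)
  # modes near the two intercepts 1.83 and 5.48
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expect_true(any(abs(peaks - 1.83) < 0.5))
  expect_true(any(abs(peaks - 5.48) < 0.5))
})

test_that("panel TSV round-trips exactly", {
  sim <- small_sim(seed = 31)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(sim$panel, f)
  back <- read_panel(f)
  expect_identical(back$counts, sim$panel$counts)
  expect_identical(back$depths, sim$panel$depths)
  expect_identical(back$groups, sim$panel$groups)
  expect_identical(back$positions, sim$panel$positions)
})

test_that("depth filter masks entries above the cap", {
  counts <- matrix(c(5L, 5L, 5L, 5L), 2, 2)
  depths <- matrix(c(10L, 600L, 10L, 10L), 2, 2)
  p <- methylation_panel("chr1", c(10L, 20L), counts, depths,
                         groups = c("case", "control"))
  expect_true(p$missing[2, 1])
  expect_false(p$missing[1, 1])
  expect_true(is.na(p$counts[2, 1]))
})
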