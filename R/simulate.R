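#' Simulate a bisulfite count panel with known truth
#'
#' Draws a hidden state path from the Markov chain in `spec`, negative
#' binomial read-depths (capped by masking at `depth_cap`), binomial
#' methylated counts given depth and the state's methylation propensity, and
#' independent entry-wise missingness. A random `dmc_fraction` of positions
#' carries a case-group shift of the propensity on the logit scale, with a
#' random sign per position, emulating hyper- and hypo-methylated
#' differential cytosines.
#'
#' @param spec A [panel_sim_spec()].
#' @return A list with elements `panel` (a [methylation_panel()]) and
#'   `truth` (a tibble with `pos`, `state`, `dmc`, `direction`, `theta_control`,
#'   `theta_case`).
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_sim_spec"))
    stop_validation("`spec` must be a panel_sim_spec")
  set.seed(spec$seed)
  L <- spec$n_positions
  K <- spec$true_order
  n_per <- spec$n_samples_per_group
  n <- 2L * n_per
  groups <- rep(c("control", "case"), each = n_per)

  # hidden path shared across samples (the state structure of the locus)
  states <- integer(L)
  states[1] <- sample.int(K, 1, prob = spec$initial_probs)
  if (L > 1) {
    for (l in 2:L) {
      states[l] <- sample.int(K, 1, prob = spec$transition_matrix[states[l - 1], ])
    }
  }

  dmc <- runif(L) < spec$dmc_fraction
  direction <- integer(L)
  direction[dmc] <- sample(c(-1L, 1L), sum(dmc), replace = TRUE)

  theta_control <- spec$true_thetas[states]
  theta_case <- inv_logit(logit(theta_control) + direction * spec$effect_size)

  depths <- matrix(rnbinom(L * n, size = spec$depth_dispersion,
                           mu = spec$depth_mean), L, n)
  theta_mat <- cbind(matrix(theta_control, L, n_per),
                     matrix(theta_case, L, n_per))
  counts <- matrix(rbinom(L * n, size = as.vector(depths),
                          prob = as.vector(theta_mat)), L, n)
  missing <- matrix(runif(L * n) < spec$missing_rate, L, n)
  missing <- missing | depths == 0L

  positions <- sort(sample.int(max(20L * L, L + 10L), L))
  panel <- methylation_panel(
    chrom = "chrSim", positions = positions, counts = counts, depths = depths,
    missing = missing, groups = groups, depth_cap = spec$depth_cap
  )
  truth <- tibble::tibble(
    chrom = "chrSim", pos = positions, state = states, dmc = dmc,
    direction = direction, theta_control = theta_control,
    theta_case = theta_case
  )
  list(panel = panel, truth = truth)
}

#' Simulate a right-censored survival dataset from a mixture AFT model
#'
#' Each subject is assigned a latent component, log survival time is
#' `intercept_k + x beta_k + sigma_k * N(0, 1)`, and an independent
#' exponential censoring time is drawn with its rate solved numerically so
#' the expected censoring fraction equals `spec$censoring_rate`. Covariates
#' are exchangeable-correlation standard normals, mean-centered by column.
#'
#' @param spec A [survival_sim_spec()].
#' @return A list with `data` (tibble: `id`, `time`, `status` with 1 = event,
#'   plus one column per covariate) and `truth` (tibble with the latent
#'   `component` and the uncensored `log_time`).
#' @export
simulate_survival <- function(spec) {
  if (!inherits(spec, "survival_sim_spec"))
    stop_validation("`spec` must be a survival_sim_spec")
  set.seed(spec$seed)
  n <- spec$n_subjects
  d <- spec$n_covariates
  rho <- spec$covariate_correlation
  z0 <- rnorm(n)
  X <- sqrt(rho) * matrix(z0, n, d) + sqrt(1 - rho) * matrix(rnorm(n * d), n, d)
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  nm <- rownames(spec$coefficients)
  colnames(X) <- if (!is.null(nm)) nm else paste0("x", seq_len(d))

  comp <- sample.int(length(spec$component_probs), n, replace = TRUE,
                     prob = spec$component_probs)
  mu <- spec$intercepts[comp] +
    rowSums(X * t(spec$coefficients)[comp, , drop = FALSE])
  log_t <- mu + spec$sigmas[comp] * rnorm(n)
  t_event <- exp(log_t)

  # exponential censoring rate solved so that E[fraction censored] hits target
  frac <- function(rate) mean(1 - exp(-rate * t_event))
  hi <- 1
  while (frac(hi) < spec$censoring_rate && hi < 1e12) hi <- hi * 10
  rate <- uniroot(function(r) frac(r) - spec$censoring_rate,
                  lower = 0, upper = hi, tol = 1e-12)$root
  c_time <- rexp(n, rate = rate)
  time <- pmin(t_event, c_time)
  status <- as.integer(t_event <= c_time)

  data <- tibble::tibble(id = seq_len(n), time = time, status = status) |>
    dplyr::bind_cols(tibble::as_tibble(X))
  truth <- tibble::tibble(id = seq_len(n), component = comp, log_time = log_t,
                          censoring_rate_used = rate)
  list(data = data, truth = truth)
}

#' Write / read a survival dataset TSV
#'
#' Columns: `id`, `time`, `status` (1 = event, 0 = censored), then one
#' column per covariate.
#'
#' @param data Survival tibble as produced by [simulate_survival()].
#' @param path File path.
#' @export
write_survival <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("id", "time", "status") %in% names(out)))
    stop_validation("survival table must have id, time, status columns")
  if (any(out$time <= 0)) stop_validation("survival times must be positive")
  out
}

#' Simulate a BED-like genomic feature annotation over panel positions
#'
#' Builds non-pathological promoter/island/shore/shelf/exon/intron intervals
#' tiling the simulated chromosome so that annotation and gene-aggregation
#' operations are testable without a genome database. Genes are laid out as
#' promoter + exon/intron blocks; islands (with flanking shores and shelves)
#' are interleaved, some overlapping promoters.
#'
#' @param positions Integer positions the annotation should span.
#' @param n_genes Number of genes to lay out.
#' @param seed Integer seed.
#' @return A tibble in BED6+2 layout: `chrom`, `start` (0-based), `end`,
#'   `name`, `score`, `strand`, `feature_class`, `gene_id`.
#' @export
simulate_annotation <- function(positions, n_genes = 20L, seed = 1L) {
  set.seed(seed)
  span <- max(positions) + 100L
  gene_starts <- sort(sample.int(span, n_genes))
  width <- pmax(diff(c(gene_starts, span + 2000L)) - 10L, 60L)
  rows <- purrr::map2_dfr(gene_starts, width, function(s, w) {
    gene <- paste0("G", s)
    prom_w <- max(20L, round(w * 0.2))
    exon_w <- max(20L, round(w * 0.3))
    tibble::tibble(
      start = c(s, s + prom_w, s + prom_w + exon_w),
      end = c(s + prom_w, s + prom_w + exon_w, s + w),
      feature_class = c("promoter", "exon", "intron"),
      gene_id = gene
    )
  })
  # CpG islands with shores/shelves, occasionally overlapping promoters
  isl_starts <- sort(sample.int(span, max(3L, n_genes %/% 2L)))
  isl <- purrr::map_dfr(isl_starts, function(s) {
    w <- sample(40:120, 1)
    tibble::tibble(
      start = c(s, pmax(0L, s - 60L), s + w, pmax(0L, s - 120L), s + w + 60L),
      end = c(s + w, s, s + w + 60L, pmax(0L, s - 60L), s + w + 120L),
      feature_class = c("island", "shore", "shore", "shelf", "shelf"),
      gene_id = NA_character_
    )
  }) |> dplyr::filter(.data$start < .data$end)
  out <- dplyr::bind_rows(rows, isl)
  tibble::tibble(
    chrom = "chrSim", start = as.integer(out$start), end = as.integer(out$end),
    name = dplyr::coalesce(out$gene_id, out$feature_class), score = 0L,
    strand = "+", feature_class = out$feature_class, gene_id = out$gene_id
  ) |> dplyr::arrange(.data$start, .data$end)
}
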