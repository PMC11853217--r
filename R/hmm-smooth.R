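#' Smooth one sample's methylation profile by trans-dimensional MCMC
#'
#' Runs the full reversible-jump chain on a single sample's counts: each
#' iteration performs one Gibbs sweep (propensities, transition rows, state
#' path), one split-merge move on the order, and the state-collapse penalty;
#' the underfitting trigger is re-evaluated every
#' `config$penalty_check_interval` iterations and cached in between. The
#' fitted methylation level at each position is the average of
#' `theta[state]` over retained (post-burn-in, thinned) draws, which is
#' defined at missing positions too (model-based imputation) and always lies
#' strictly inside (0, 1).
#'
#' @param y,m Integer vectors of methylated counts and depths for one sample.
#' @param missing Logical vector; defaults to `NA` entries of `y`/`m`.
#' @param config An [mcmc_config()]; `config$seed` (if non-`NULL`) seeds the
#'   chain.
#' @return A list with `fitted` (per-position posterior-mean level),
#'   `order_trace` (retained draws of `K`), `acceptance` (tibble of
#'   split/merge proposal and acceptance counts), and `n_retained`.
#' @export
smooth_sample <- function(y, m, missing = NULL, config = mcmc_config()) {
  if (is.null(missing)) missing <- is.na(y) | is.na(m)
  L <- length(y)
  if (all(missing))
    stop_validation("sample has no observed positions: nothing to smooth")
  if (!is.null(config$seed)) set.seed(config$seed)

  # initialization: two states at the observed methylation-ratio quantiles
  ratio <- (y + 0.5) / (m + 1)
  ratio[missing] <- NA
  K0 <- min(2L, config$k_max)
  q <- quantile(ratio, probs = seq(0.25, 0.75, length.out = K0), na.rm = TRUE)
  th0 <- clamp_unit(sort(unique(pmin(pmax(q, 0.05), 0.95))))
  if (length(th0) < K0) th0 <- clamp_unit(th0 + seq(0, 0.1, length.out = length(th0))) # degenerate data
  K0 <- length(th0)
  params <- hmm_params(th0, hyper = list(alpha = config$alpha,
                                         beta = config$beta,
                                         gamma = config$gamma,
                                         k_max = config$k_max))
  states <- rep(1L, L)
  obsr <- ratio
  obsr[missing] <- mean(ratio, na.rm = TRUE)
  states <- max.col(-abs(outer(obsr, th0, "-")))

  retain <- seq(config$burn_in + 1L, config$n_iter, by = config$thin)
  fitted_sum <- numeric(L)
  order_trace <- integer(length(retain))
  acc <- c(split_prop = 0L, split_acc = 0L, merge_prop = 0L, merge_acc = 0L)
  underfit <- FALSE
  r_idx <- 1L

  for (it in seq_len(config$n_iter)) {
    sw <- gibbs_sweep(params, states, y, m, missing, config)
    params <- sw$params
    states <- sw$states

    if (config$underfit_penalty_weight > 1 &&
        (it == 1L || it %% config$penalty_check_interval == 0L)) {
      underfit <- as.logical(underfit_flag(params, states, y, m, missing, config))
    }
    mv <- split_merge_move(params, states, y, m, missing, config, underfit)
    if (mv$move == "split") {
      acc["split_prop"] <- acc["split_prop"] + 1L
      if (mv$accepted) acc["split_acc"] <- acc["split_acc"] + 1L
    } else if (mv$move == "merge") {
      acc["merge_prop"] <- acc["merge_prop"] + 1L
      if (mv$accepted) acc["merge_acc"] <- acc["merge_acc"] + 1L
    }
    params <- mv$params
    states <- mv$states

    pen <- apply_penalties(params, states, config)
    params <- pen$params
    states <- pen$states

    if (r_idx <= length(retain) && it == retain[r_idx]) {
      fitted_sum <- fitted_sum + params$thetas[states]
      order_trace[r_idx] <- params$K
      r_idx <- r_idx + 1L
    }
  }
  acceptance <- tibble::tibble(
    move = c("split", "merge"),
    proposed = c(acc[["split_prop"]], acc[["merge_prop"]]),
    accepted = c(acc[["split_acc"]], acc[["merge_acc"]])
  )
  list(fitted = fitted_sum / length(retain), order_trace = order_trace,
       acceptance = acceptance, n_retained = length(retain))
}

#' Smooth every sample of a methylation panel
#'
#' Runs [smooth_sample()] independently per sample (the chains are
#' embarrassingly parallel in principle; here they run sequentially with
#' per-sample seeds derived from `config$seed` by fixed offsets, so results
#' are reproducible).
#'
#' @param panel A [methylation_panel()].
#' @param config An [mcmc_config()]; `config$seed` is the master seed
#'   (default 1 when `NULL`).
#' @return An object of class `smoothed_profile`: fitted `L x n` levels,
#'   per-sample order traces and acceptance tables, plus the panel's
#'   coordinates, groups, and observation mask.
#' @export
smooth_panel <- function(panel, config = mcmc_config()) {
  master <- config$seed %||% 1L
  n <- length(panel$sample_ids)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(master, i)
    fits[[i]] <- smooth_sample(panel$counts[, i], panel$depths[, i],
                               panel$missing[, i], cfg_i)
  }
  fitted <- vapply(fits, `[[`, numeric(length(panel$positions)), "fitted")
  fitted <- matrix(fitted, ncol = n, dimnames = list(NULL, panel$sample_ids))
  structure(
    list(chrom = panel$chrom, positions = panel$positions, fitted = fitted,
         groups = panel$groups, sample_ids = panel$sample_ids,
         observed = !panel$missing,
         order_traces = lapply(fits, `[[`, "order_trace"),
         acceptance = lapply(fits, `[[`, "acceptance"),
         master_seed = master),
    class = "smoothed_profile"
  )
}

#' @export
print.smoothed_profile <- function(x, ...) {
  modal_k <- vapply(x$order_traces, function(tr) {
    as.integer(names(which.max(table(tr))))
  }, integer(1))
  cat("<smoothed_profile> ", length(x$positions), " positions x ",
      length(x$sample_ids), " samples; modal orders: ",
      paste(modal_k, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.smoothed_profile <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom,
    pos = rep(x$positions, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$positions)),
    group = rep(x$groups, each = length(x$positions)),
    fitted = as.vector(x$fitted),
    observed = as.vector(x$observed)
  )
}

#' Write a smoothed profile as TSV plus a JSON diagnostics sidecar
#'
#' The TSV has `chrom`, `pos`, and one fitted-level column per sample; the
#' sidecar (same path with `.json` appended) stores the order-trace
#' histograms, split/merge acceptance rates, and the master seed.
#'
#' @param profile A `smoothed_profile`.
#' @param path Output TSV path.
#' @export
write_profile <- function(profile, path) {
  tab <- tibble::as_tibble(as.data.frame(profile$fitted))
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = profile$chrom, pos = profile$positions), tab
  )
  readr::write_tsv(out, path)
  diag <- list(
    master_seed = profile$master_seed,
    groups = as.list(setNames(profile$groups, profile$sample_ids)),
    order_histogram = lapply(profile$order_traces,
                             function(tr) as.list(table(tr))),
    acceptance = lapply(profile$acceptance, function(a) {
      list(split = list(proposed = a$proposed[1], accepted = a$accepted[1]),
           merge = list(proposed = a$proposed[2], accepted = a$accepted[2]))
    })
  )
  jsonlite::write_json(diag, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
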