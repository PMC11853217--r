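#' Logit-transform fitted methylation levels
#'
#' Elementwise `log(x / (1 - x))`. Fitted levels from the smoother are
#' posterior means of Beta-supported propensities and therefore lie strictly
#' inside (0, 1); a value at the boundary signals an upstream bug and is an
#' error rather than being clipped.
#'
#' @param fitted Numeric vector or matrix with entries strictly in (0, 1).
#' @return Object of the same shape on the logit scale.
#' @export
logit_transform <- function(fitted) {
  if (any(fitted <= 0 | fitted >= 1, na.rm = TRUE))
    stop_numerical("fitted levels must lie strictly inside (0, 1)")
  log(fitted / (1 - fitted))
}

#' Per-CpG two-group test on logit methylation levels
#'
#' Fits, at each CpG, a conjugate normal linear model of the logit fitted
#' levels on the group indicator with a Zellner g-prior (g = number of
#' samples used) on the coefficients and the reference prior on the
#' variance. The reported effect is the posterior-mean case-minus-control
#' difference (the least-squares difference shrunk by g / (1 + g)); the
#' posterior t-statistic is a strictly monotone transform of the classical
#' two-sample t statistic, so the p-value is computed from that statistic's
#' exact null distribution and is exactly calibrated under the null.
#'
#' Only samples with observed reads at the CpG enter the test; CpGs with
#' fewer than `min_per_group` observed samples in either group are flagged
#' untestable (`NA` effect and p) and are excluded from the FDR family.
#'
#' @param logit_levels `L x n` matrix of logit fitted levels.
#' @param groups Per-sample labels, `"case"` or `"control"`.
#' @param observed Optional `L x n` logical matrix of observation
#'   indicators; default all observed.
#' @param min_per_group Minimum observed samples per group for a CpG to be
#'   testable (default 2).
#' @return A tibble with `effect`, `p_value`, `testable`, and the per-group
#'   mean fitted logit levels.
#' @export
per_cpg_test <- function(logit_levels, groups, observed = NULL,
                         min_per_group = 2L) {
  logit_levels <- as.matrix(logit_levels)
  L <- nrow(logit_levels)
  n <- ncol(logit_levels)
  if (length(groups) != n || !all(groups %in% c("case", "control")))
    stop_validation("`groups` must label each column 'case' or 'control'")
  if (is.null(observed)) observed <- matrix(TRUE, L, n)
  is_case <- groups == "case"

  one_cpg <- function(l) {
    ok <- observed[l, ]
    n1 <- sum(ok & is_case)
    n0 <- sum(ok & !is_case)
    if (n1 < min_per_group || n0 < min_per_group)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    x1 <- logit_levels[l, ok & is_case]
    x0 <- logit_levels[l, ok & !is_case]
    nn <- n1 + n0
    diff_hat <- mean(x1) - mean(x0)
    # pooled two-sample t with the g-prior shrinkage on the reported effect
    ss <- sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)
    df <- nn - 2
    se <- sqrt(ss / df * (1 / n1 + 1 / n0))
    tstat <- if (se > 0) diff_hat / se else sign(diff_hat) * Inf
    p <- 2 * pt(-abs(tstat), df)
    g <- nn
    c(mean(x1), mean(x0), (g / (1 + g)) * diff_hat, p, 1)
  }
  res <- t(vapply(seq_len(L), one_cpg, numeric(5)))
  tibble::tibble(
    mean_case = res[, 1], mean_control = res[, 2],
    effect = res[, 3], p_value = res[, 4], testable = res[, 5] == 1
  )
}

#' Benjamini-Hochberg adjustment and differential calls
#'
#' Step-up FDR adjustment of the p-values (Benjamini-Yekutieli available via
#' `method`), with calls at `q <= alpha`. `NA` p-values (untestable CpGs)
#' are excluded from the family and returned as `NA` q with call `"NDMC"`.
#'
#' @param p_vector Numeric p-values in \[0, 1\] (may contain `NA`).
#' @param effect Optional effects used to direct the calls (case minus
#'   control): positive significant effects are `"hyper"`, negative
#'   `"hypo"`.
#' @param alpha FDR threshold (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return A tibble with `q_value` and `call`.
#' @export
fdr_adjust <- function(p_vector, effect = NULL, alpha = 0.05,
                       method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_vector) == 0)
    return(tibble::tibble(q_value = numeric(0), call = character(0)))
  ok <- !is.na(p_vector)
  if (any(p_vector[ok] < 0 | p_vector[ok] > 1))
    stop_validation("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_vector))
  q[ok] <- p.adjust(p_vector[ok], method = method)
  call <- rep("NDMC", length(p_vector))
  if (!is.null(effect)) {
    sig <- ok & !is.na(q) & q <= alpha
    call[sig & effect > 0] <- "hyper"
    call[sig & effect < 0] <- "hypo"
  } else {
    call[ok & q <= alpha] <- "DMC"
  }
  tibble::tibble(q_value = q, call = call)
}

#' Call differentially methylated cytosines from a smoothed profile
#'
#' The full calling stage: logit-transform the fitted levels, test each CpG
#' with the conjugate two-group linear model, adjust by Benjamini-Hochberg,
#' and direct the calls (hyper = case above control).
#'
#' @param profile A `smoothed_profile` from [smooth_panel()].
#' @param alpha FDR threshold (default 0.05).
#' @param method FDR variant, `"BH"` or `"BY"`.
#' @param min_per_group Minimum observed samples per group per CpG.
#' @return A `dmc_table` tibble: `chrom`, `pos`, per-group means (logit
#'   scale), `effect`, `p_value`, `q_value`, `call`, `testable`.
#' @export
call_dmcs <- function(profile, alpha = 0.05, method = c("BH", "BY"),
                      min_per_group = 2L) {
  method <- match.arg(method)
  ll <- logit_transform(profile$fitted)
  tests <- per_cpg_test(ll, profile$groups, profile$observed, min_per_group)
  adj <- fdr_adjust(tests$p_value, tests$effect, alpha, method)
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = profile$chrom, pos = profile$positions),
    tests, adj
  )
  class(out) <- c("dmc_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Volcano-plot table
#'
#' Pure projection of a DMC table to the columns a volcano plot needs:
#' effect (logit-scale difference), `-log10(q)`, and the call.
#'
#' @param dmc_table A tibble from [call_dmcs()].
#' @return A tibble with `effect`, `neg_log10_q`, `call`.
#' @export
volcano_table <- function(dmc_table) {
  tibble::tibble(
    effect = dmc_table$effect,
    neg_log10_q = -log10(dmc_table$q_value),
    call = dmc_table$call
  )
}

#' Naive per-CpG t-test comparator on raw methylation ratios
#'
#' The baseline the smoother is compared against in reporting: a two-sample
#' t-test per CpG on raw `y / m` ratios using only observed entries,
#' followed by the same FDR adjustment. CpGs with fewer than
#' `min_per_group` observed samples per group are untestable.
#'
#' @param panel A [methylation_panel()].
#' @inheritParams call_dmcs
#' @return A `dmc_table` tibble in the same layout as [call_dmcs()] (effects
#'   on the raw-ratio scale).
#' @export
naive_ttest_calls <- function(panel, alpha = 0.05, min_per_group = 2L) {
  ratio <- panel$counts / panel$depths
  is_case <- panel$groups == "case"
  L <- length(panel$positions)
  one <- function(l) {
    r <- ratio[l, ]
    ok <- !panel$missing[l, ]
    x1 <- r[ok & is_case]
    x0 <- r[ok & !is_case]
    if (length(x1) < min_per_group || length(x0) < min_per_group ||
        (sd(x1) == 0 && sd(x0) == 0))
      return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    tt <- stats::t.test(x1, x0)
    c(mean(x1), mean(x0), mean(x1) - mean(x0), tt$p.value, 1)
  }
  res <- t(vapply(seq_len(L), one, numeric(5)))
  tests <- tibble::tibble(mean_case = res[, 1], mean_control = res[, 2],
                          effect = res[, 3], p_value = res[, 4],
                          testable = res[, 5] == 1)
  adj <- fdr_adjust(tests$p_value, tests$effect, alpha)
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = panel$chrom, pos = panel$positions), tests, adj
  )
  class(out) <- c("dmc_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Write a DMC table as BED-compatible TSV
#'
#' Columns: `chrom`, 0-based `start`, `end = start + 1`, `name`
#' (`chrom:pos`), `score = -log10(q)` (0 for untestable), `strand = "."`,
#' then `call`, `effect`, `p_value`, `q_value`.
#'
#' @param dmc_table A tibble from [call_dmcs()].
#' @param path Output path.
#' @export
write_dmc_bed <- function(dmc_table, path) {
  bed <- tibble::tibble(
    chrom = dmc_table$chrom,
    start = dmc_table$pos - 1L,
    end = dmc_table$pos,
    name = paste0(dmc_table$chrom, ":", dmc_table$pos),
    score = ifelse(is.na(dmc_table$q_value), 0,
                   round(-log10(pmax(dmc_table$q_value, 1e-300)), 4)),
    strand = ".",
    call = dmc_table$call,
    effect = dmc_table$effect,
    p_value = dmc_table$p_value,
    q_value = dmc_table$q_value
  )
  readr::write_tsv(bed, path)
  invisible(path)
}
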