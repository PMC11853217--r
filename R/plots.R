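#' Volcano plot of differential methylation calls
#'
#' Effect (logit-scale case-minus-control difference) against `-log10(q)`,
#' colored by call: hypo-methylated DMCs to the left, hyper-methylated to
#' the right, with the FDR threshold drawn as a horizontal line.
#'
#' @param dmc_table A tibble from [call_dmcs()].
#' @param alpha FDR threshold line (defaults to the table's own).
#' @return A ggplot object.
#' @export
plot_volcano <- function(dmc_table, alpha = attr(dmc_table, "alpha") %||% 0.05) {
  vt <- volcano_table(dmc_table) |> dplyr::filter(!is.na(.data$effect))
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$effect, y = .data$neg_log10_q,
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(NDMC = "grey60", hyper = "red3",
                                           hypo = "blue3")) +
    ggplot2::labs(x = "effect (logit case - control)",
                  y = expression(-log[10](q)), color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dmc_table <- function(object, ...) plot_volcano(object)

#' Plot a smoothed methylation profile against the raw ratios
#'
#' @param object A `smoothed_profile`.
#' @param samples Sample ids to show (default: first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_profile <- function(object, samples = NULL, ...) {
  samples <- samples %||% head(object$sample_ids, 2)
  df <- as_tibble(object) |> dplyr::filter(.data$sample_id %in% samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$fitted)) +
    ggplot2::geom_line(color = "red3") +
    ggplot2::facet_wrap(~sample_id, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position", y = "fitted methylation level") +
    ggplot2::theme_minimal()
}

#' Posterior membership plot for a fitted mixture AFT model
#'
#' Posterior probability of the shortest-survival component per subject,
#' stratified by event status — the standard diagnostic for whether the
#' aggressive-disease component captures the deceased patients.
#'
#' @param object An `fmaft_fit`.
#' @param data The survival tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmaft_fit <- function(object, data, ...) {
  pm <- posterior_membership(object, data)
  df <- tibble::tibble(
    tau1 = pm$tau[, 1],
    status = factor(ifelse(data$status == 1, "Dead", "Alive"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$tau1)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "P(component 1 | data)") +
    ggplot2::theme_minimal()
}

#' Plot the presmoothed survival-time density
#'
#' @param times Observed times.
#' @param status Event indicators.
#' @return A ggplot object.
#' @export
plot_survival_density <- function(times, status) {
  dens <- presmooth_density(times, status)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$time, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble::tibble(t = times[status == 1]),
                      ggplot2::aes(x = .data$t), inherit.aes = FALSE,
                      alpha = 0.4) +
    ggplot2::labs(x = "survival time", y = "density") +
    ggplot2::theme_minimal()
}
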