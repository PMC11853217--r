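#' Tidy a fitted mixture AFT model
#'
#' One row per (component, term), including the intercepts, in the gene-by-
#' component layout of the coefficient reporting.
#'
#' @param x An `fmaft_fit`.
#' @param ... Unused.
#' @return A tibble with `component`, `term`, `estimate`.
#' @export
tidy.fmaft_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    tibble::tibble(
      component = k,
      term = c("(Intercept)", x$covariates),
      estimate = c(x$intercepts[k], x$beta[, k])
    )
  })
}

#' @rdname tidy.fmaft_fit
#' @return For `glance()`: a one-row tibble with `K`, `logLik`, `df`, `BIC`,
#'   `lambda`, `penalty`, `converged`, `nobs`.
#' @export
glance.fmaft_fit <- function(x, ...) {
  tibble::tibble(K = x$K, logLik = x$loglik, df = x$df, BIC = x$bic,
                 lambda = x$lambda, penalty = x$penalty,
                 converged = x$converged, nobs = x$n)
}

#' @export
tidy.fmaft_selection <- function(x, ...) x$table

#' @export
glance.fmaft_selection <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, best_bic = min(x$table$bic),
                 n_orders = nrow(x$table))
}

#' @export
tidy.cars_scores <- function(x, ...) tibble::as_tibble(unclass(x))

#' Coefficient table in the gene-by-component layout
#'
#' Wide coefficient table (terms as rows, one column per component),
#' matching how mixture AFT effects are conventionally reported.
#'
#' @param fit An `fmaft_fit`.
#' @return A tibble with `term` and one `comp<k>` column per component.
#' @export
coefficient_table <- function(fit) {
  tidy(fit) |>
    dplyr::mutate(component = paste0("comp", .data$component)) |>
    tidyr::pivot_wider(names_from = "component", values_from = "estimate")
}
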