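#' Logit and inverse logit
#'
#' `logit()` maps `(0, 1)` to the real line; `inv_logit()` is its inverse.
#' Used throughout: differential-methylation effects are expressed on the
#' logit scale so they are comparable across methylation states.
#'
#' @param p Numeric in `(0, 1)`.
#' @param x Numeric.
#' @return Numeric vector of the same length.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix with few columns, vectorized over rows
row_log_sum_exp <- function(mat) {
  m <- mat[, 1]
  for (k in seq_len(ncol(mat))[-1]) m <- pmax(m, mat[, k])
  s <- exp(mat[, 1] - m)
  for (k in seq_len(ncol(mat))[-1]) s <- s + exp(mat[, k] - m)
  m + log(s)
}

#' Derive a stream seed from a master seed
#'
#' Per-sample MCMC chains and replicate simulations each get their own seed
#' derived from one master seed by a fixed offset, so runs are reproducible
#' and chains are decoupled. Kept below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param offset Non-negative integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(length(master) == 1, length(offset) == 1, offset >= 0)
  as.integer((as.numeric(master) * 1000003 + 7919 * as.numeric(offset)) %% 2147483629L)
}

# Dirichlet draw via normalized gammas; alpha is a vector.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

# classed conditions: validation errors (bad inputs) vs numerical failures
stop_validation <- function(msg) {
  abort(msg, class = "methaft_validation_error")
}

stop_numerical <- function(msg) {
  abort(msg, class = "methaft_numerical_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
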