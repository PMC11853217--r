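#' Correlation-adjusted regression survival (CARS) screening
#'
#' Screens high-dimensional covariates for relevance to right-censored log
#' survival time. The design is decorrelated by the inverse square root of a
#' shrinkage-regularized correlation matrix (a Mahalanobis-type transform),
#' then each decorrelated covariate's squared correlation with log observed
#' time is computed with inverse-probability-of-censoring (IPC) weights from
#' the Kaplan-Meier estimate of the censoring distribution. Covariates with
#' scores at or above the `quantile` threshold are selected.
#'
#' Under an orthonormal design with no censoring the scores reduce to the
#' squared Pearson correlations with log time.
#'
#' @param data A tibble with `time`, `status` (1 = event), and covariate
#'   columns (everything except `id`, `time`, `status`).
#' @param quantile Selection threshold quantile of the scores (default 0.95,
#'   i.e. the top 5%).
#' @param shrink Shrink the correlation matrix toward the identity with an
#'   analytic intensity before inversion (default `TRUE`). With
#'   `shrink = FALSE` a singular correlation matrix is an error instructing
#'   shrinkage.
#' @return A `cars_scores` tibble: `covariate`, `score`, `selected`, with
#'   the threshold in the `threshold` attribute.
#' @export
cars_screen <- function(data, quantile = 0.95, shrink = TRUE) {
  X <- as.matrix(data[setdiff(names(data), c("id", "time", "status"))])
  n <- nrow(X)
  d <- ncol(X)
  if (d < 2) stop_validation("CARS screening needs at least 2 covariates")
  if (any(data$time <= 0)) stop_validation("times must be positive")
  y <- log(data$time)
  delta <- data$status

  w <- ipc_weights(data$time, delta)

  Xs <- scale(X)
  R <- stats::cor(X)
  if (shrink) {
    lambda <- shrinkage_intensity(Xs, R)
    R <- (1 - lambda) * R
    diag(R) <- 1
  }
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) < 1e-10) {
    if (!shrink)
      stop_numerical("correlation matrix is singular; rerun with shrink = TRUE")
    eig$values <- pmax(eig$values, 1e-10)
  }
  R_inv_sqrt <- eig$vectors %*% diag(1 / sqrt(eig$values)) %*% t(eig$vectors)
  Xd <- Xs %*% R_inv_sqrt

  rho <- apply(Xd, 2, weighted_cor, y = y, w = w)
  scores <- rho^2
  thr <- stats::quantile(scores, quantile, type = 7)
  out <- tibble::tibble(
    covariate = colnames(X) %||% paste0("x", seq_len(d)),
    score = unname(scores),
    selected = scores >= thr
  )
  attr(out, "threshold") <- unname(thr)
  class(out) <- c("cars_scores", class(out))
  out
}

# Kaplan-Meier IPC weights: events weighted by 1 / G(t-), censored subjects 0;
# normalized to sum to 1. With no censoring all events get equal weight.
ipc_weights <- function(time, status) {
  n <- length(time)
  if (all(status == 1)) return(rep(1 / n, n))
  km_cens <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  G <- stats::stepfun(km_cens$time, c(1, km_cens$surv), right = FALSE)
  # G evaluated just before each event time
  g <- vapply(time, function(t) G(t * (1 - 1e-12)), numeric(1))
  g <- pmax(g, 1e-8)
  w <- ifelse(status == 1, 1 / g, 0)
  if (sum(w) == 0) stop_validation("no observed events: cannot weight")
  w / sum(w)
}

weighted_cor <- function(x, y, w) {
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(0)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# Schafer-Strimmer style analytic shrinkage intensity toward the identity
# for a correlation matrix
shrinkage_intensity <- function(Xs, R) {
  n <- nrow(Xs)
  d <- ncol(Xs)
  if (n < 4) return(0.5)
  var_r <- matrix(0, d, d)
  for (j in seq_len(d - 1)) {
    for (k in (j + 1):d) {
      wjk <- Xs[, j] * Xs[, k]
      var_r[j, k] <- n / ((n - 1)^3) * sum((wjk - mean(wjk))^2)
    }
  }
  off <- R[upper.tri(R)]
  denom <- sum(off^2)
  if (denom == 0) return(0)
  min(1, max(0, sum(var_r[upper.tri(var_r)]) / denom))
}

#' Presmoothed density of observed survival times
#'
#' Descriptive diagnostic: a kernel density estimate of the event times with
#' inverse-probability-of-censoring weights, renormalized to integrate to 1
#' on its grid. Used to eyeball multimodality (a hint of latent survival
#' subpopulations) before mixture fitting.
#'
#' @param times Observed times (events and censoring).
#' @param status Event indicators (1 = event).
#' @param n_grid Number of grid points (default 512).
#' @return A tibble with `time` and `density`.
#' @export
presmooth_density <- function(times, status, n_grid = 512L) {
  if (length(times) < 20)
    stop_validation("need at least 20 observations for a density estimate")
  if (all(status == 0)) stop_validation("all observations censored")
  w <- ipc_weights(times, status)
  ev <- status == 1
  dens <- stats::density(times[ev], weights = w[ev] / sum(w[ev]),
                         bw = stats::bw.nrd0(times[ev]),
                         n = n_grid, from = max(min(times[ev]) / 2, 0))
  dx <- diff(dens$x[1:2])
  z <- sum(dens$y) * dx
  tibble::tibble(time = dens$x, density = dens$y / z)
}
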