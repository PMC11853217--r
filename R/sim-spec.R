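#' Simulation specification for a bisulfite count panel
#'
#' Describes the generative model the smoothing stage assumes: a hidden
#' Markov chain over `true_order` methylation states along CpG positions,
#' binomial methylated-read counts given negative-binomial read-depths, a
#' two-group case/control design with a fraction of positions carrying a
#' group shift of the methylation propensity on the logit scale, and
#' independent entry-wise missingness emulating the heavy partial missing
#' data of reduced-representation bisulfite sequencing.
#'
#' @param n_positions Number of CpG positions `L`.
#' @param n_samples_per_group Samples per group (case and control).
#' @param true_order Generating HMM order `K*` (>= 1).
#' @param true_thetas Strictly increasing vector in `(0, 1)` of methylation
#'   propensities, length `true_order`.
#' @param transition_matrix Row-stochastic `K* x K*` matrix; default is a
#'   sticky chain with self-transition probability 0.9.
#' @param initial_probs Simplex vector of length `true_order`; default uniform.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean and
#'   dispersion (`size`); depths are then hard-capped at `depth_cap` by
#'   masking, mirroring the preprocessing filter against PCR-biased CpGs.
#' @param depth_cap Depth cap; entries with larger depth are masked missing.
#' @param missing_rate Independent per-(position, sample) missingness
#'   probability in `[0, 1)`.
#' @param dmc_fraction Fraction of positions with a group-shifted propensity
#'   (injected differentially methylated cytosines).
#' @param effect_size Magnitude of the case-group shift at injected DMCs, on
#'   the logit scale; each injected position receives the shift with a
#'   random sign (hyper- and hypo-methylation both occur).
#' @param seed Integer seed.
#' @return An object of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_positions = 500L,
                           n_samples_per_group = 10L,
                           true_order = 3L,
                           true_thetas = c(0.1, 0.5, 0.9),
                           transition_matrix = NULL,
                           initial_probs = NULL,
                           depth_mean = 30,
                           depth_dispersion = 5,
                           depth_cap = 500L,
                           missing_rate = 0.2,
                           dmc_fraction = 0,
                           effect_size = 1.5,
                           seed = 1L) {
  K <- as.integer(true_order)
  if (is.na(K) || K < 1) stop_validation("`true_order` must be an integer >= 1")
  if (length(true_thetas) != K)
    stop_validation("`true_thetas` must have length `true_order`")
  if (any(true_thetas <= 0) || any(true_thetas >= 1))
    stop_validation("`true_thetas` must lie strictly in (0, 1)")
  if (is.unsorted(true_thetas, strictly = TRUE))
    stop_validation("`true_thetas` must be strictly increasing")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix((1 - 0.9) / max(K - 1, 1), K, K)
    diag(transition_matrix) <- if (K == 1) 1 else 0.9
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(K, K)))
    stop_validation("`transition_matrix` must be K* x K*")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop_validation("`transition_matrix` rows must be probabilities summing to 1")
  if (is.null(initial_probs)) initial_probs <- rep(1 / K, K)
  if (length(initial_probs) != K || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-12)
    stop_validation("`initial_probs` must be a length-K* simplex vector")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_validation("`missing_rate` must be in [0, 1)")
  if (dmc_fraction < 0 || dmc_fraction > 1)
    stop_validation("`dmc_fraction` must be in [0, 1]")
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop_validation("depth distribution parameters must be positive")
  structure(
    list(
      n_positions = as.integer(n_positions),
      n_samples_per_group = as.integer(n_samples_per_group),
      true_order = K,
      true_thetas = as.numeric(true_thetas),
      transition_matrix = transition_matrix,
      initial_probs = as.numeric(initial_probs),
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      depth_cap = as.integer(depth_cap),
      missing_rate = missing_rate,
      dmc_fraction = dmc_fraction,
      effect_size = effect_size,
      seed = as.integer(seed)
    ),
    class = "panel_sim_spec"
  )
}

#' Simulation specification for a right-censored survival dataset
#'
#' Describes a finite mixture of log-normal accelerated failure time
#' regressions: each subject belongs to one latent component, log survival
#' time is linear in the covariates with component-specific sparse
#' coefficients and noise scale, and censoring is exponential with the rate
#' calibrated so the expected censoring fraction matches `censoring_rate`.
#'
#' The defaults reproduce the two-component model fitted to the colorectal
#' TCGA cohort: 252 subjects, 19 gene-promoter methylation covariates with
#' exchangeable correlation 0.3, component intercepts 1.83 and 5.48, unit
#' noise scales, equal mixing weights, about 30% right censoring, and seven
#' nonzero coefficients (component 1: CDH11 -3.60, EPB41L3 2.11,
#' DOCK2 -3.71; component 2: TMEM215 -3.08, PPP1R14A -2.36, GPR158 1.86,
#' NAPSB -2.93), all other coefficients exactly zero.
#'
#' @param n_subjects Number of subjects.
#' @param component_probs Mixing probabilities, a simplex vector.
#' @param intercepts Per-component intercepts on the log-time scale.
#' @param coefficients `d x K` matrix of per-component coefficient vectors
#'   (rows may be named after genes).
#' @param sigmas Per-component noise standard deviations (> 0).
#' @param censoring_rate Target censoring fraction in `(0, 1)`.
#' @param covariate_correlation Exchangeable correlation of the standard
#'   normal covariates, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `survival_sim_spec`.
#' @export
survival_sim_spec <- function(n_subjects = 252L,
                              component_probs = c(0.5, 0.5),
                              intercepts = c(1.83, 5.48),
                              coefficients = default_survival_coefficients(),
                              sigmas = c(1, 1),
                              censoring_rate = 0.3,
                              covariate_correlation = 0.3,
                              seed = 1L) {
  K <- length(component_probs)
  coefficients <- as.matrix(coefficients)
  if (any(component_probs < 0) || abs(sum(component_probs) - 1) > 1e-12)
    stop_validation("`component_probs` must be a simplex vector")
  if (length(intercepts) != K || length(sigmas) != K || ncol(coefficients) != K)
    stop_validation("intercepts, sigmas and coefficient columns must match the number of components")
  if (any(sigmas <= 0)) stop_validation("`sigmas` must be positive")
  if (censoring_rate <= 0 || censoring_rate >= 1)
    stop_validation("`censoring_rate` must be in (0, 1)")
  if (covariate_correlation < 0 || covariate_correlation >= 1)
    stop_validation("`covariate_correlation` must be in [0, 1)")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_covariates = nrow(coefficients),
      component_probs = as.numeric(component_probs),
      intercepts = as.numeric(intercepts),
      coefficients = coefficients,
      sigmas = as.numeric(sigmas),
      censoring_rate = censoring_rate,
      covariate_correlation = covariate_correlation,
      seed = as.integer(seed)
    ),
    class = "survival_sim_spec"
  )
}

#' Default sparse coefficient matrix for the survival generator
#'
#' The 19-gene, two-component coefficient pattern estimated for the
#' colorectal cohort: three genes active in the short-survival component and
#' four in the long-survival component, the rest exactly zero.
#'
#' @return A named 19 x 2 matrix.
#' @export
default_survival_coefficients <- function() {
  genes <- c("CDH11", "FOXF1", "TRIM29", "DCHS2", "TMEM215", "GALNT13",
             "MIR34B", "CHST10", "TFAP2B", "EPB41L3", "DOCK2", "SLC4A11",
             "PPP1R14A", "GPR158", "TFAP2C", "STX18", "RAMP3", "MEF2D",
             "NAPSB")
  beta <- matrix(0, length(genes), 2, dimnames = list(genes, c("comp1", "comp2")))
  beta["CDH11", 1] <- -3.60
  beta["EPB41L3", 1] <- 2.11
  beta["DOCK2", 1] <- -3.71
  beta["TMEM215", 2] <- -3.08
  beta["PPP1R14A", 2] <- -2.36
  beta["GPR158", 2] <- 1.86
  beta["NAPSB", 2] <- -2.93
  beta
}
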