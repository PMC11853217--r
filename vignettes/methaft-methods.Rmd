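---
title: "Methods: penalized trans-dimensional HMM smoothing and sparse mixture AFT survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized trans-dimensional HMM smoothing and sparse mixture AFT survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaft)
```

# Scope

`methaft` implements a two-stage analysis of bisulfite-sequencing
methylation data. Stage one smooths each sample's noisy per-CpG methylation
signal with a hidden Markov model whose number of states is itself unknown,
then calls differentially methylated cytosines (DMCs) between case and
control groups and aggregates promoter calls into differentially methylated
genes (DMGs). Stage two asks whether gene-level methylation predicts
patient survival, allowing for latent patient subpopulations: covariates
are screened by censoring-aware correlation-adjusted scores and a sparse
finite mixture of accelerated failure time (AFT) regressions is fitted by
penalized EM, with the number of components chosen by BIC.

Everything is driven by a synthetic-data generator that reproduces the
statistical structure both stages assume, so the full pipeline is testable
on a desk with no downloads.

# Stage one: the methylation HMM

## Model

For one sample, let `(y_l, m_l)` be the methylated read count and
read-depth at CpG `l = 1..L`. A hidden state `S_l` in `{1..K}` carries a
methylation propensity `theta_k` in `(0, 1)`; given the state,
`y_l ~ Binomial(m_l, theta_{S_l})`. The joint likelihood of counts and a
state path is the product of binomial emissions and the initial/transition
probabilities `p_{k'k}` of the chain. Priors: each `theta_k` is
`Beta(alpha, beta)` (flat by default), each transition row is
`Dirichlet(gamma)` (flat by default), and the order `K` is uniform on
`1..K_max` (default `K_max = 10`). The hyperparameters are fixed rather
than sampled, which keeps runs deterministic given a seed.

Missing entries — the dominant practical nuisance in reduced-representation
bisulfite data, where most positions are observed in only a subset of
samples — contribute an emission factor of 1 and are never discarded. The
fitted value at a missing position is the model-based imputation implied by
the chain. Entries with depth above 500 are masked at load time: extreme
depths are a signature of PCR amplification bias, and masking the entry
(rather than dropping the whole position) preserves the other samples'
reads there.

## Sampler

Each iteration performs:

1. **Gibbs sweep.** `theta_k` from its conjugate Beta full conditional
   (states with no observed site draw from the prior), transition rows
   from their Dirichlet full conditionals, and the state path by
   forward-filtering backward-sampling (FFBS; the `O(L K^2)` recursions
   are compiled code). Propensities are re-sorted ascending with states
   relabelled — the label-switching canon that makes posterior means of
   `theta_{S_l}` well defined.

2. **Split–merge move on `K`.** A reversible-jump proposal: a split picks a
   state uniformly, perturbs its propensity to `theta_j - u, theta_j + u`
   with `u ~ Uniform(0, g_min / 3)` (`g_min` = smallest gap between
   adjacent propensities, including the distance of `theta_j` to 0 and 1),
   and reassigns its sites by fair coin; a merge collapses the adjacent
   pair with the smallest gap to its midpoint. The `u < g_min / 3` cap
   guarantees the freshly split pair *is* the smallest-gap pair, so the
   reverse of every split is the deterministic merge — the proposal ratio
   is exact with no Jacobian. The move targets the posterior with the
   transition matrix integrated out analytically (Dirichlet–multinomial),
   and the matrix is redrawn from its full conditional after an accepted
   move (a partially collapsed scheme). Merges at `K = 1` and splits at
   `K = K_max` have proposal probability 0.

3. **Penalties.** Two penalties regularize the order, implemented as
   configurable rules because only their qualitative behaviour is fixed by
   the method's design:

   * *Collapse (against overfitting):* adjacent propensities closer than
     `collapse_tol` (`delta`, default 0.02 on the theta scale) are
     deterministically merged. The default is half a typical depth-30
     binomial standard error — states closer than this are statistically
     indistinguishable at realistic depths.
   * *Underfit up-weight:* when the within-state binomial deviance exceeds
     the 95th percentile of its parametric-bootstrap null (counts
     re-simulated from the fitted binomials), the split-proposal
     probability is multiplied by `underfit_penalty_weight` (default 2).
     The bootstrap threshold is re-evaluated every
     `penalty_check_interval` iterations (default 20) and cached in
     between; re-simulating every iteration would dominate runtime while
     changing the trigger rarely. The up-weight makes the chain *look
     for* a missing state sooner; the acceptance ratio still uses the
     modified proposal probabilities, so the approximation is confined to
     the cached trigger.

The fitted methylation level at position `l` is the average of
`theta_{S_l}` over retained draws (default 5000 iterations, 2000 burn-in,
thin 5; the tests and examples use shorter desk-scale chains stated with
each use). Averages of Beta-supported draws lie strictly inside `(0, 1)`,
which the downstream logit transform relies on.

Each sample is smoothed by its own independent chain, with per-sample seeds
derived from one master seed by fixed offsets. Per-sample fitting matches
the stage-two interface (per position *and* individual fitted values) and
makes chains embarrassingly parallel.

## Differential calling

Fitted levels are logit-transformed and each CpG is tested with a two-group
conjugate normal linear model under a Zellner g-prior (`g` = number of
samples used at that CpG) with the reference variance prior. The reported
effect is the posterior-mean case-minus-control difference (the
least-squares difference shrunk by `g / (1 + g)`). Because the posterior
t-statistic is a strictly monotone transform of the classical two-sample t
statistic, the p-value is evaluated from that statistic's exact null
distribution: the test is exactly calibrated under the null while the
reported effect remains the posterior mean. Only samples with observed
reads at the CpG enter its test; CpGs with fewer than two observed samples
per group are flagged untestable and excluded from the multiple-testing
family (assigning them p = 1 would deflate everyone else's q-values).
Benjamini–Hochberg adjustment (Benjamini–Yekutieli available) and an FDR
threshold of 0.05 direct the calls: hyper-methylated when the case group is
above control, hypo-methylated below.

One consequence worth knowing: smoothing pools information along the
chromosome *within each sample*, so when a large fraction of positions
carries a group shift, some signal leaks into neighbouring null positions
of the case samples. Null calibration (verified on panels with no injected
signal) is unaffected, but realized false-discovery proportions on panels
with very dense signal can exceed the nominal level. This is a property of
any smoothing-based caller, and the reason the calibration tests use
signal-free panels.

## Annotation and gene aggregation

Each CpG receives exactly one genomic context by the precedence
promoter > island > shore > shelf > exon > intron > intergenic (interval
overlap via `GenomicRanges`; coordinates are 0-based half-open internally,
1-based in TSV interfaces). A gene is a DMG when at least
`min_promoter_dmcs` (default 1 — the minimal reading of "genes with
differentially methylated promoters") of its promoter CpGs is significant;
the gene's direction is the majority direction, ties reported as mixed.
Genes with exons on both strands or on multiple reference sequences are
dropped at load. The agreement and overlap reporting operations work on
integer 2 x 2 counts and recompute all percentages from those counts, so
printed summaries can always be re-derived exactly.

# Stage two: sparse mixture AFT survival

## Screening

With thousands of candidate genes and a few hundred patients, covariates
are first screened by correlation-adjusted regression survival (CARS)
scores: the design is decorrelated by the inverse square root of a
shrinkage-regularized correlation matrix (Schäfer–Strimmer-style analytic
intensity toward the identity; with `shrink = FALSE` a singular matrix is
an error that names the remedy), and each decorrelated covariate's squared
correlation with log observed time is computed with inverse-probability-of-
censoring weights from the Kaplan–Meier estimate of the censoring
distribution. Covariates above the 95th percentile of the scores are kept.
Under an orthonormal design with no censoring the scores reduce to squared
Pearson correlations — a useful sanity anchor that the tests assert.

## Model and estimation

Each subject belongs latently to one of `K` components; within component
`k`, log survival time is `intercept_k + x beta_k + sigma_k * eps` with
standard normal `eps` (a log-normal AFT regression). Right-censored
subjects contribute the normal survival function instead of the density.
All likelihoods are evaluated on the log-time scale; the `1/t`
change-of-variable Jacobian is constant in the parameters and dropped, so
BIC comparisons across `K` remain valid.

The penalized maximum likelihood estimator maximizes
`loglik - n * sum_k pi_k * sum_j p_lambda(|beta_kj|)` — note the mixing
weights inside the penalty, so small components are penalized
proportionally less in absolute terms. The EM:

* **E-step:** posterior memberships `tau_ik`, and for censored subjects the
  truncated-normal conditional mean and variance of the latent log-time
  within each component.
* **M-step:** per component, a penalized weighted least squares problem
  solved by coordinate descent in covariance form (the weighted Gram
  matrix is formed once; concave penalties — SCAD `a = 3.7`, MCP
  `gamma = 3` — are handled by local linear approximation, re-linearized a
  few times). The scale update is closed-form and floored at
  `sigma_floor_frac` (default 0.05) times the marginal log-time standard
  deviation — a Hathaway-type constraint that keeps the mixture likelihood
  bounded; without it, components collapse onto a handful of subjects with
  vanishing variance and the BIC comparison across orders becomes
  meaningless. The mixing-weight update accounts for the `pi_k` factor in
  the penalty by a one-dimensional root-finding step, preserving exact
  EM ascent of the penalized objective (asserted per iteration in tests,
  with 1e-8 relative slack for floating point).

The default penalty is the adaptive lasso, with weights from an
unpenalized weighted-least-squares pilot fit per component (normalized so
the lambda scale is comparable to the plain lasso); lasso, SCAD and MCP are
available. Coefficients below `zero_tol = 1e-5` after convergence are set
exactly to zero (the coordinate updates already produce exact zeros).
Lambda is chosen on a grid (default `exp(seq(log(0.01), log(2), length.out
= 8))`) by the BIC of the full fit; one common lambda is used across
components rather than a per-component grid, which would be combinatorial —
the per-component lambda slot is retained in the fit object should
component-wise selection be added.

Initialization is multi-start: one hard k-means start on
`(scaled log time, status)` plus random-posterior starts (5 total), each
run for 15 short EM iterations, the best penalized objective continued to
convergence (tolerance 1e-6 on the relative change). A component whose
membership column has maximum below `comp_floor = 1e-3` or effective size
below 3 is declared empty and triggers a counted restart. Components are
canonicalized by ascending intercept, so component 1 is always the
shortest-survival (most aggressive) subpopulation.

`select_order()` fits `K = 1..7` (each with its own multi-start and lambda
search) and returns the order with the lowest
`BIC = -2 loglik + df log n`, where `df` counts nonzero coefficients plus
`K` intercepts, `K` scales, and `K - 1` free mixing weights.

Intercepts are kept outside the penalty (per-component unpenalized
location), matching how the coefficient tables report an explicit intercept
row per component.

# The synthetic-data generator

The generator is the package's definition of the study conditions, not a
tuning knob.

* **Count panels:** a hidden path from the specified Markov chain
  (default: sticky, self-transition 0.9); negative-binomial depths
  (default mean 30, dispersion 5) hard-capped at 500 by masking;
  binomial counts given depth and state propensity; independent
  per-entry Bernoulli missingness (default rate 0.2 — with 20 samples
  this reproduces the observed pattern that only a few percent of
  positions are complete in every sample). A chosen fraction of positions
  carries a case-group shift of the propensity on the logit scale —
  comparable effect sizes across states — with a random sign per position,
  since both hyper- and hypo-methylation occur in the data being
  emulated; the truth record stores the signed direction. The missingness
  mechanism in the real data is uncharacterized (coverage-driven
  mechanisms are plausible); independent masking is the simplest
  emulation, and the provenance of that choice is recorded here rather
  than guessed at in code.
* **Survival data:** exchangeable-correlation standard normal covariates
  (mean-centered), a categorical latent component, log-normal AFT times,
  and exponential censoring whose rate is solved numerically so the
  expected censoring fraction hits the target. The defaults are the
  fitted two-component colorectal model: n = 252 subjects, 19 named gene
  covariates with correlation 0.3, intercepts 1.83 and 5.48, unit scales,
  seven nonzero coefficients (CDH11 -3.60, EPB41L3 2.11, DOCK2 -3.71 in
  the short-survival component; TMEM215 -3.08, PPP1R14A -2.36,
  GPR158 1.86, NAPSB -2.93 in the long-survival component), and ~30%
  censoring. The mixing weights are not reported for the original fit;
  0.5/0.5 was chosen once as the neutral default.
* **Annotation:** promoter/exon/intron gene blocks with interleaved CpG
  islands, shores and shelves tiling the simulated chromosome — enough
  structure to exercise precedence and gene aggregation. It does not
  emulate realistic CpG spacing, read-level chemistry, or strand effects,
  so passing tests say nothing about those aspects of real data.

What the generator deliberately does *not* reproduce: within-sample
beta-binomial overdispersion beyond the state structure, coverage-driven
(informative) missingness, chromosome-scale spatial heterogeneity, and
covariate distributions of real methylation (real mean-adjusted log
promoter methylation has smaller spread than unit-variance normals).
Results on synthetic panels therefore certify the estimators and their
calibration under the assumed model, not performance on any particular
real cohort.

# Numerical choices and degenerate inputs

* FFBS and the forward likelihood run in log space; a fully missing
  position passes probability through unchanged, and an all-missing sample
  is an explicit error.
* Conjugate Beta draws are clamped to `(1e-12, 1 - 1e-12)`; fitted levels
  are means of interior points, so the logit transform treats a boundary
  value as an upstream bug (error), never clips.
* The split radius `g_min / 3` makes split/merge exactly reversible; a
  merge whose reverse split could not have generated it (pair gap too
  wide) is rejected outright.
* Ties in the merge choice (equal gaps) resolve to the first index —
  deterministic, and its probability is what enters the proposal ratio.
* `update_pi` root-finding brackets are expanded geometrically before
  `uniroot`; equal penalties reduce to the unpenalized closed form.
* Empty survival components restart with a new random posterior (counted
  in `n_restarts`); all-censored inputs are validation errors wherever a
  likelihood or density needs an event.
* Problem sizes in the tests: order-recovery panels use 2000 positions at
  depth 30 with 2000-iteration chains; calibration panels use 20
  replicates of 150 positions, 6 vs 6 samples; power panels 500 positions,
  10 vs 10; survival simulations n = 252 with 10 seeds. These sizes were
  chosen once as desk-scale study conditions.

# Pipeline and provenance

`run_pipeline()` executes simulate → smooth → call → annotate → survival
into a run directory with a JSON manifest recording the resolved
configuration, master seed, and per-stage content keys and output
checksums. Stages are cached by content key, so re-running with only a
downstream setting changed reuses the expensive smoothing outputs, and any
table in the directory can be regenerated from the manifest alone. The
pipeline is a set of exported R functions (with YAML config round-trip)
rather than a shell tool: the package's users work in R, and the functions
compose with the usual tidyverse idiom. Validation failures and numerical
failures raise distinct condition classes (`methaft_validation_error`,
`methaft_numerical_error`).

# Known limitations

* The two order penalties implement the stated qualitative behaviour with
  explicit, configurable rules; other reasonable functional forms exist,
  and the cached bootstrap trigger is an approximation (exact only between
  re-evaluations).
* Smoothing-induced signal spillover under very dense differential signal
  (see above).
* One lambda across mixture components; per-component selection is a
  possible refinement.
* The CARS screen uses IPC-weighted correlations; with very heavy
  censoring (few events) the weights become unstable, and the screen
  should be read as a ranking rather than a test.
* Per-sample HMM fits do not share information across samples; a joint
  multi-sample HMM is out of scope.
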