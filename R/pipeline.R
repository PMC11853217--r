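#' Pipeline configuration
#'
#' Resolved, serializable configuration for the end-to-end synthetic
#' replication: simulate counts and survival data, smooth per sample, call
#' DMCs, annotate and aggregate to genes, screen and fit the survival
#' mixture. All module defaults are exposed; `seed` is the master seed from
#' which every stage derives its own stream. The object round-trips through
#' YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Master seed.
#' @param stages Named logical list toggling `simulate`, `smooth`, `dmc`,
#'   `annotate`, `survival`.
#' @param panel Arguments for [panel_sim_spec()].
#' @param annotation Arguments for [simulate_annotation()] (`n_genes`).
#' @param chain Arguments for [mcmc_config()].
#' @param dmc List with `alpha`, `method`, `min_per_group`.
#' @param dmg List with `min_promoter_dmcs`.
#' @param survival_sim Arguments for [survival_sim_spec()] (coefficient
#'   defaults are kept).
#' @param survival_fit List with `K_range`, `penalty`, `cars_quantile`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = list(simulate = TRUE, smooth = TRUE,
                                          dmc = TRUE, annotate = TRUE,
                                          survival = TRUE),
                            panel = list(),
                            annotation = list(n_genes = 25L),
                            chain = list(),
                            dmc = list(alpha = 0.05, method = "BH",
                                       min_per_group = 2L),
                            dmg = list(min_promoter_dmcs = 1L),
                            survival_sim = list(),
                            survival_fit = list(K_range = 1:4,
                                                penalty = "adaptive-lasso",
                                                cars_quantile = 0.95)) {
  structure(list(seed = as.integer(seed), stages = stages, panel = panel,
                 annotation = annotation, chain = chain, dmc = dmc,
                 dmg = dmg, survival_sim = survival_sim,
                 survival_fit = survival_fit),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' A configuration sized so the complete synthetic replication runs in
#' minutes on one CPU: a 300-position, 4-vs-4 panel and a shortened chain.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed,
    panel = list(n_positions = 300L, n_samples_per_group = 4L,
                 dmc_fraction = 0.15, effect_size = 2),
    chain = list(n_iter = 1200L, burn_in = 400L, thin = 4L),
    survival_fit = list(K_range = 1:3, penalty = "adaptive-lasso",
                        cars_quantile = 0.95)
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

# content hash of an R object (stage configs, upstream keys) via md5 of its
# canonical serialization
hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(obj), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

stage_cached <- function(manifest, stage, key, files) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$key, key) &&
    all(file.exists(files))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in order, writing every table to `out_dir`
#' together with a provenance manifest (`manifest.json`: resolved
#' configuration, master seed, per-stage content keys and output checksums).
#' Stages are cached: a stage whose configuration and upstream inputs are
#' unchanged (by content key) is skipped and its outputs reused, so
#' re-running with only a downstream stage toggled does not recompute the
#' expensive smoothing. Runs are deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("`config` must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$config <- unclass(config)
  manifest$seed <- config$seed
  results <- list()

  paths <- list(
    panel = file.path(out_dir, "panel.tsv"),
    truth = file.path(out_dir, "panel_truth.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    survival = file.path(out_dir, "survival.tsv"),
    survival_truth = file.path(out_dir, "survival_truth.tsv"),
    profile = file.path(out_dir, "smoothed_profile.tsv"),
    dmc = file.path(out_dir, "dmc_calls.tsv"),
    ttest = file.path(out_dir, "ttest_calls.tsv"),
    context = file.path(out_dir, "dmc_context.tsv"),
    dmg = file.path(out_dir, "dmg_calls.tsv"),
    agreement = file.path(out_dir, "agreement.csv"),
    venn = file.path(out_dir, "venn.json"),
    screening = file.path(out_dir, "cars_screening.csv"),
    selection = file.path(out_dir, "model_selection.csv"),
    coefficients = file.path(out_dir, "coefficients.csv"),
    membership = file.path(out_dir, "membership.tsv")
  )

  # ---- simulate ----
  key_sim <- hash_obj(list(config$panel, config$annotation,
                           config$survival_sim, config$seed))
  if (isTRUE(config$stages$simulate)) {
    sim_files <- unlist(paths[c("panel", "truth", "annotation", "survival",
                                "survival_truth")])
    if (!stage_cached(manifest, "simulate", key_sim, sim_files)) {
      pspec <- do.call(panel_sim_spec,
                       modifyList(list(seed = derive_seed(config$seed, 1)),
                                  config$panel))
      sim <- simulate_panel(pspec)
      write_panel(sim$panel, paths$panel)
      readr::write_tsv(sim$truth, paths$truth)
      ann <- simulate_annotation(sim$panel$positions,
                                 n_genes = config$annotation$n_genes %||% 25L,
                                 seed = derive_seed(config$seed, 2))
      readr::write_tsv(ann, paths$annotation)
      sspec <- do.call(survival_sim_spec,
                       modifyList(list(seed = derive_seed(config$seed, 3)),
                                  config$survival_sim))
      surv <- simulate_survival(sspec)
      write_survival(surv$data, paths$survival)
      readr::write_tsv(surv$truth, paths$survival_truth)
      manifest$stages$simulate <- list(key = key_sim,
                                       outputs = as.list(tools::md5sum(sim_files)))
    }
  }

  # ---- smooth ----
  key_smooth <- hash_obj(list(key_sim, config$chain))
  if (isTRUE(config$stages$smooth)) {
    if (!stage_cached(manifest, "smooth", key_smooth, paths$profile)) {
      panel <- read_panel(paths$panel)
      chain <- do.call(mcmc_config,
                       modifyList(list(seed = derive_seed(config$seed, 4)),
                                  config$chain))
      profile <- smooth_panel(panel, chain)
      write_profile(profile, paths$profile)
      results$profile <- profile
      manifest$stages$smooth <- list(key = key_smooth,
                                     outputs = as.list(tools::md5sum(paths$profile)))
    }
  }

  # ---- dmc ----
  key_dmc <- hash_obj(list(key_smooth, config$dmc))
  if (isTRUE(config$stages$dmc)) {
    dmc_files <- unlist(paths[c("dmc", "ttest")])
    if (!stage_cached(manifest, "dmc", key_dmc, dmc_files)) {
      panel <- read_panel(paths$panel)
      profile <- results$profile %||% read_profile_with_panel(paths$profile, panel)
      dmc_tab <- call_dmcs(profile, alpha = config$dmc$alpha,
                           method = config$dmc$method,
                           min_per_group = config$dmc$min_per_group)
      readr::write_tsv(dmc_tab, paths$dmc)
      tt <- naive_ttest_calls(panel, alpha = config$dmc$alpha,
                              min_per_group = config$dmc$min_per_group)
      readr::write_tsv(tt, paths$ttest)
      results$dmc <- dmc_tab
      results$ttest <- tt
      manifest$stages$dmc <- list(key = key_dmc,
                                  outputs = as.list(tools::md5sum(dmc_files)))
    }
  }

  # ---- annotate ----
  key_ann <- hash_obj(list(key_dmc, config$dmg))
  if (isTRUE(config$stages$annotate)) {
    ann_files <- unlist(paths[c("context", "dmg", "agreement", "venn")])
    if (!stage_cached(manifest, "annotate", key_ann, ann_files)) {
      dmc_tab <- results$dmc %||% readr::read_tsv(paths$dmc, show_col_types = FALSE)
      tt <- results$ttest %||% readr::read_tsv(paths$ttest, show_col_types = FALSE)
      ann <- read_annotation(paths$annotation)
      ctx <- assign_context(dmc_tab, ann)
      readr::write_tsv(ctx, paths$context)
      dmg <- call_dmgs(ctx, min_promoter_dmcs = config$dmg$min_promoter_dmcs)
      readr::write_tsv(dmg, paths$dmg)
      agr <- agreement_table(dmc_tab, tt)
      readr::write_csv(agr$percentages, paths$agreement)
      tt_ctx <- assign_context(tt, ann)
      tt_dmg <- call_dmgs(tt_ctx, min_promoter_dmcs = config$dmg$min_promoter_dmcs)
      vc <- venn_counts(list(smoothed = dmg$gene_id, ttest = tt_dmg$gene_id))
      jsonlite::write_json(vc, paths$venn)
      results$dmg <- dmg
      manifest$stages$annotate <- list(key = key_ann,
                                       outputs = as.list(tools::md5sum(ann_files)))
    }
  }

  # ---- survival ----
  key_surv <- hash_obj(list(key_sim, config$survival_fit))
  if (isTRUE(config$stages$survival)) {
    surv_files <- unlist(paths[c("screening", "selection", "coefficients",
                                 "membership")])
    if (!stage_cached(manifest, "survival", key_surv, surv_files)) {
      sdata <- read_survival(paths$survival)
      scr <- cars_screen(sdata, quantile = config$survival_fit$cars_quantile)
      readr::write_csv(tidy(scr), paths$screening)
      keep <- scr$covariate[scr$selected]
      sel_data <- sdata[c("id", "time", "status", keep)]
      sel <- select_order(sel_data,
                          K_range = config$survival_fit$K_range,
                          penalty = config$survival_fit$penalty,
                          seed = derive_seed(config$seed, 5))
      readr::write_csv(sel$table, paths$selection)
      readr::write_csv(coefficient_table(sel$best_fit), paths$coefficients)
      pm <- posterior_membership(sel$best_fit, sel_data)
      memb <- dplyr::bind_cols(
        tibble::tibble(id = sel_data$id, label = pm$labels),
        tibble::as_tibble(pm$tau, .name_repair = ~paste0("tau_", seq_len(ncol(pm$tau))))
      )
      readr::write_tsv(memb, paths$membership)
      results$selection <- sel
      manifest$stages$survival <- list(key = key_surv,
                                       outputs = as.list(tools::md5sum(surv_files)))
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# rebuild a smoothed_profile object from its TSV plus the panel metadata
read_profile_with_panel <- function(path, panel) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  fitted <- as.matrix(tab[panel$sample_ids])
  structure(
    list(chrom = panel$chrom, positions = panel$positions, fitted = fitted,
         groups = panel$groups, sample_ids = panel$sample_ids,
         observed = !panel$missing, order_traces = NULL, acceptance = NULL,
         master_seed = NA),
    class = "smoothed_profile"
  )
}
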