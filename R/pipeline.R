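#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the cohort (a
#' [cohort_config] to simulate, or pre-built volumes), preprocessing
#' parameters, decomposition controls, inference controls and output
#' options. All randomness derives from the single `seed` via
#' [fanout_seed].
#'
#' @param cohort a [cohort_config] (simulated cohort) or a ready-made
#'   `cohort` object.
#' @param highpass_sec high-pass cutoff (seconds); `NULL` skips.
#' @param varnorm variance-normalize voxel series during preprocessing;
#'   off by default because the generator's noise is homoscedastic, which
#'   keeps subject maps on the coupling-amplitude scale.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 skips.
#' @param ica_order fixed decomposition order, or `NULL` for automatic
#'   selection capped at `max_order`.
#' @param max_order cap on the automatic order search.
#' @param order_subsample temporal subsampling target (samples) for the
#'   order-estimation spectrum.
#' @param r_min,p_min component classification thresholds.
#' @param n_perm permutations per inference.
#' @param alpha FWE threshold for analysis masks.
#' @param alpha_report stricter threshold used for the subgroup
#'   "large alteration" query masks.
#' @param tfce a [tfce_params].
#' @param z_thr |Z| threshold defining each network's extent for ranking.
#' @param keep_nuisance retain demographic nuisance covariates in the
#'   covariate stages.
#' @param scenario_convention `"results"` or `"methods"` (see
#'   [scenario_sign_table]).
#' @param subgroup_contrasts run the MS_short vs MS_long contrasts.
#' @param keep_volumes retain the (large) preprocessed volumes in the run
#'   object.
#' @param seed master seed.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            highpass_sec = 150, fwhm_mm = 5, varnorm = FALSE,
                            ica_order = NULL, max_order = 40,
                            order_subsample = 500,
                            r_min = 0.4, p_min = 0.5,
                            n_perm = 5000, alpha = 0.05,
                            alpha_report = 0.01,
                            tfce = tfce_params(), z_thr = 3,
                            keep_nuisance = TRUE,
                            scenario_convention = "results",
                            subgroup_contrasts = TRUE,
                            keep_volumes = FALSE,
                            seed = 1, outdir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> preprocess -> group ICA (automatic order) ->
#' component classification -> dual regression -> group contrasts with
#' TFCE permutation inference -> gFC network ranking -> subgroup
#' contrasts -> masked covariate cascade (T2LL, then MSSS) -> mechanism
#' scenario classification and report. Identical `(config, seed)` yields
#' identical outputs.
#'
#' @param config a [pipeline_config].
#' @return a `pipeline_run` list (see fields in the implementation):
#'   `ica`, `fc_stats`, `gfc_table`, `subgroup_stats`, `cascades`,
#'   `scenario_map`, `report`, plus the cohort design and ground truth.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  if (config$n_perm < 100)
    warning(sprintf("n_perm=%d limits attainable p-values to >= 1/%d",
                    config$n_perm, config$n_perm + 1))

  ## --- cohort -----------------------------------------------------------
  cohort <- config$cohort
  if (inherits(cohort, "cohort_config"))
    cohort <- simulate_cohort(cohort, seed = fanout_seed(seed, 10L))
  stopifnot(inherits(cohort, "cohort"))
  design <- cohort$design

  ## --- preprocessing ----------------------------------------------------
  pre <- lapply(cohort$volumes, preprocess,
                highpass_sec = config$highpass_sec,
                fwhm_mm = config$fwhm_mm, varnorm = config$varnorm)
  if (!config$keep_volumes) cohort$volumes <- NULL

  ## --- group ICA --------------------------------------------------------
  order <- config$ica_order
  if (is.null(order)) {
    X <- do.call(rbind, lapply(pre, vol_matrix))
    take <- unique(round(seq(1, nrow(X),
                             length.out = min(config$order_subsample,
                                              nrow(X), ncol(X) - 1L))))
    order <- max(2L, as.integer(estimate_model_order(X[take, , drop = FALSE],
                                                     config$max_order)))
    rm(X)
  }
  ica <- group_decompose(pre, order = order, seed = fanout_seed(seed, 20L))
  ica <- classify_components(ica, cohort$templates,
                             r_min = config$r_min, p_min = config$p_min)
  rsn_idx <- which(ica$labels != "artifact")
  if (length(rsn_idx) == 0) stop("stage group_ica: no component classified as RSN")

  ## --- dual regression --------------------------------------------------
  sm <- dual_regression(pre, ica, components = rsn_idx)
  if (!config$keep_volumes) rm(pre)
  analysis_mask <- ica$mask
  ms_rows <- which(design$group == "MS")
  ms_design <- design[ms_rows, , drop = FALSE]

  rsn_names <- ica$labels[rsn_idx]
  atlas <- lapply(seq_along(rsn_idx), function(j)
    abs(component_map(ica, rsn_idx[j])) >= config$z_thr)
  names(atlas) <- rsn_names

  ## --- group contrasts with permutation inference -----------------------
  contrasts <- list(`MS>HC` = +1, `MS<HC` = -1)
  fc_stats <- list()
  for (j in seq_along(rsn_idx)) {
    pe_all <- stack_component(sm, j, "pe")
    for (cn in names(contrasts)) {
      spec <- make_group_spec(design, "MS", contrasts[[cn]])
      fc_stats[[paste(rsn_names[j], cn, sep = "|")]] <-
        permutation_fwe(pe_all, spec, params = config$tfce,
                        n_perm = config$n_perm, mask = analysis_mask,
                        seed = fanout_seed(seed, 30L + j),
                        stage = "tstatFC", component = rsn_names[j],
                        contrast_name = cn)
    }
  }
  gfc_table <- rank_networks(fc_stats, atlas, alpha = config$alpha)

  ## --- subgroup contrasts (disease duration) ----------------------------
  subgroup_stats <- list()
  if (config$subgroup_contrasts && all(c("MS_short", "MS_long") %in%
                                       design$subgroup)) {
    sg_contrasts <- list(`MS_short>MS_long` = +1, `MS_short<MS_long` = -1)
    for (j in seq_along(rsn_idx)) {
      pe_ms <- stack_component(sm[ms_rows], j, "pe")
      for (cn in names(sg_contrasts)) {
        spec <- make_group_spec(ms_design, "MS_short", sg_contrasts[[cn]],
                                group_col = "subgroup")
        subgroup_stats[[paste(rsn_names[j], cn, sep = "|")]] <-
          permutation_fwe(pe_ms, spec, params = config$tfce,
                          n_perm = config$n_perm, mask = analysis_mask,
                          seed = fanout_seed(seed, 60L + j),
                          stage = "tstatFC", component = rsn_names[j],
                          contrast_name = cn)
      }
    }
  }

  ## --- covariate cascade and scenario classification --------------------
  cascades <- list()
  scen_maps <- list()
  for (j in seq_along(rsn_idx)) {
    pe_ms <- stack_component(sm[ms_rows], j, "pe")
    z_ms <- stack_component(sm[ms_rows], j, "z")
    for (cn in names(contrasts)) {
      key <- paste(rsn_names[j], cn, sep = "|")
      casc <- run_cascade(fc_stats[[key]], pe_ms, z_ms, analysis_mask,
                          ms_design, alpha = config$alpha,
                          within = atlas[[rsn_names[j]]],
                          n_perm = config$n_perm, params = config$tfce,
                          seed = fanout_seed(seed, 90L + 10L * j +
                                               contrasts[[cn]] + 2L),
                          keep_nuisance = config$keep_nuisance)
      cascades[[key]] <- casc
      sgn <- cascade_sign_maps(casc, contrasts[[cn]])
      scen_maps[[key]] <- classify_scenarios(sgn$fc_dir, sgn$t2ll_sign,
                                             sgn$msss_sign,
                                             convention = config$scenario_convention)
    }
  }
  scenario_map <- merge_scenario_maps(scen_maps, on_conflict = "first")

  query_masks <- NULL
  if (length(subgroup_stats)) {
    query_masks <- lapply(c("MS_short>MS_long", "MS_short<MS_long"),
                          function(cn) {
      keys <- grep(paste0("\\|", cn, "$"), names(subgroup_stats), value = TRUE)
      Reduce(`|`, lapply(subgroup_stats[keys], build_stage_mask,
                         alpha = config$alpha_report))
    })
    names(query_masks) <- c("MS_short>MS_long", "MS_short<MS_long")
  }
  report <- scenario_report(scenario_map, network_masks = atlas,
                            query_masks = query_masks)

  run <- structure(list(design = design, templates = cohort$templates,
                        ground_truth = cohort$ground_truth,
                        scenarios = cohort$scenarios,
                        ica = ica, rsn_idx = rsn_idx, atlas = atlas,
                        subject_maps = if (config$keep_volumes) sm else NULL,
                        fc_stats = fc_stats, gfc_table = gfc_table,
                        subgroup_stats = subgroup_stats,
                        cascades = cascades,
                        scenario_map = scenario_map, report = report,
                        config = config, seed = seed),
                   class = "pipeline_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subjects, %d RSN components, seed %d\n",
              nrow(x$design), length(x$rsn_idx), x$seed))
  cat("scenarios present:", paste(x$report$present, collapse = ", "), "\n")
  invisible(x)
}

#' Write a stat map as NIfTI triplet plus JSON sidecar
#' @param stat a `stat_map`.
#' @param prefix path prefix; writes `<prefix>_{t,tfce,pfwe}.nii.gz` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_stat_map <- function(stat, prefix) {
  RNifti::writeNifti(RNifti::asNifti(stat$t), paste0(prefix, "_t.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(stat$tfce), paste0(prefix, "_tfce.nii.gz"))
  p <- stat$p_fwe; p[is.na(p)] <- 1
  RNifti::writeNifti(RNifti::asNifti(p), paste0(prefix, "_pfwe.nii.gz"))
  jsonlite::write_json(list(stage = stat$stage, component = stat$component,
                            contrast = stat$contrast_name,
                            n_perm = stat$n_perm,
                            exhaustive = stat$exhaustive,
                            seed = stat$seed,
                            params = unclass(stat$params)),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Write pipeline outputs to a run directory
#' @param run a `pipeline_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$gfc_table, file.path(dir, "gfc_ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (key in names(run$fc_stats))
    write_stat_map(run$fc_stats[[key]],
                   file.path(dir, gsub("[|><]", "_", key)))
  write_scenario_map(run$scenario_map, file.path(dir, "scenario_map.nii.gz"))
  pearson <- do.call(rbind, lapply(run$cascades, function(cs) cs$pearson))
  if (!is.null(pearson))
    utils::write.table(pearson, file.path(dir, "pearson.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$report$counts, file.path(dir, "scenario_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$report$overlaps))
    utils::write.table(run$report$overlaps,
                       file.path(dir, "scenario_overlaps.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = run$seed,
                            n_perm = run$config$n_perm,
                            alpha = run$config$alpha,
                            order = run$ica$order,
                            rsn_labels = run$ica$labels,
                            scenarios_present = run$report$present),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
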