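# End-to-end run: simulate (optional) -> growth metrics -> fold changes ->
# normalisation -> ratios -> changed genes -> enrichment -> summaries ->
# correlation, with a checksum manifest of every artifact.

# Build wild-type logistic parameters whose analytic effective growth rate on
# xylulose equals `target_rate`, by solving the saturation-crossing time in
# closed form for the logistic rate constant.
wt_params_for_rate <- function(target_rate, growth, saturation_fraction) {
  max_od <- growth$baseline_od + growth$capacity
  t_sat <- max_od / target_rate
  if (t_sat <= growth$lag) {
    abort("target effective growth rate is too fast for the lag phase.",
          class = "xylevo_parameter_error")
  }
  q <- (saturation_fraction * max_od - growth$baseline_od) / growth$capacity
  k <- log((1 - .lag_fraction) / .lag_fraction)
  rate <- (k + log(q / (1 - q))) / (t_sat - growth$lag)
  growth_sim_params(
    baseline_od = growth$baseline_od, capacity = growth$capacity,
    rate = rate, lag = growth$lag, noise_sd = growth$noise_sd,
    sampling_interval = growth$sampling_interval,
    duration = t_sat + 14 / rate
  )
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "xylevo_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic or user-supplied inputs and writes all
#' artifacts plus a JSON manifest with MD5 checksums to the output directory.
#' With `simulate = TRUE` the growth and expression simulations share one
#' strain panel: the growth curves are parameterised so each strain's
#' analytic effective growth rate equals the rate driving its expression
#' effects, so the correlation stage sees a coherent experiment. Fully
#' deterministic given the configuration seed.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  gcfg <- growth_config(
    smooth_window = an$smooth_window, slope_window = an$slope_window,
    saturation_fraction = an$saturation_fraction
  )
  paths <- character(0)
  emit <- function(x, name, writer = write_tsv_table) {
    p <- file.path(out_dir, name)
    writer(x, p)
    paths <<- c(paths, p)
    p
  }

  # --- inputs -----------------------------------------------------------
  if (config$simulate) {
    xy_log(config, "info", "simulating strain panel (seed %d)", config$seed)
    ep_opts <- config$expression
    eparams <- run_stage("simulate", expression_sim_params(
      n_genes = ep_opts$n_genes, n_strains = ep_opts$n_strains,
      baseline_log_mean = ep_opts$baseline_log_mean,
      baseline_log_sd = ep_opts$baseline_log_sd,
      aa_induction_intercept = ep_opts$aa_induction_intercept,
      aa_induction_slope = ep_opts$aa_induction_slope,
      rp_coupling = ep_opts$rp_coupling,
      evolved_aa_residual = ep_opts$evolved_aa_residual,
      dispersion = ep_opts$dispersion, library_size = ep_opts$library_size,
      n_replicates = ep_opts$n_replicates,
      seed = stage_seed(config$seed, "expression_sim")
    ))
    sim <- run_stage("simulate", simulate_expression(eparams))
    rates <- sim$truth
    wt_list <- lapply(rates$growth_rate_wt, wt_params_for_rate,
                      growth = config$growth,
                      saturation_fraction = an$saturation_fraction)
    panel <- run_stage("simulate", simulate_strain_panel(
      tibble(strain = rates$strain, max_od_fold = 1,
             time_to_max_fold = rates$growth_rate_wt /
               rates$growth_rate_evolved),
      wt_params = wt_list,
      n_replicates = config$growth$n_replicates,
      saturation_fraction = an$saturation_fraction,
      seed = stage_seed(config$seed, "growth_sim")
    ))
    curves <- dplyr::mutate(
      panel$curves,
      well = sprintf("%s_%s_r%d", .data$strain, .data$status,
                     .data$replicate)
    )
    growth_samples <- dplyr::distinct(
      curves, .data$well, .data$strain, .data$status, .data$replicate
    )
    counts <- sim$counts
    design <- sim$design
    gene_sets <- sim$groups[c("aa_module", "rp_module")]
    emit(curves, "plate_od.csv", write_plate_csv)
    emit(growth_samples, "growth_samples.tsv")
    emit(counts, "counts.tsv")
    emit(design, "expr_samples.tsv")
    emit(gene_sets, "gene_sets.gmt", write_gmt)
    emit(sim$truth, "truth.tsv")
  } else {
    xy_log(config, "info", "reading inputs")
    growth_samples <- run_stage("read_inputs",
                                read_tsv_table(config$growth_samples_path))
    curves <- run_stage("read_inputs",
                        read_plate_csv(config$plates_path, growth_samples))
    counts <- run_stage("read_inputs", read_counts(config$counts_path))
    design <- run_stage("read_inputs",
                        read_sample_sheet(config$design_path))
    gene_sets <- run_stage("read_inputs", read_gmt(config$gmt_path))
  }

  # --- growth -----------------------------------------------------------
  xy_log(config, "info", "growth metrics (smooth window %d, saturation %g)",
         an$smooth_window, an$saturation_fraction)
  metrics <- run_stage("growth_metrics", compute_metrics(curves, gcfg))
  folds <- run_stage("fold_change", fold_change(metrics))
  improvement <- run_stage("classification", classify_improvement(folds))
  emit(metrics, "growth_metrics.tsv")
  emit(folds, "growth_folds.tsv")
  emit(improvement, "improvement.tsv")

  # --- expression -------------------------------------------------------
  xy_log(config, "info", "expression pipeline (pseudocount %g)",
         an$pseudocount)
  norm <- run_stage("normalization", normalize_to_million(counts))
  avg <- run_stage("replicate_averaging", average_replicates(norm, design))
  ratios <- run_stage("log_ratios",
                      log_ratio_xyl_glu(avg, pseudocount = an$pseudocount))
  wt_ratios <- dplyr::filter(ratios, .data$status == "wt")
  changed <- run_stage("changed_genes", identify_changed_genes(
    wt_ratios, threshold = an$changed_threshold,
    min_sign_fraction = an$min_sign_fraction
  ))
  enrich <- run_stage("enrichment",
                      enrichment_test(changed, gene_sets, counts$gene))
  summaries <- run_stage("group_summary", group_summary(ratios, gene_sets))
  profile <- run_stage("group_profile", per_gene_group_profile(
    avg, gene_sets[[1]], sugar = "xylulose"
  ))
  emit(norm, "normalized_counts.tsv")
  emit(ratios, "ratios.tsv")
  emit(changed, "changed_genes.tsv")
  emit(enrich, "enrichment.tsv")
  emit(summaries, "group_summary.tsv")
  emit(profile, "group_profile.tsv")

  # --- adaptation -------------------------------------------------------
  xy_log(config, "info", "correlation (%d permutations)", an$permutations)
  changes <- dplyr::bind_rows(lapply(names(gene_sets), function(g) {
    run_stage("expression_change", expression_change(
      avg, gene_sets[[g]], sugar = "xylulose",
      pseudocount = an$pseudocount, group_name = g
    ))
  }))
  records <- run_stage("correlation", strain_change_records(changes, folds))
  correlation <- run_stage("correlation", correlate_change_with_growth(
    records, permutations = an$permutations, seed = config$seed
  ))
  coords <- run_stage("coordinates", group_vs_group_coordinates(
    ratios, gene_sets[[1]], gene_sets[[min(2L, length(gene_sets))]],
    names_ab = names(gene_sets)[c(1L, min(2L, length(gene_sets)))]
  ))
  emit(records, "strain_change_records.tsv")
  emit(tidy(correlation), "correlation.tsv")
  emit(coords, "scatter_coords.tsv")

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  paths <- c(paths, cfg_path)
  manifest <- tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  jsonlite::write_json(
    purrr::map2(manifest$file, manifest$md5, ~ list(file = .x, md5 = .y)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  xy_log(config, "info", "wrote %d artifacts to %s", nrow(manifest), out_dir)
  invisible(manifest)
}
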