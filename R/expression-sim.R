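# Synthetic RNA-seq count matrices with growth-rate-coupled module effects:
# amino-acid biosynthesis induction on xylulose that is anti-correlated with
# growth rate in ancestral strains and (by default) absent after evolution,
# plus growth-rate-coupled ribosomal expression, over negative-binomial noise.

#' Parameters for the expression simulator
#'
#' Defines a full factorial design (`n_strains` x \{wt, evolved\} x
#' \{glucose, xylulose\} x `n_replicates`) of negative-binomial count
#' profiles. Per-gene glucose means are log-normal baselines rescaled so each
#' sample's expected total is `library_size`. On xylulose, a gene's mean is
#' its baseline times `2^effect`, where the effect is:
#'
#' * amino-acid module, wild type: `aa_induction_intercept -
#'   aa_induction_slope * growth_rate` — stronger induction in slower
#'   ancestors (anti-correlation with growth rate);
#' * amino-acid module, evolved: `evolved_aa_residual` (default 0 — the
#'   induction is lost after adaptation);
#' * ribosomal module (either status): `rp_coupling * growth_rate` of that
#'   strain and status;
#' * background genes: 0.
#'
#' Every numeric default is invented for testing purposes — chosen to give a
#' clearly recoverable but noisy signal at plate-experiment scale — and none
#' is a measured value.
#'
#' @param n_genes Number of genes.
#' @param n_strains Number of strains.
#' @param strain_growth_rates Data frame with columns `wt` and `evolved`
#'   giving each strain's effective growth rate on xylulose (OD/h); default is
#'   an invented spread of ancestors (0.04–0.14) whose evolved derivatives
#'   converge toward a common faster rate, so slower ancestors improve more.
#' @param baseline_log_mean,baseline_log_sd Log-normal (natural-log scale)
#'   parameters for per-gene baselines before rescaling to `library_size`.
#' @param aa_induction_intercept,aa_induction_slope Intercept (log2) and slope
#'   (log2 per OD/h) of the wild-type amino-acid-module induction on xylulose.
#' @param rp_coupling Ribosomal-module coupling (log2 per OD/h).
#' @param evolved_aa_residual Residual amino-acid-module effect after
#'   evolution (log2; default 0).
#' @param dispersion Negative-binomial dispersion shared by all genes
#'   (variance `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_size Expected total counts per sample.
#' @param n_replicates Replicates per strain/status/sugar.
#' @param group_assignment Optional named character vector mapping every gene
#'   id to one of `"aa_module"`, `"rp_module"`, `"background"`; by default the
#'   first 3% of genes (at least 10) form the amino-acid module and the next
#'   3% the ribosomal module.
#' @param seed Default RNG seed used by [simulate_expression()] when no seed
#'   is passed there.
#' @return An object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000,
                                  n_strains = 12,
                                  strain_growth_rates = NULL,
                                  baseline_log_mean = 0,
                                  baseline_log_sd = 1,
                                  aa_induction_intercept = 1.0,
                                  aa_induction_slope = 5.0,
                                  rp_coupling = 2.0,
                                  evolved_aa_residual = 0,
                                  dispersion = 0.05,
                                  library_size = 1e6,
                                  n_replicates = 2,
                                  group_assignment = NULL,
                                  seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", lower = 10L)
  n_strains <- check_count(n_strains, "n_strains", lower = 1L)
  check_number(baseline_log_sd, "baseline_log_sd", lower = 0)
  check_number(dispersion, "dispersion", lower = 0)
  check_number(library_size, "library_size", lower = 0,
               allow_equal_lower = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates")

  if (is.null(strain_growth_rates)) {
    wt <- seq(0.04, 0.14, length.out = n_strains)
    strain_growth_rates <- tibble(wt = wt, evolved = 0.10 + 0.5 * wt)
  }
  check_data_frame(strain_growth_rates, "strain_growth_rates",
                   c("wt", "evolved"))
  if (nrow(strain_growth_rates) != n_strains) {
    abort("`strain_growth_rates` must have one row per strain.",
          class = "xylevo_input_error")
  }
  if (any(strain_growth_rates$wt <= 0) ||
      any(strain_growth_rates$evolved <= 0)) {
    abort("growth rates must be positive.", class = "xylevo_parameter_error")
  }

  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(group_assignment)) {
    n_mod <- max(10L, round(0.03 * n_genes))
    group_assignment <- setNames(rep("background", n_genes), genes)
    group_assignment[seq_len(n_mod)] <- "aa_module"
    group_assignment[n_mod + seq_len(n_mod)] <- "rp_module"
  } else {
    unknown <- setdiff(names(group_assignment), genes)
    if (length(unknown) || length(group_assignment) != n_genes) {
      abort("`group_assignment` must name every simulated gene exactly once.",
            class = "xylevo_input_error")
    }
    group_assignment <- group_assignment[genes]
    bad <- setdiff(unique(group_assignment),
                   c("aa_module", "rp_module", "background"))
    if (length(bad)) {
      abort(sprintf("unknown group label(s): %s.", paste(bad, collapse = ", ")),
            class = "xylevo_input_error")
    }
  }

  structure(
    list(n_genes = n_genes, n_strains = n_strains,
         strain_growth_rates = as_tibble(strain_growth_rates),
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         aa_induction_intercept = aa_induction_intercept,
         aa_induction_slope = aa_induction_slope,
         rp_coupling = rp_coupling,
         evolved_aa_residual = evolved_aa_residual,
         dispersion = dispersion, library_size = library_size,
         n_replicates = n_replicates, genes = genes,
         group_assignment = group_assignment, seed = seed),
    class = "expression_sim_params"
  )
}

# log2 xylulose/glucose effect for one gene group in one strain/status
module_effect <- function(params, group, status, growth_rate) {
  switch(group,
    aa_module = if (status == "wt") {
      params$aa_induction_intercept - params$aa_induction_slope * growth_rate
    } else {
      params$evolved_aa_residual
    },
    rp_module = params$rp_coupling * growth_rate,
    background = 0
  )
}

#' Simulate an expression count matrix with known module effects
#'
#' Draws a full factorial count matrix under [expression_sim_params()] and
#' returns it together with its sample design and a record of every injected
#' effect, so recovery tests need no re-derivation. Deterministic given the
#' seed.
#'
#' @param params An [expression_sim_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A list of class `expression_sim` with elements:
#' \describe{
#'   \item{counts}{tibble, `gene` column then one integer column per sample.}
#'   \item{design}{tibble `sample_id`, `strain`, `status`, `sugar`,
#'     `replicate`.}
#'   \item{truth}{tibble per strain: growth rates, growth fold, and the true
#'     log2 xylulose/glucose effects of each module before and after
#'     evolution.}
#'   \item{baseline}{tibble of per-gene expected glucose means and group
#'     membership (the generative mean of every glucose sample).}
#'   \item{groups}{named list of gene ids per module (GMT-ready).}
#'   \item{params}{the input parameters.}
#' }
#' @examples
#' sim <- simulate_expression(expression_sim_params(n_genes = 50,
#'                                                  n_strains = 3), seed = 1)
#' dim(sim$counts)
#' @export
simulate_expression <- function(params, seed = NULL) {
  stopifnot(inherits(params, "expression_sim_params"))
  seed <- seed %||% params$seed

  rates <- params$strain_growth_rates
  strains <- sprintf("strain%02d", seq_len(params$n_strains))
  design <- tidyr::expand_grid(
    strain = strains,
    status = c("wt", "evolved"),
    sugar = c("glucose", "xylulose"),
    replicate = seq_len(params$n_replicates)
  )
  design <- dplyr::mutate(
    design,
    sample_id = sprintf("%s_%s_%s_r%d", .data$strain, .data$status,
                        .data$sugar, .data$replicate),
    .before = 1
  )

  group <- params$group_assignment

  with_seed(seed, {
    baseline <- rlnorm(params$n_genes, params$baseline_log_mean,
                       params$baseline_log_sd)
    baseline <- baseline / sum(baseline) * params$library_size

    counts <- matrix(0L, nrow = params$n_genes, ncol = nrow(design),
                     dimnames = list(params$genes, design$sample_id))
    for (j in seq_len(nrow(design))) {
      s_idx <- match(design$strain[j], strains)
      g <- if (design$status[j] == "wt") rates$wt[s_idx] else
        rates$evolved[s_idx]
      effect <- numeric(params$n_genes)
      if (design$sugar[j] == "xylulose") {
        for (grp in c("aa_module", "rp_module")) {
          effect[group == grp] <-
            module_effect(params, grp, design$status[j], g)
        }
      }
      mu <- baseline * 2^effect
      counts[, j] <- if (params$dispersion > 0) {
        rnbinom(params$n_genes, mu = mu, size = 1 / params$dispersion)
      } else {
        rpois(params$n_genes, lambda = mu)
      }
    }

    truth <- tibble(
      strain = strains,
      growth_rate_wt = rates$wt,
      growth_rate_evolved = rates$evolved,
      growth_fold = rates$evolved / rates$wt,
      aa_effect_wt = params$aa_induction_intercept -
        params$aa_induction_slope * rates$wt,
      aa_effect_evolved = params$evolved_aa_residual,
      rp_effect_wt = params$rp_coupling * rates$wt,
      rp_effect_evolved = params$rp_coupling * rates$evolved
    )

    structure(
      list(
        counts = dplyr::bind_cols(tibble(gene = params$genes),
                                  as_tibble(counts)),
        design = design,
        truth = truth,
        baseline = tibble(gene = params$genes, baseline_mean = baseline,
                          group = unname(group)),
        groups = split(names(group), group),
        params = params
      ),
      class = "expression_sim"
    )
  })
}
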