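# Shared fixture builders. All fixtures are generated in code; the
# independent oracles used against package results live in the test files.

# one curve as the package expects it, with identifying columns
make_curve <- function(time_h, od, strain = "s1", status = "wt",
                       replicate = 1L) {
  tibble::tibble(strain = strain, status = status, replicate = replicate,
                 time_h = time_h, od = od)
}

# independent logistic evaluator (same model family, written from scratch so
# generator bugs cannot cancel): midpoint placed where the logistic term is
# 1% of capacity at t = lag
oracle_logistic <- function(t, baseline, capacity, rate, lag) {
  t_mid <- lag + log(99) / rate
  baseline + capacity / (1 + exp(-rate * (t - t_mid)))
}

# small count matrix with a known design, values chosen by hand
make_tiny_counts <- function() {
  counts <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    s1_wt_glu_r1 = c(10, 20, 30, 40),
    s1_wt_glu_r2 = c(30, 20, 10, 40),
    s1_wt_xyl_r1 = c(40, 20, 30, 10),
    s1_wt_xyl_r2 = c(20, 20, 30, 30)
  )
  design <- tibble::tibble(
    sample_id = names(counts)[-1],
    strain = "s1",
    status = "wt",
    sugar = rep(c("glucose", "xylulose"), each = 2),
    replicate = rep(1:2, times = 2)
  )
  list(counts = counts, design = design)
}

# replicate-averaged matrix built directly (bypassing average_replicates)
# for closed-form ratio tests
make_avg_counts <- function(values_by_condition, genes = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(length(values_by_condition[[1]])))
  counts <- tibble::as_tibble(values_by_condition)
  counts <- dplyr::bind_cols(tibble::tibble(gene = genes), counts)
  parts <- strsplit(names(values_by_condition), "_", fixed = TRUE)
  attr(counts, "design") <- tibble::tibble(
    sample_id = names(values_by_condition),
    strain = vapply(parts, `[[`, character(1), 1),
    status = vapply(parts, `[[`, character(1), 2),
    sugar = vapply(parts, `[[`, character(1), 3)
  )
  counts
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# default small simulated expression panel used by several recovery tests
small_sim <- function(seed = 11, n_genes = 600, n_strains = 12, ...) {
  simulate_expression(
    expression_sim_params(n_genes = n_genes, n_strains = n_strains, ...,
                          seed = seed)
  )
}
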