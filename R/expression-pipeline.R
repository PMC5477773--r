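# Count normalisation, xylulose/glucose log-ratios, changed-gene calling,
# gene-set projection and enrichment.

sample_cols <- function(counts) setdiff(names(counts), "gene")

validate_counts <- function(counts, name = "counts") {
  check_data_frame(counts, name, "gene")
  if (anyDuplicated(counts$gene)) {
    abort(sprintf("`%s` has duplicated gene ids.", name),
          class = "xylevo_input_error")
  }
  cols <- sample_cols(counts)
  if (!length(cols)) {
    abort(sprintf("`%s` has no sample columns.", name),
          class = "xylevo_input_error")
  }
  if (anyDuplicated(cols)) {
    abort(sprintf("`%s` has duplicated sample ids.", name),
          class = "xylevo_input_error")
  }
  neg <- vapply(counts[cols], function(x) any(x < 0), logical(1))
  if (any(neg)) {
    abort(sprintf("negative counts in sample(s): %s.",
                  paste(cols[neg], collapse = ", ")),
          class = "xylevo_input_error")
  }
  invisible(counts)
}

validate_design <- function(design, name = "design") {
  check_data_frame(design, name,
                   c("sample_id", "strain", "status", "sugar", "replicate"))
  bad_status <- setdiff(unique(design$status), c("wt", "evolved"))
  bad_sugar <- setdiff(unique(design$sugar), c("glucose", "xylulose"))
  if (length(bad_status) || length(bad_sugar)) {
    abort("`status` must be wt/evolved and `sugar` glucose/xylulose.",
          class = "xylevo_input_error")
  }
  key <- paste(design$strain, design$status, design$sugar, design$replicate)
  if (anyDuplicated(key)) {
    abort("(strain, status, sugar, replicate) tuples must be unique.",
          class = "xylevo_input_error")
  }
  invisible(design)
}

#' Normalise each sample to one million counts
#'
#' Scales every sample column so its total equals `target` (counts per
#' million), making expression comparable across sequencing depths. The
#' operation is idempotent.
#'
#' @param counts Tibble with a `gene` column and one numeric column per
#'   sample.
#' @param target Per-sample total after scaling (default 1e6).
#' @return The counts tibble with scaled sample columns.
#' @export
normalize_to_million <- function(counts, target = 1e6) {
  validate_counts(counts)
  check_number(target, "target", lower = 0, allow_equal_lower = FALSE)
  counts <- as_tibble(counts)
  cols <- sample_cols(counts)
  totals <- vapply(counts[cols], sum, numeric(1))
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s.",
                  paste(cols[totals == 0], collapse = ", ")),
          class = "xylevo_normalization_error")
  }
  counts[cols] <- purrr::map2(counts[cols], totals, ~ .x / .y * target)
  counts
}

#' Average replicate samples per condition
#'
#' Collapses replicates to one column per (strain, status, sugar) condition
#' by arithmetic mean. Apply after [normalize_to_million()], so replicate
#' depth differences do not leak into the averages.
#'
#' @param counts Normalised counts tibble.
#' @param design Sample design tibble (`sample_id`, `strain`, `status`,
#'   `sugar`, `replicate`) covering all sample columns.
#' @return A counts tibble with one column per condition, named
#'   `strain_status_sugar`; the collapsed design (without the replicate
#'   dimension) is attached as attribute `"design"`.
#' @export
average_replicates <- function(counts, design) {
  validate_counts(counts)
  validate_design(design)
  counts <- as_tibble(counts)
  cols <- sample_cols(counts)
  missing <- setdiff(cols, design$sample_id)
  if (length(missing)) {
    abort(sprintf("design lacks sample(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "xylevo_input_error")
  }
  design <- dplyr::filter(design, .data$sample_id %in% cols)
  if (nrow(design) == 0L) {
    abort("no design rows match the count columns.",
          class = "xylevo_input_error")
  }
  conds <- design |>
    dplyr::distinct(.data$strain, .data$status, .data$sugar) |>
    dplyr::mutate(sample_id = paste(.data$strain, .data$status, .data$sugar,
                                    sep = "_"))
  out <- tibble(gene = counts$gene)
  for (i in seq_len(nrow(conds))) {
    members <- design$sample_id[design$strain == conds$strain[i] &
                                  design$status == conds$status[i] &
                                  design$sugar == conds$sugar[i]]
    out[[conds$sample_id[i]]] <- rowMeans(counts[, members, drop = FALSE])
  }
  attr(out, "design") <- conds[, c("sample_id", "strain", "status", "sugar")]
  out
}

avg_design <- function(counts, design = NULL) {
  design <- design %||% attr(counts, "design")
  if (is.null(design)) {
    abort(paste("no design available; pass `design` or use the output of",
                "average_replicates()."),
          class = "xylevo_input_error")
  }
  check_data_frame(design, "design", c("sample_id", "strain", "status",
                                       "sugar"))
  design
}

#' Per-gene log2 xylulose/glucose expression ratios
#'
#' For each strain and status, computes `log2((xylulose + pseudocount) /
#' (glucose + pseudocount))` per gene from a replicate-averaged matrix. The
#' pseudocount (in normalised-count units) guards against zeros.
#'
#' @param counts Replicate-averaged counts from [average_replicates()].
#' @param design Collapsed design; defaults to the attribute attached by
#'   [average_replicates()].
#' @param strains,statuses Optional subsets; default all present.
#' @param pseudocount Added to both conditions before the ratio (default 1).
#' @return A long tibble: `gene`, `strain`, `status`, `log2_ratio`.
#' @export
log_ratio_xyl_glu <- function(counts, design = NULL, strains = NULL,
                              statuses = NULL, pseudocount = 1) {
  validate_counts(counts)
  design <- avg_design(counts, design)
  check_number(pseudocount, "pseudocount", lower = 0)
  strains <- strains %||% unique(design$strain)
  statuses <- statuses %||% unique(design$status)
  out <- list()
  for (s in strains) {
    for (st in statuses) {
      xyl <- design$sample_id[design$strain == s & design$status == st &
                                design$sugar == "xylulose"]
      glu <- design$sample_id[design$strain == s & design$status == st &
                                design$sugar == "glucose"]
      if (length(xyl) != 1L || length(glu) != 1L ||
          !all(c(xyl, glu) %in% names(counts))) {
        abort(sprintf("strain %s (%s) lacks a xylulose or glucose condition.",
                      s, st),
              class = "xylevo_input_error")
      }
      out[[paste(s, st)]] <- tibble(
        gene = counts$gene, strain = s, status = st,
        log2_ratio = log2((counts[[xyl]] + pseudocount) /
                            (counts[[glu]] + pseudocount))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Identify genes with consistent expression change
#'
#' A gene is called changed when the absolute median of its log2 ratios
#' across strains reaches `threshold` *and* the median's sign is shared by at
#' least `min_sign_fraction` of the strains. This robust rule is used instead
#' of a per-gene variance model, which two replicates cannot support.
#'
#' @param ratios Long ratio tibble from [log_ratio_xyl_glu()] (filter to one
#'   status before calling if statuses should not be pooled).
#' @param threshold Minimum |median log2 ratio| (default 1 = two-fold).
#' @param min_sign_fraction Minimum fraction of strains sharing the median's
#'   sign (default 2/3).
#' @return A tibble of changed genes: `gene`, `direction` (`"up"`/`"down"`),
#'   `median_ratio`, `sign_fraction`.
#' @export
identify_changed_genes <- function(ratios, threshold = 1,
                                   min_sign_fraction = 2 / 3) {
  check_data_frame(ratios, "ratios", c("gene", "strain", "log2_ratio"))
  check_number(threshold, "threshold", lower = 0)
  check_number(min_sign_fraction, "min_sign_fraction", lower = 0, upper = 1)
  as_tibble(ratios) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      median_ratio = median(.data$log2_ratio),
      sign_fraction = if (median(.data$log2_ratio) == 0) 0 else {
        mean(sign(.data$log2_ratio) == sign(median(.data$log2_ratio)))
      },
      .groups = "drop"
    ) |>
    dplyr::filter(abs(.data$median_ratio) >= threshold,
                  .data$sign_fraction >= min_sign_fraction) |>
    dplyr::mutate(direction = ifelse(.data$median_ratio > 0, "up", "down"),
                  .after = "gene")
}

#' Hypergeometric enrichment of changed genes in gene sets
#'
#' For each gene set, tests whether the changed genes overlap it more than
#' expected by chance under sampling without replacement from the universe:
#' the p-value is the upper-tail hypergeometric probability of at least the
#' observed overlap. Benjamini–Hochberg adjustment is applied across the
#' collection.
#'
#' @param changed Character vector of changed genes (or a tibble with a
#'   `gene` column, e.g. from [identify_changed_genes()]).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of all genes considered (e.g. all genes
#'   in the count matrix). Set members outside the universe are dropped.
#' @return A tibble: `set`, `set_size` (within universe), `overlap`,
#'   `n_changed`, `universe_size`, `p`, `q`.
#' @export
enrichment_test <- function(changed, gene_sets, universe) {
  if (is.data.frame(changed)) changed <- changed$gene
  if (!length(universe)) {
    abort("`universe` must be non-empty.", class = "xylevo_input_error")
  }
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a named list.", class = "xylevo_input_error")
  }
  universe <- unique(universe)
  outside <- setdiff(changed, universe)
  if (length(outside)) {
    warn(sprintf("%d changed gene(s) outside the universe were dropped.",
                 length(outside)))
  }
  changed <- intersect(changed, universe)
  n_univ <- length(universe)
  n_changed <- length(changed)
  res <- purrr::imap(gene_sets, function(members, set_name) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(changed, members))
    m <- length(members)
    tibble(
      set = set_name, set_size = m, overlap = k, n_changed = n_changed,
      universe_size = n_univ,
      p = phyper(k - 1, m, n_univ - m, n_changed, lower.tail = FALSE)
    )
  })
  res <- dplyr::bind_rows(res)
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Group-level summary of expression ratios
#'
#' Projects per-gene log2 xylulose/glucose ratios onto gene sets: for each
#' set and status, the set's genes are averaged per strain and the resulting
#' per-strain means are then averaged across strains, with the standard error
#' taken across strains (SD / sqrt(n_strains)). Gene-first-then-strain order
#' follows the averaging convention for grouped expression summaries.
#'
#' @param ratios Long ratio tibble (`gene`, `strain`, `status`,
#'   `log2_ratio`).
#' @param gene_sets Named list of gene-id vectors. Sets with no gene present
#'   in `ratios` are skipped with a warning; absent members are dropped.
#' @return A tibble: `set`, `status`, `mean`, `se`, `n_genes`, `n_strains`,
#'   `single_strain` (flag: SE reported as 0 because only one strain was
#'   available).
#' @export
group_summary <- function(ratios, gene_sets) {
  check_data_frame(ratios, "ratios", c("gene", "strain", "status",
                                       "log2_ratio"))
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a named list.", class = "xylevo_input_error")
  }
  ratios <- as_tibble(ratios)
  present <- unique(ratios$gene)
  out <- list()
  for (set_name in names(gene_sets)) {
    members <- intersect(unique(gene_sets[[set_name]]), present)
    if (!length(members)) {
      warn(sprintf("gene set '%s' has no genes in the matrix; skipped.",
                   set_name))
      next
    }
    per_strain <- ratios |>
      dplyr::filter(.data$gene %in% members) |>
      dplyr::group_by(.data$strain, .data$status) |>
      dplyr::summarise(strain_mean = mean(.data$log2_ratio),
                       .groups = "drop")
    out[[set_name]] <- per_strain |>
      dplyr::group_by(.data$status) |>
      dplyr::summarise(
        mean = mean(.data$strain_mean),
        se = if (dplyr::n() > 1) sd(.data$strain_mean) / sqrt(dplyr::n())
             else 0,
        n_genes = length(members),
        n_strains = dplyr::n(),
        single_strain = dplyr::n() == 1L,
        .groups = "drop"
      ) |>
      dplyr::mutate(set = set_name, .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Per-gene wild-type vs evolved profile of a gene group
#'
#' For each gene of a group, averages its (replicate-averaged) expression on
#' the chosen sugar over all strains, separately before and after evolution,
#' and divides both means by the gene's total reads over all samples of the
#' matrix. This per-gene normalisation puts lowly and highly expressed genes
#' on a common scale for paired comparison.
#'
#' @param counts Replicate-averaged counts from [average_replicates()].
#' @param genes Character vector of group member genes (order preserved).
#' @param design Collapsed design; defaults to the attached attribute.
#' @param sugar Sugar context for the per-status means (default
#'   `"xylulose"`).
#' @return A tibble: `gene`, `wt_value`, `evolved_value`. Genes absent from
#'   the matrix or with zero total reads are excluded with a warning.
#' @export
per_gene_group_profile <- function(counts, genes, design = NULL,
                                   sugar = "xylulose") {
  validate_counts(counts)
  design <- avg_design(counts, design)
  genes_in <- genes[genes %in% counts$gene]
  if (length(genes_in) < length(genes)) {
    warn(sprintf("%d group gene(s) absent from the matrix were dropped.",
                 length(genes) - length(genes_in)))
  }
  if (!length(genes_in)) {
    abort("no group genes present in the matrix.",
          class = "xylevo_input_error")
  }
  idx <- match(genes_in, counts$gene)
  all_cols <- sample_cols(counts)
  totals <- rowSums(counts[idx, all_cols, drop = FALSE])
  wt_cols <- design$sample_id[design$status == "wt" & design$sugar == sugar]
  ev_cols <- design$sample_id[design$status == "evolved" &
                                design$sugar == sugar]
  if (!length(wt_cols) || !length(ev_cols)) {
    abort(sprintf("matrix lacks wt or evolved samples on %s.", sugar),
          class = "xylevo_input_error")
  }
  wt_mean <- rowMeans(counts[idx, wt_cols, drop = FALSE])
  ev_mean <- rowMeans(counts[idx, ev_cols, drop = FALSE])
  keep <- totals > 0
  if (any(!keep)) {
    warn(sprintf("%d gene(s) with zero total reads were excluded.",
                 sum(!keep)))
  }
  tibble(
    gene = genes_in[keep],
    wt_value = wt_mean[keep] / totals[keep],
    evolved_value = ev_mean[keep] / totals[keep]
  )
}
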