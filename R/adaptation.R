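# Per-strain expression change of a gene group between evolved and ancestral
# populations, and its correlation with growth improvement.

#' Per-strain evolved/wild-type expression change of a gene group
#'
#' For each strain, computes `log2(mean evolved expression / mean wild-type
#' expression)` of the group's genes on the chosen sugar, from a
#' replicate-averaged matrix. A loss of induction after evolution shows up as
#' a negative change.
#'
#' @param counts Replicate-averaged counts from [average_replicates()].
#' @param genes Character vector of group member genes.
#' @param design Collapsed design; defaults to the attached attribute.
#' @param sugar Sugar context (default `"xylulose"`, the condition under
#'   selection).
#' @param pseudocount Added to both group means before the ratio (default 1).
#' @param group_name Optional label copied into the output.
#' @return A tibble: `strain`, `group`, `expression_change` (log2).
#' @export
expression_change <- function(counts, genes, design = NULL,
                              sugar = "xylulose", pseudocount = 1,
                              group_name = "group") {
  validate_counts(counts)
  design <- avg_design(counts, design)
  check_number(pseudocount, "pseudocount", lower = 0)
  genes_in <- intersect(genes, counts$gene)
  if (!length(genes_in)) {
    abort(sprintf("gene group '%s' has no genes in the matrix.", group_name),
          class = "xylevo_input_error")
  }
  idx <- match(genes_in, counts$gene)
  strains <- unique(design$strain)
  change <- vapply(strains, function(s) {
    ev <- design$sample_id[design$strain == s & design$status == "evolved" &
                             design$sugar == sugar]
    wt <- design$sample_id[design$strain == s & design$status == "wt" &
                             design$sugar == sugar]
    if (length(ev) != 1L || length(wt) != 1L) {
      abort(sprintf("strain %s lacks wt or evolved samples on %s.", s, sugar),
            class = "xylevo_input_error")
    }
    log2((mean(counts[[ev]][idx]) + pseudocount) /
           (mean(counts[[wt]][idx]) + pseudocount))
  }, numeric(1))
  tibble(strain = strains, group = group_name,
         expression_change = unname(change))
}

correlate_one <- function(df, permutations, seed) {
  n <- nrow(df)
  if (n < 3L) {
    abort("at least 3 strains are required for a correlation.",
          class = "xylevo_input_error")
  }
  x <- df$expression_change
  y <- df$growth_improvement
  if (anyNA(x) || anyNA(y)) {
    abort("missing values in correlation inputs.",
          class = "xylevo_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: correlation is undefined.",
          class = "xylevo_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r_obs <- unname(ct$estimate)
  p_perm <- NA_real_
  if (permutations > 0) {
    p_perm <- with_seed(seed, {
      hits <- sum(vapply(seq_len(permutations), function(i) {
        abs(cor(x, sample(y))) >= abs(r_obs)
      }, logical(1)))
      (1 + hits) / (1 + permutations)
    })
  }
  tibble(r = r_obs, p = ct$p.value, p_permutation = p_perm, n = n)
}

#' Correlate expression change with growth improvement
#'
#' Pearson correlation between per-strain expression change of a gene group
#' (evolved/wild type, log2) and per-strain growth improvement (the
#' effective-growth-rate fold change). The parametric two-sided p-value uses
#' the t transform with n - 2 degrees of freedom; a seeded permutation
#' p-value (shuffling the improvement values) is reported alongside as a
#' distribution-free check.
#'
#' @param records A tibble with columns `expression_change` and
#'   `growth_improvement`, one row per strain, and optionally `group` for
#'   several groups at once. Build it by joining [expression_change()] with
#'   [fold_change()] output (see [strain_change_records()]).
#' @param permutations Number of permutations (default 10000; 0 disables).
#' @param seed Seed for the permutation draw.
#' @return An object of class `evo_correlation`; use [tidy()] for the
#'   per-group results (`group`, `r`, `p`, `p_permutation`, `n`) and
#'   [glance()] for a one-row summary.
#' @export
correlate_change_with_growth <- function(records, permutations = 10000,
                                         seed = NULL) {
  check_data_frame(records, "records",
                   c("expression_change", "growth_improvement"))
  check_number(permutations, "permutations", lower = 0)
  if (any(records$growth_improvement <= 0, na.rm = TRUE)) {
    abort("growth improvement folds must be positive.",
          class = "xylevo_input_error")
  }
  records <- as_tibble(records)
  if (!"group" %in% names(records)) records$group <- "group"
  result <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ correlate_one(.x, permutations,
                                        stage_seed(seed, "correlation"))) |>
    dplyr::ungroup()
  structure(
    list(result = result, records = records, permutations = permutations),
    class = "evo_correlation"
  )
}

#' Assemble strain-change records for correlation
#'
#' Joins per-strain expression changes with growth-improvement folds into the
#' record format [correlate_change_with_growth()] expects.
#'
#' @param changes Output of [expression_change()] (possibly several groups
#'   row-bound together).
#' @param folds Output of [fold_change()].
#' @return A tibble: `strain`, `group`, `expression_change`,
#'   `growth_improvement`.
#' @export
strain_change_records <- function(changes, folds) {
  check_data_frame(changes, "changes", c("strain", "group",
                                         "expression_change"))
  check_data_frame(folds, "folds", c("strain", "effective_fold"))
  dplyr::inner_join(
    as_tibble(changes),
    dplyr::select(as_tibble(folds), "strain",
                  growth_improvement = "effective_fold"),
    by = "strain"
  )
}

#' @method tidy evo_correlation
#' @export
tidy.evo_correlation <- function(x, ...) x$result

#' @method glance evo_correlation
#' @export
glance.evo_correlation <- function(x, ...) {
  tibble(
    n_groups = nrow(x$result),
    min_p = min(x$result$p),
    permutations = x$permutations,
    n_strains = x$result$n[1]
  )
}

#' @method print evo_correlation
#' @export
print.evo_correlation <- function(x, ...) {
  cat("Expression-change vs growth-improvement correlation\n")
  print(x$result, ...)
  invisible(x)
}

#' Group-vs-group expression coordinates
#'
#' For each strain and status, computes the pair of group-mean log2
#' xylulose/glucose ratios for two gene groups, giving scatter coordinates
#' that place every population in the plane spanned by the two programmes
#' (e.g. amino-acid biosynthesis vs ribosomal proteins). The average
#' displacement acquired during evolution (evolved minus wild-type mean,
#' averaged over strains) is attached as attribute `"displacement"`.
#'
#' @param ratios Long ratio tibble from [log_ratio_xyl_glu()].
#' @param set_a,set_b Character vectors of member genes.
#' @param names_ab Axis labels (default `c("a", "b")`).
#' @param contexts Optional tibble of `strain`/`status` rows to restrict to;
#'   unknown contexts raise an error.
#' @return A tibble: `strain`, `status`, `mean_a`, `mean_b` (columns named
#'   `mean_<label>`), with attribute `"displacement"`.
#' @export
group_vs_group_coordinates <- function(ratios, set_a, set_b,
                                       names_ab = c("a", "b"),
                                       contexts = NULL) {
  check_data_frame(ratios, "ratios", c("gene", "strain", "status",
                                       "log2_ratio"))
  stopifnot(length(names_ab) == 2L)
  ratios <- as_tibble(ratios)
  present <- unique(ratios$gene)
  a_in <- intersect(set_a, present)
  b_in <- intersect(set_b, present)
  if (!length(a_in) || !length(b_in)) {
    abort("both gene groups must intersect the matrix.",
          class = "xylevo_input_error")
  }
  mean_of <- function(members) {
    ratios |>
      dplyr::filter(.data$gene %in% members) |>
      dplyr::group_by(.data$strain, .data$status) |>
      dplyr::summarise(m = mean(.data$log2_ratio), .groups = "drop")
  }
  col_a <- paste0("mean_", names_ab[1])
  col_b <- paste0("mean_", names_ab[2])
  coords <- dplyr::inner_join(
    dplyr::rename(mean_of(a_in), !!col_a := "m"),
    dplyr::rename(mean_of(b_in), !!col_b := "m"),
    by = c("strain", "status")
  )
  if (!is.null(contexts)) {
    check_data_frame(contexts, "contexts", c("strain", "status"))
    key <- paste(coords$strain, coords$status)
    want <- paste(contexts$strain, contexts$status)
    unknown <- setdiff(want, key)
    if (length(unknown)) {
      abort(sprintf("unknown context(s): %s.", paste(unknown, collapse = ", ")),
            class = "xylevo_input_error")
    }
    coords <- coords[key %in% want, ]
  }
  wide <- coords |>
    tidyr::pivot_longer(dplyr::all_of(c(col_a, col_b)),
                        names_to = "axis", values_to = "value") |>
    tidyr::pivot_wider(names_from = "status", values_from = "value")
  disp <- if (all(c("evolved", "wt") %in% names(wide))) {
    wide |>
      dplyr::group_by(.data$axis) |>
      dplyr::summarise(
        displacement = mean(.data$evolved - .data$wt, na.rm = TRUE),
        .groups = "drop"
      )
  } else {
    tibble(axis = c(col_a, col_b), displacement = NA_real_)
  }
  attr(coords, "displacement") <- disp
  coords
}
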