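#' Published growth-parameter fold changes for twelve evolved yeast strains
#'
#' Evolved/ancestor fold changes in growth parameters reported for twelve
#' wild *S. cerevisiae* isolates after ~300 generations of serial-dilution
#' propagation on xylulose. Columns give the fold change (evolved / wild
#' type) in the log-phase growth rate, the maximum OD600, the time to
#' maximum OD, and the published effective growth rate (maximum OD / time to
#' maximum OD).
#'
#' The printed effective-fold column is carried for reference; it can be
#' recomputed from the maximum-OD and time columns with [fold_change()] (the
#' printed values are rounded to two decimals for most rows, one for some).
#'
#' @format A tibble with 12 rows and 5 columns: `strain` (integer),
#'   `growth_rate_fold`, `max_od_fold`, `time_to_max_fold`,
#'   `effective_fold_printed` (doubles).
#' @export
strain_growth_folds <- tibble::tibble(
  strain = 1:12,
  growth_rate_fold = c(1.32, 1.03, 1.78, 1.13, 1.38, 0.78,
                       1.11, 1.36, 1.14, 1.40, 1.14, 0.92),
  max_od_fold = c(3.00, 1.39, 3.27, 1.36, 1.80, 1.15,
                  1.07, 1.41, 1.29, 1.14, 1.38, 0.97),
  time_to_max_fold = c(1.53, 1.20, 1.36, 0.82, 0.76, 0.79,
                       0.73, 0.80, 1.21, 1.19, 0.94, 0.88),
  effective_fold_printed = c(1.96, 1.16, 2.40, 1.66, 2.37, 1.46,
                             1.47, 1.76, 1.07, 0.96, 1.47, 1.10)
)
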