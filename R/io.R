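# Readers and writers for the interchange formats: wide plate-reader CSV,
# sample-sheet / counts / results TSVs, GMT gene sets and the YAML run
# configuration. Every writer's output is accepted by its paired reader.

#' Write and read wide plate-reader CSV
#'
#' The wide format has a `time_h` first column and one OD column per well.
#' `read_plate_csv()` validates the file (strictly increasing times, positive
#' ODs) and reports offending rows by line number; with a sample sheet it
#' returns annotated curves.
#'
#' @param curves Curve tibble with `time_h`, `od` and a `well` column (one
#'   series per well; all wells must share the time grid).
#' @param path File path.
#' @param samples Optional sample sheet (`well`, `strain`, `status`,
#'   `replicate`) used to annotate wells; unknown wells raise an error.
#' @return `read_plate_csv()` returns a curve tibble (`well`, `time_h`, `od`,
#'   plus annotation columns when `samples` is given).
#' @export
write_plate_csv <- function(curves, path) {
  check_data_frame(curves, "curves", c("well", "time_h", "od"))
  wide <- tidyr::pivot_wider(
    as_tibble(curves)[, c("well", "time_h", "od")],
    names_from = "well", values_from = "od"
  )
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path, samples = NULL) {
  # base read.csv: correctly-rounded double parsing, so write/read round-trips
  # are bit-exact
  wide <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (names(wide)[1] != "time_h") {
    abort("plate CSV must have `time_h` as its first column.",
          class = "xylevo_validation_error")
  }
  bad_t <- which(diff(wide$time_h) <= 0)
  if (length(bad_t)) {
    abort(sprintf("non-monotone time at data line(s): %s.",
                  paste(bad_t + 1L, collapse = ", ")),
          class = "xylevo_validation_error")
  }
  long <- tidyr::pivot_longer(wide, -"time_h", names_to = "well",
                              values_to = "od")
  bad_od <- long[long$od <= 0 | is.na(long$od), ]
  if (nrow(bad_od)) {
    lines <- match(bad_od$time_h, wide$time_h) + 1L
    abort(sprintf("non-positive OD in well(s) %s (line(s) %s).",
                  paste(unique(bad_od$well), collapse = ", "),
                  paste(unique(lines), collapse = ", ")),
          class = "xylevo_validation_error")
  }
  long <- dplyr::arrange(long, .data$well, .data$time_h)
  if (!is.null(samples)) {
    check_data_frame(samples, "samples", c("well", "strain", "status",
                                           "replicate"))
    unknown <- setdiff(unique(long$well), samples$well)
    if (length(unknown)) {
      abort(sprintf("well(s) not in sample sheet: %s.",
                    paste(unknown, collapse = ", ")),
            class = "xylevo_validation_error")
    }
    long <- dplyr::inner_join(long, as_tibble(samples), by = "well")
    long <- long[, c("well", "strain", "status", "replicate", "time_h", "od")]
  }
  long
}

#' Write and read tab-separated tables
#'
#' Thin TSV wrappers (tab separator, `.` decimal mark, header row) used for
#' sample sheets, count matrices and all result tables. `read_counts()`
#' additionally validates the count-matrix contract (first column `gene`,
#' unique ids, non-negative values).
#'
#' @param x A data frame.
#' @param path File path.
#' @return Readers return tibbles.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname write_tsv_table
#' @export
read_counts <- function(path) {
  counts <- read_tsv_table(path)
  if (names(counts)[1] != "gene") {
    abort("counts TSV must have `gene` as its first column.",
          class = "xylevo_validation_error")
  }
  validate_counts(counts)
  counts
}

#' @rdname write_tsv_table
#' @export
read_sample_sheet <- function(path) {
  design <- read_tsv_table(path)
  validate_design(design)
  design
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member genes. Duplicate members within a set are deduplicated with a
#' warning; empty sets and duplicate set names are rejected.
#'
#' @param path File path.
#' @param gene_sets Named list of gene-id vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt()` returns a named list of gene-id vectors with the
#'   descriptions attached as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate gene-set name(s): %s.",
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")),
          class = "xylevo_validation_error")
  }
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      abort(sprintf("gene set '%s' is empty.", p[1]),
            class = "xylevo_validation_error")
    }
    if (anyDuplicated(members)) {
      warn(sprintf("gene set '%s' has duplicated members; deduplicated.",
                   p[1]))
      members <- unique(members)
    }
    members
  })
  names(sets) <- names_
  attr(sets, "descriptions") <- vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else ""
  }, character(1))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a named list.", class = "xylevo_input_error")
  }
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with its
#' default, plus the global seed. A single configuration serialises to YAML
#' and round-trips losslessly through [write_run_config()] /
#' [read_run_config()]. The global seed fans out to per-stage seeds by fixed
#' offsets, so each stage is individually reproducible.
#'
#' @param seed Global integer seed.
#' @param simulate If `TRUE`, the pipeline generates its own synthetic inputs
#'   from the `growth`/`expression` blocks; if `FALSE`, the `*_path` entries
#'   must point at existing input files.
#' @param growth Named list overriding [growth_sim_params()] defaults, plus
#'   `n_replicates` (wells per strain and status).
#' @param expression Named list overriding [expression_sim_params()]
#'   defaults.
#' @param analysis Named list of stage parameters: `smooth_window`,
#'   `slope_window`, `saturation_fraction`, `pseudocount`,
#'   `changed_threshold`, `min_sign_fraction`, `permutations`.
#' @param plates_path,growth_samples_path,counts_path,design_path,gmt_path
#'   Input paths when `simulate = FALSE`.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       simulate = TRUE,
                       growth = list(),
                       expression = list(),
                       analysis = list(),
                       plates_path = NULL,
                       growth_samples_path = NULL,
                       counts_path = NULL,
                       design_path = NULL,
                       gmt_path = NULL,
                       log_level = "info") {
  seed <- check_count(seed, "seed", lower = 0L)
  stopifnot(is.logical(simulate), length(simulate) == 1L)
  if (!log_level %in% c("quiet", "info", "debug")) {
    abort("`log_level` must be quiet, info or debug.",
          class = "xylevo_parameter_error")
  }
  growth_defaults <- list(baseline_od = 0.05, capacity = 1.0, lag = 2,
                          noise_sd = 0.005, sampling_interval = 0.25,
                          n_replicates = 2L)
  expression_defaults <- list(n_genes = 2000L, n_strains = 12L,
                              baseline_log_mean = 0, baseline_log_sd = 1,
                              aa_induction_intercept = 1.0,
                              aa_induction_slope = 5.0, rp_coupling = 2.0,
                              evolved_aa_residual = 0, dispersion = 0.05,
                              library_size = 1e6, n_replicates = 2L)
  analysis_defaults <- list(smooth_window = 5L, slope_window = 5L,
                            saturation_fraction = 0.95, pseudocount = 1,
                            changed_threshold = 1, min_sign_fraction = 2 / 3,
                            permutations = 10000L)
  merge_block <- function(defaults, user, block) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      abort(sprintf("unknown %s option(s): %s.", block,
                    paste(unknown, collapse = ", ")),
            class = "xylevo_config_error")
    }
    utils::modifyList(defaults, user)
  }
  cfg <- structure(
    list(
      seed = seed,
      simulate = simulate,
      growth = merge_block(growth_defaults, growth, "growth"),
      expression = merge_block(expression_defaults, expression, "expression"),
      analysis = merge_block(analysis_defaults, analysis, "analysis"),
      plates_path = plates_path,
      growth_samples_path = growth_samples_path,
      counts_path = counts_path,
      design_path = design_path,
      gmt_path = gmt_path,
      log_level = log_level
    ),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!cfg$simulate) {
    needed <- c("plates_path", "growth_samples_path", "counts_path",
                "design_path", "gmt_path")
    missing <- needed[vapply(cfg[needed], is.null, logical(1))]
    if (length(missing)) {
      abort(sprintf(
        "simulate = FALSE but input path(s) missing: %s.",
        paste(missing, collapse = ", ")
      ), class = "xylevo_config_error")
    }
    absent <- needed[!vapply(cfg[needed], function(p) {
      is.null(p) || file.exists(p)
    }, logical(1))]
    if (length(absent)) {
      abort(sprintf("input file(s) not found: %s.",
                    paste(unlist(cfg[absent]), collapse = ", ")),
            class = "xylevo_config_error")
    }
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  # 17 significant digits so doubles round-trip bit-exactly
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

xy_log <- function(cfg, level, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[cfg$log_level]] >= levels[[level]]) {
    message(sprintf(...))
  }
}
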