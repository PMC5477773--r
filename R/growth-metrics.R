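# Growth-parameter extraction from OD600 time series and evolved/ancestor
# fold-change summaries.

curve_id_cols <- function(df) {
  intersect(c("strain", "status", "replicate", "well"), names(df))
}

validate_curve <- function(df, label = "curve") {
  check_data_frame(df, label, c("time_h", "od"))
  if (nrow(df) < 4L) {
    abort(sprintf("%s must have at least 4 timepoints.", label),
          class = "xylevo_input_error")
  }
  if (any(diff(df$time_h) <= 0)) {
    abort(sprintf("%s times must be strictly increasing.", label),
          class = "xylevo_input_error")
  }
  if (any(df$od <= 0)) {
    abort(sprintf("%s optical densities must all be positive.", label),
          class = "xylevo_input_error")
  }
  invisible(df)
}

# truncated-window running mean: windows shrink at the series ends
run_mean_trunc <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# truncated-window running median (same endpoint convention as the mean)
run_median_trunc <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Smooth optical-density curves
#'
#' Applies a running median followed by a running mean, both with the same odd
#' window; windows are truncated at the series ends. The median step removes
#' isolated spikes (a bubble or misread well) without blunting the sigmoid,
#' and the mean step suppresses residual jitter. `window = 1` is the identity.
#'
#' @param curves A data frame of curves with columns `time_h` and `od`, plus
#'   any of `strain`, `status`, `replicate`, `well` identifying separate
#'   curves (smoothing never crosses curve boundaries).
#' @param window Odd positive integer, at most the number of timepoints.
#' @return The input tibble with `od` replaced by its smoothed values.
#' @export
smooth_curve <- function(curves, window = 5) {
  check_data_frame(curves, "curves", c("time_h", "od"))
  check_count(window, "window")
  if (window %% 2L == 0L) {
    abort("`window` must be odd.", class = "xylevo_parameter_error")
  }
  ids <- curve_id_cols(curves)
  out <- dplyr::group_by(as_tibble(curves), dplyr::across(dplyr::all_of(ids)))
  n_min <- min(dplyr::summarise(out, n = dplyr::n())$n)
  if (window > n_min) {
    abort("`window` exceeds the length of at least one curve.",
          class = "xylevo_parameter_error")
  }
  out <- dplyr::mutate(
    out,
    od = run_mean_trunc(run_median_trunc(.data$od, window), window)
  )
  dplyr::ungroup(out)
}

#' Configuration for growth-metric extraction
#'
#' @param smooth_window Odd window for [smooth_curve()] (1 disables smoothing).
#' @param slope_window Number of consecutive points in each sliding
#'   least-squares fit of `ln(OD)` vs time when estimating the log-phase rate.
#' @param saturation_fraction Fraction of the maximum smoothed OD that defines
#'   "time to saturation"; `1.0` means the time of the maximum itself.
#' @param baseline OD subtracted before taking logs for the rate fit (0 fits
#'   raw `ln(OD)`; supply the blank/inoculum OD to recover the intrinsic
#'   logistic rate). Points at or below the baseline are excluded from the fit.
#' @param interpolate If `TRUE` (default) the saturation time is read off by
#'   linear interpolation of the smoothed curve at the exact threshold
#'   crossing; if `FALSE`, the earliest sampled time at or above the threshold
#'   is reported.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(smooth_window = 5, slope_window = 5,
                          saturation_fraction = 0.95, baseline = 0,
                          interpolate = TRUE) {
  check_count(smooth_window, "smooth_window")
  check_count(slope_window, "slope_window", lower = 2L)
  check_number(saturation_fraction, "saturation_fraction",
               lower = 0, upper = 1, allow_equal_lower = FALSE)
  check_number(baseline, "baseline", lower = 0)
  structure(
    list(smooth_window = smooth_window, slope_window = slope_window,
         saturation_fraction = saturation_fraction, baseline = baseline,
         interpolate = interpolate),
    class = "growth_config"
  )
}

# maximum sliding-window least-squares slope of ln(od - baseline) vs time
max_log_slope <- function(time_h, od, baseline, window) {
  keep <- od > baseline
  t <- time_h[keep]
  y <- log(od[keep] - baseline)
  n <- length(y)
  if (n < window) return(NA_real_)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- t[idx] - mean(t[idx])
    sum(tt * (y[idx] - mean(y[idx]))) / sum(tt^2)
  }, numeric(1))
  max(slopes)
}

compute_metrics_one <- function(df, config) {
  validate_curve(df)
  sm <- smooth_curve(df[, c("time_h", "od")], config$smooth_window)
  od <- sm$od
  t <- sm$time_h
  i_max <- which.max(od) # which.max takes the earliest tie
  max_od <- od[i_max]
  degenerate <- max_od <= od[1L]

  if (config$saturation_fraction >= 1) {
    t_sat <- t[i_max]
  } else {
    thr <- config$saturation_fraction * max_od
    j <- which(od >= thr)[1L]
    if (config$interpolate && j > 1L && od[j] > thr) {
      t_sat <- t[j - 1L] +
        (thr - od[j - 1L]) / (od[j] - od[j - 1L]) * (t[j] - t[j - 1L])
    } else {
      t_sat <- t[j]
    }
  }
  tibble(
    log_growth_rate = max_log_slope(t, od, config$baseline,
                                    config$slope_window),
    max_od = max_od,
    time_to_max_od = t_sat,
    effective_growth_rate = max_od / t_sat,
    degenerate = degenerate
  )
}

#' Extract growth metrics from OD time series
#'
#' For each curve, computes the log-phase growth rate (maximum sliding-window
#' least-squares slope of `ln(OD)` vs time), the maximum smoothed OD, the time
#' to saturation (earliest time the smoothed curve reaches
#' `saturation_fraction` of its maximum) and the effective growth rate,
#' defined as maximum OD divided by time to saturation — a single figure that
#' rewards both higher yield and faster saturation.
#'
#' Curves without net growth (maximum not above the first reading) are flagged
#' `degenerate = TRUE` with a warning; their metrics are still reported so
#' batch runs complete.
#'
#' @param curves Data frame of curves (`time_h`, `od`, plus identifier columns
#'   among `strain`, `status`, `replicate`, `well`).
#' @param config A [growth_config()] object.
#' @return A tibble, one row per curve: identifiers, `log_growth_rate`,
#'   `max_od`, `time_to_max_od`, `effective_growth_rate`, `degenerate`.
#' @examples
#' curve <- simulate_growth_curve(growth_sim_params(noise_sd = 0))
#' compute_metrics(dplyr::mutate(curve, strain = "s1", status = "wt"))
#' @export
compute_metrics <- function(curves, config = growth_config()) {
  check_data_frame(curves, "curves", c("time_h", "od"))
  stopifnot(inherits(config, "growth_config"))
  ids <- curve_id_cols(curves)
  out <- as_tibble(curves) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(~ compute_metrics_one(.x, config)) |>
    dplyr::ungroup()
  if (any(out$degenerate)) {
    warn(sprintf("%d curve(s) show no net growth; flagged degenerate.",
                 sum(out$degenerate)))
  }
  out
}

geom_mean <- function(x) exp(mean(log(x)))

#' Evolved/ancestor fold changes in growth metrics
#'
#' Computes per-strain evolved/wild-type ratios for each growth metric. When
#' replicate measurements are present, metrics are first combined across
#' replicates by geometric mean (so the fold of the combined metrics equals
#' the geometric mean of per-replicate folds). By construction the effective
#' fold equals the maximum-OD fold divided by the time fold.
#'
#' @param metrics A tibble from [compute_metrics()] covering both statuses
#'   (`wt` and `evolved`) for each strain; degenerate curves are dropped with
#'   a warning.
#' @return A tibble with one row per strain: `growth_rate_fold`,
#'   `max_od_fold`, `time_to_max_fold`, `effective_fold`.
#' @examples
#' # reproduce a printed effective fold from max-OD and time folds alone
#' m <- tibble::tibble(
#'   strain = "strain1", status = c("wt", "evolved"),
#'   log_growth_rate = c(1, 1.32), max_od = c(1, 3),
#'   time_to_max_od = c(1, 1.53)
#' )
#' m$effective_growth_rate <- m$max_od / m$time_to_max_od
#' fold_change(m)
#' @export
fold_change <- function(metrics) {
  check_data_frame(metrics, "metrics",
                   c("strain", "status", "log_growth_rate", "max_od",
                     "time_to_max_od", "effective_growth_rate"))
  metrics <- as_tibble(metrics)
  if ("degenerate" %in% names(metrics) && any(metrics$degenerate)) {
    warn("dropping degenerate curves before computing fold changes.")
    metrics <- dplyr::filter(metrics, !.data$degenerate)
  }
  vals <- c("log_growth_rate", "max_od", "time_to_max_od",
            "effective_growth_rate")
  if (any(metrics[vals] <= 0)) {
    abort("all metrics must be positive to form fold changes.",
          class = "xylevo_division_error")
  }
  collapsed <- metrics |>
    dplyr::group_by(.data$strain, .data$status) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vals), geom_mean),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(collapsed, names_from = "status",
                             values_from = dplyr::all_of(vals))
  needed <- paste(rep(vals, each = 2), c("wt", "evolved"), sep = "_")
  if (!all(needed %in% names(wide)) || anyNA(wide[needed])) {
    abort("each strain needs both wt and evolved metrics.",
          class = "xylevo_input_error")
  }
  tibble(
    strain = wide$strain,
    growth_rate_fold = wide$log_growth_rate_evolved / wide$log_growth_rate_wt,
    max_od_fold = wide$max_od_evolved / wide$max_od_wt,
    time_to_max_fold = wide$time_to_max_od_evolved / wide$time_to_max_od_wt,
    effective_fold = wide$effective_growth_rate_evolved /
      wide$effective_growth_rate_wt
  )
}

#' Classify strains as improved or not
#'
#' A strain counts as improved when its effective-growth-rate fold change
#' (evolved/ancestor) strictly exceeds `threshold`.
#'
#' @param folds A tibble with columns `strain` and `effective_fold`
#'   (e.g. from [fold_change()]).
#' @param threshold Fold-change threshold (default 1: any strict improvement).
#' @return The input with added `improved` (logical) and `label`
#'   (`"improved"` / `"not_improved"`); the number of improved strains is
#'   attached as attribute `n_improved`.
#' @examples
#' cls <- classify_improvement(
#'   fold_change_from_table(strain_growth_folds)
#' )
#' attr(cls, "n_improved")
#' @export
classify_improvement <- function(folds, threshold = 1.0) {
  check_data_frame(folds, "folds", c("strain", "effective_fold"))
  check_number(threshold, "threshold", lower = 0)
  if (nrow(folds) == 0L) {
    abort("`folds` must be non-empty.", class = "xylevo_input_error")
  }
  out <- dplyr::mutate(
    as_tibble(folds),
    improved = .data$effective_fold > threshold,
    label = ifelse(.data$improved, "improved", "not_improved")
  )
  attr(out, "n_improved") <- sum(out$improved)
  out
}

#' Recompute fold-change records from a published fold table
#'
#' Convenience constructor turning a table of per-strain maximum-OD and
#' time-to-saturation fold changes (such as [strain_growth_folds]) into the
#' same record [fold_change()] produces, recomputing the effective fold as
#' `max_od_fold / time_to_max_fold` rather than trusting any printed value.
#'
#' @param table Data frame with `strain`, `max_od_fold`, `time_to_max_fold`
#'   and optionally `growth_rate_fold`.
#' @return A tibble matching the [fold_change()] output contract.
#' @export
fold_change_from_table <- function(table) {
  check_data_frame(table, "table",
                   c("strain", "max_od_fold", "time_to_max_fold"))
  if (any(table$time_to_max_fold <= 0)) {
    abort("time folds must be positive.", class = "xylevo_division_error")
  }
  tibble(
    strain = table$strain,
    growth_rate_fold = table$growth_rate_fold %||% rep(NA_real_, nrow(table)),
    max_od_fold = table$max_od_fold,
    time_to_max_fold = table$time_to_max_fold,
    effective_fold = table$max_od_fold / table$time_to_max_fold
  )
}

#' Generations elapsed under serial dilution
#'
#' Each dilution by factor `d` is regrown to saturation, i.e. log2(d)
#' doublings; `n_dilutions` cycles therefore span `n_dilutions * log2(d)`
#' generations (a 1:64 daily dilution is 6 generations per day).
#'
#' @param dilution_factor Dilution factor per cycle (> 1).
#' @param n_dilutions Number of dilution cycles (>= 0).
#' @return Number of generations (double).
#' @examples
#' generations_elapsed(64, 50) # ~300 generations
#' @export
generations_elapsed <- function(dilution_factor, n_dilutions) {
  check_number(dilution_factor, "dilution_factor", lower = 1,
               allow_equal_lower = FALSE)
  check_number(n_dilutions, "n_dilutions", lower = 0)
  n_dilutions * log2(dilution_factor)
}
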