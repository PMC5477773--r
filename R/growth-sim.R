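# Synthetic plate-reader growth curves: baseline-shifted logistic with an
# explicit lag phase and additive Gaussian measurement noise.

# Fraction of the carrying capacity reached at t = lag; fixes the logistic
# midpoint so that visible growth departs from baseline after the lag.
.lag_fraction <- 0.01

#' Parameters for a synthetic growth curve
#'
#' Describes one well's optical-density trajectory as a baseline-shifted
#' logistic, `OD(t) = baseline_od + capacity / (1 + exp(-rate * (t - t_mid)))`,
#' with the midpoint `t_mid` placed so that the logistic term is 1% of
#' `capacity` at `t = lag`: growth becomes visible only after the lag phase.
#' Gaussian noise with standard deviation `noise_sd` is added to each reading
#' and the result is clipped at a small positive floor, as a plate reader
#' never reports non-positive optical density.
#'
#' All defaults are invented, chosen to resemble slow microbial batch growth
#' in a plate reader (saturation density near 1 OD over one to two days); none
#' are measurements.
#'
#' @param baseline_od Starting optical density (dimensionless, > 0).
#' @param capacity Carrying-capacity increment above the baseline (OD, > 0).
#' @param rate Logistic rate constant (per hour, > 0).
#' @param lag Lag-phase duration (hours, >= 0).
#' @param noise_sd Measurement noise standard deviation (OD, >= 0).
#' @param sampling_interval Time between readings (hours, > 0).
#' @param duration Total observation time (hours, must exceed `lag`).
#' @return An object of class `growth_sim_params` (a named list).
#' @seealso [simulate_growth_curve()], [simulate_strain_panel()]
#' @export
growth_sim_params <- function(baseline_od = 0.05, capacity = 1.0, rate = 0.3,
                              lag = 2, noise_sd = 0.005,
                              sampling_interval = 0.25, duration = 48) {
  check_number(baseline_od, "baseline_od", lower = 0, allow_equal_lower = FALSE)
  check_number(capacity, "capacity", lower = 0, allow_equal_lower = FALSE)
  check_number(rate, "rate", lower = 0, allow_equal_lower = FALSE)
  check_number(lag, "lag", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sampling_interval, "sampling_interval", lower = 0,
               allow_equal_lower = FALSE)
  check_number(duration, "duration", lower = 0, allow_equal_lower = FALSE)
  if (duration <= lag) {
    abort("`duration` must exceed `lag`.", class = "xylevo_parameter_error")
  }
  structure(
    list(baseline_od = baseline_od, capacity = capacity, rate = rate,
         lag = lag, noise_sd = noise_sd,
         sampling_interval = sampling_interval, duration = duration),
    class = "growth_sim_params"
  )
}

# Noiseless model evaluation at arbitrary times.
growth_model_od <- function(params, times) {
  t_mid <- params$lag + log((1 - .lag_fraction) / .lag_fraction) / params$rate
  params$baseline_od +
    params$capacity / (1 + exp(-params$rate * (times - t_mid)))
}

#' Analytic growth metrics of the noiseless simulation model
#'
#' Closed-form counterparts of the pipeline metrics for a noiseless logistic
#' curve: the asymptotic maximum OD (`baseline_od + capacity`), the time at
#' which the curve crosses `saturation_fraction` of that maximum, the
#' effective growth rate (their ratio) and the logistic rate constant.
#' Useful as ground truth when validating metric extraction.
#'
#' @param params A [growth_sim_params()] object.
#' @param saturation_fraction Fraction of the maximum OD defining saturation.
#' @return A one-row tibble with `max_od`, `time_to_max_od`,
#'   `effective_growth_rate` and `log_growth_rate`.
#' @export
growth_sim_metrics <- function(params, saturation_fraction = 0.95) {
  stopifnot(inherits(params, "growth_sim_params"))
  check_number(saturation_fraction, "saturation_fraction",
               lower = 0, upper = 1, allow_equal_lower = FALSE)
  max_od <- params$baseline_od + params$capacity
  t_sat <- saturation_time(params, saturation_fraction)
  tibble(
    max_od = max_od,
    time_to_max_od = t_sat,
    effective_growth_rate = max_od / t_sat,
    log_growth_rate = params$rate
  )
}

# Time at which the noiseless curve reaches `frac` of its asymptotic maximum.
saturation_time <- function(params, frac) {
  q <- (frac * (params$baseline_od + params$capacity) - params$baseline_od) /
    params$capacity
  if (q <= 0 || q >= 1) {
    abort("saturation fraction does not intersect the growth range.",
          class = "xylevo_parameter_error")
  }
  k <- log((1 - .lag_fraction) / .lag_fraction)
  params$lag + (k + log(q / (1 - q))) / params$rate
}

#' Simulate one optical-density growth curve
#'
#' Evaluates the baseline-shifted logistic of [growth_sim_params()] on a
#' regular time grid, adds Gaussian measurement noise and clips readings at a
#' positive floor. Identical parameters and seed give a bit-identical series.
#'
#' @param params A [growth_sim_params()] object.
#' @param seed Integer seed for the measurement noise, or `NULL` to use the
#'   current RNG state.
#' @return A tibble with columns `time_h` and `od`.
#' @examples
#' curve <- simulate_growth_curve(growth_sim_params(noise_sd = 0), seed = 1)
#' tail(curve, 3)
#' @export
simulate_growth_curve <- function(params, seed = NULL) {
  stopifnot(inherits(params, "growth_sim_params"))
  times <- seq(0, params$duration, by = params$sampling_interval)
  od <- growth_model_od(params, times)
  if (params$noise_sd > 0) {
    od <- with_seed(seed, od + rnorm(length(od), sd = params$noise_sd))
  }
  tibble(time_h = times, od = pmax(od, 1e-4))
}

#' Simulate a panel of ancestral and evolved strains
#'
#' Builds paired wild-type/evolved growth curves for a strain panel. Evolved
#' parameters are derived from the wild-type parameters so that the *noiseless*
#' fold changes in maximum OD and in time-to-saturation equal the requested
#' targets: the evolved capacity is set from the maximum-OD fold, and the
#' evolved logistic rate is solved in closed form so the saturation-crossing
#' time scales by the time fold. Because the effective growth rate is the
#' ratio of these two quantities, its analytic fold equals
#' `max_od_fold / time_to_max_fold`.
#'
#' @param fold_targets A data frame with one row per strain and columns
#'   `max_od_fold` and `time_to_max_fold` (both > 0); an optional `strain`
#'   column supplies identifiers.
#' @param wt_params A single [growth_sim_params()] object recycled across
#'   strains, or a list with one per strain.
#' @param n_replicates Number of replicate wells per strain and status.
#' @param saturation_fraction Saturation definition used for the analytic
#'   time-to-saturation (match the value later passed to [compute_metrics()]).
#' @param seed Integer seed controlling all measurement noise.
#' @return A list with `curves` (tibble: `strain`, `status`, `replicate`,
#'   `time_h`, `od`) and `params` (tibble of per-curve model parameters and
#'   analytic metrics, including the realised analytic folds for evolved rows).
#' @examples
#' panel <- simulate_strain_panel(
#'   tibble::tibble(max_od_fold = c(3, 1.8), time_to_max_fold = c(1.53, 0.76)),
#'   wt_params = growth_sim_params(noise_sd = 0)
#' )
#' panel$params[, c("strain", "status", "max_od", "time_to_saturation")]
#' @export
simulate_strain_panel <- function(fold_targets,
                                  wt_params = growth_sim_params(),
                                  n_replicates = 1,
                                  saturation_fraction = 0.95,
                                  seed = NULL) {
  check_data_frame(fold_targets, "fold_targets",
                   c("max_od_fold", "time_to_max_fold"))
  n_strains <- nrow(fold_targets)
  if (n_strains == 0L) {
    abort("`fold_targets` must have at least one row.",
          class = "xylevo_input_error")
  }
  if (any(fold_targets$max_od_fold <= 0) ||
      any(fold_targets$time_to_max_fold <= 0)) {
    abort("fold targets must be strictly positive.",
          class = "xylevo_parameter_error")
  }
  check_count(n_replicates, "n_replicates")
  if (inherits(wt_params, "growth_sim_params")) {
    wt_params <- rep(list(wt_params), n_strains)
  }
  if (length(wt_params) != n_strains) {
    abort("`wt_params` must be one parameter set or one per strain.",
          class = "xylevo_input_error")
  }
  strains <- if ("strain" %in% names(fold_targets)) {
    as.character(fold_targets$strain)
  } else {
    sprintf("strain%02d", seq_len(n_strains))
  }

  k <- log((1 - .lag_fraction) / .lag_fraction)

  # derive all evolved parameters first so every well can share one horizon
  derived <- vector("list", n_strains)
  for (i in seq_len(n_strains)) {
    wt <- wt_params[[i]]
    t_sat_wt <- saturation_time(wt, saturation_fraction)
    max_wt <- wt$baseline_od + wt$capacity

    cap_ev <- fold_targets$max_od_fold[i] * max_wt - wt$baseline_od
    if (cap_ev <= 0) {
      abort(sprintf(
        "max_od_fold %g for strain %s leaves no capacity above baseline.",
        fold_targets$max_od_fold[i], strains[i]
      ), class = "xylevo_parameter_error")
    }
    t_sat_ev <- fold_targets$time_to_max_fold[i] * t_sat_wt
    if (t_sat_ev <= wt$lag) {
      abort(sprintf(
        "time_to_max_fold %g for strain %s puts saturation inside the lag.",
        fold_targets$time_to_max_fold[i], strains[i]
      ), class = "xylevo_parameter_error")
    }
    max_ev <- wt$baseline_od + cap_ev
    q_ev <- (saturation_fraction * max_ev - wt$baseline_od) / cap_ev
    rate_ev <- (k + log(q_ev / (1 - q_ev))) / (t_sat_ev - wt$lag)
    derived[[i]] <- list(wt = wt, t_sat_wt = t_sat_wt, cap_ev = cap_ev,
                         rate_ev = rate_ev, t_sat_ev = t_sat_ev)
  }
  # one rectangular plate: horizon generous enough that the slowest well's
  # sampled maximum sits at its asymptote
  duration <- max(vapply(derived, function(d) {
    max(d$wt$duration, d$t_sat_wt + 14 / d$wt$rate,
        d$t_sat_ev + 14 / d$rate_ev)
  }, numeric(1)))

  rows <- list()
  curves <- list()
  idx <- 1L
  for (i in seq_len(n_strains)) {
    wt <- derived[[i]]$wt
    t_sat_wt <- derived[[i]]$t_sat_wt
    t_sat_ev <- derived[[i]]$t_sat_ev
    ev <- growth_sim_params(
      baseline_od = wt$baseline_od, capacity = derived[[i]]$cap_ev,
      rate = derived[[i]]$rate_ev, lag = wt$lag, noise_sd = wt$noise_sd,
      sampling_interval = wt$sampling_interval, duration = duration
    )
    wt_run <- growth_sim_params(
      baseline_od = wt$baseline_od, capacity = wt$capacity, rate = wt$rate,
      lag = wt$lag, noise_sd = wt$noise_sd,
      sampling_interval = wt$sampling_interval, duration = duration
    )

    for (status in c("wt", "evolved")) {
      p <- if (status == "wt") wt_run else ev
      t_sat <- if (status == "wt") t_sat_wt else t_sat_ev
      for (rep_i in seq_len(n_replicates)) {
        curve_seed <- if (is.null(seed)) NULL else {
          (stage_seed(seed, "panel") + 1000L * i +
             100L * (status == "evolved") + rep_i) %% .Machine$integer.max
        }
        curves[[idx]] <- dplyr::mutate(
          simulate_growth_curve(p, seed = curve_seed),
          strain = strains[i], status = status, replicate = rep_i,
          .before = 1
        )
        idx <- idx + 1L
      }
      rows[[length(rows) + 1L]] <- tibble(
        strain = strains[i], status = status,
        baseline_od = p$baseline_od, capacity = p$capacity, rate = p$rate,
        lag = p$lag, noise_sd = p$noise_sd, duration = p$duration,
        max_od = p$baseline_od + p$capacity,
        time_to_saturation = t_sat,
        effective_growth_rate = (p$baseline_od + p$capacity) / t_sat,
        max_od_fold_target = ifelse(status == "evolved",
                                    fold_targets$max_od_fold[i], NA_real_),
        time_fold_target = ifelse(status == "evolved",
                                  fold_targets$time_to_max_fold[i], NA_real_)
      )
    }
  }
  list(
    curves = dplyr::bind_rows(curves),
    params = dplyr::bind_rows(rows)
  )
}
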