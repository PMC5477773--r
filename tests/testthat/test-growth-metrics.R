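test_that("smoothing is the identity for window 1 and on constant series", {
  curve <- make_curve(0:9, c(0.1, 0.12, 0.5, 0.4, 0.8, 1.2, 1.1, 1.3, 1.3,
                             1.32))
  expect_equal(smooth_curve(curve, 1), curve)
  flat <- make_curve(0:9, rep(0.7, 10))
  expect_equal(smooth_curve(flat, 5)$od, rep(0.7, 10))
})

test_that("a single-point spike is removed by median smoothing", {
  od <- rep(0.5, 15)
  od[8] <- 10.5
  curve <- make_curve(0:14, od)
  sm <- smooth_curve(curve, 5)
  expect_lt(max(abs(sm$od - 0.5)), 1e-9)
  # brute-force oracle: median of each truncated window, then its mean
  oracle <- vapply(1:15, function(i) {
    idx <- max(1, i - 2):min(15, i + 2)
    median(od[idx])
  }, numeric(1))
  oracle <- vapply(1:15, function(i) {
    idx <- max(1, i - 2):min(15, i + 2)
    mean(oracle[idx])
  }, numeric(1))
  expect_equal(sm$od, oracle)
})

test_that("invalid smoothing windows are rejected", {
  curve <- make_curve(0:9, seq(0.1, 1, length.out = 10))
  expect_error(smooth_curve(curve, 4), class = "xylevo_parameter_error")
  expect_error(smooth_curve(curve, 11), class = "xylevo_parameter_error")
})

test_that("metrics match closed forms on exponential and plateau curves", {
  # pure exponential: max log-slope equals the rate
  tt <- seq(0, 10, by = 0.25)
  m <- compute_metrics(make_curve(tt, 0.05 * exp(0.3 * tt)), growth_config())
  expect_equal(m$log_growth_rate, 0.3, tolerance = 0.01)

  # plateau 3.0 reached at t = 10 h; saturation fraction 1 means time of max
  tt2 <- seq(0, 20, by = 0.5)
  od2 <- pmin(3.0, 0.3 * tt2 + 0.03)
  od2[tt2 == 0] <- 0.03
  m2 <- compute_metrics(make_curve(tt2, pmax(od2, 0.03)),
                        growth_config(smooth_window = 1,
                                      saturation_fraction = 1))
  expect_equal(m2$max_od, 3.0)
  expect_equal(m2$time_to_max_od, 10)
  expect_equal(m2$effective_growth_rate, 0.3)
})

test_that("coarse-grid metrics agree with a dense-grid oracle within 2%", {
  for (rate in c(0.2, 0.45)) {
    p <- growth_sim_params(rate = rate, capacity = 1.2, noise_sd = 0,
                           duration = 80)
    coarse <- compute_metrics(
      dplyr::mutate(simulate_growth_curve(p), strain = "s", status = "wt"),
      growth_config(baseline = p$baseline_od)
    )
    # oracle on a 0.001 h grid, computed directly from first principles
    dense_t <- seq(0, p$duration, by = 0.001)
    dense_od <- oracle_logistic(dense_t, p$baseline_od, p$capacity, rate,
                                p$lag)
    o_max <- max(dense_od)
    o_tsat <- dense_t[which(dense_od >= 0.95 * o_max)[1]]
    o_rate <- max(diff(log(dense_od - p$baseline_od)) / 0.001)
    expect_equal(coarse$max_od, o_max, tolerance = 0.02)
    expect_equal(coarse$time_to_max_od, o_tsat, tolerance = 0.02)
    expect_equal(coarse$effective_growth_rate, o_max / o_tsat,
                 tolerance = 0.02)
    expect_equal(coarse$log_growth_rate, o_rate, tolerance = 0.02)
  }
})

test_that("reported effective growth rate always equals max OD over time to max", {
  set.seed(4)
  p <- growth_sim_params(noise_sd = 0.01)
  curves <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_curve(seq(0, 48, 0.25),
               simulate_growth_curve(p, seed = i)$od,
               strain = sprintf("s%d", i))
  }))
  m <- compute_metrics(curves, growth_config())
  expect_identical(m$effective_growth_rate, m$max_od / m$time_to_max_od)
})

test_that("metrics transform correctly under time shifts and OD scaling", {
  p <- growth_sim_params(noise_sd = 0.005)
  base <- dplyr::mutate(simulate_growth_curve(p, seed = 8),
                        strain = "s", status = "wt")
  cfg <- growth_config()
  m0 <- compute_metrics(base, cfg)

  shifted <- dplyr::mutate(base, time_h = .data$time_h + 3.5)
  m_shift <- compute_metrics(shifted, cfg)
  expect_equal(m_shift$time_to_max_od, m0$time_to_max_od + 3.5)
  expect_equal(m_shift$max_od, m0$max_od)
  expect_equal(m_shift$log_growth_rate, m0$log_growth_rate)

  scaled <- dplyr::mutate(base, od = .data$od * 2.7)
  m_scale <- compute_metrics(scaled, cfg)
  expect_equal(m_scale$max_od, m0$max_od * 2.7)
  expect_equal(m_scale$effective_growth_rate,
               m0$effective_growth_rate * 2.7)
  expect_equal(m_scale$time_to_max_od, m0$time_to_max_od)
  expect_equal(m_scale$log_growth_rate, m0$log_growth_rate)
})

test_that("curves without net growth are flagged degenerate with a warning", {
  decay <- make_curve(0:9, seq(1, 0.4, length.out = 10))
  expect_warning(m <- compute_metrics(decay, growth_config(smooth_window = 1)),
                 "degenerate")
  expect_true(m$degenerate)
})

test_that("fold changes reproduce the published effective folds from max-OD and time folds", {
  folds <- fold_change_from_table(strain_growth_folds)
  # strains printed at two decimals
  expect_equal(round(folds$effective_fold[folds$strain == 1], 2), 1.96)
  expect_equal(round(folds$effective_fold[folds$strain == 5], 2), 2.37)
  expect_equal(round(folds$effective_fold[folds$strain == 8], 2), 1.76)
  expect_equal(round(folds$effective_fold[folds$strain == 10], 2), 0.96)
  # strain 12 is printed at one decimal
  expect_equal(round(folds$effective_fold[folds$strain == 12], 1), 1.1)

  # the same arithmetic through fold_change() on metric sets
  m <- tibble::tibble(
    strain = "strain5", status = c("wt", "evolved"),
    log_growth_rate = c(1, 1.38), max_od = c(1, 1.8),
    time_to_max_od = c(1, 0.76)
  )
  m$effective_growth_rate <- m$max_od / m$time_to_max_od
  expect_equal(round(fold_change(m)$effective_fold, 2), 2.37)
})

test_that("fold change of a metric set against itself is identity", {
  set.seed(2)
  for (i in 1:5) {
    vals <- stats::runif(4, 0.2, 5)
    m <- tibble::tibble(
      strain = "s", status = c("wt", "evolved"),
      log_growth_rate = vals[1], max_od = vals[2],
      time_to_max_od = vals[3], effective_growth_rate = vals[4]
    )
    f <- fold_change(m)
    expect_equal(unlist(f[-1]), c(growth_rate_fold = 1, max_od_fold = 1,
                                  time_to_max_fold = 1, effective_fold = 1))
  }
})

test_that("improvement classification counts strict threshold crossings", {
  cls <- classify_improvement(fold_change_from_table(strain_growth_folds))
  expect_identical(attr(cls, "n_improved"), 11L)
  expect_identical(cls$label[cls$strain == 10], "not_improved")

  all_one <- tibble::tibble(strain = letters[1:4], effective_fold = 1)
  expect_identical(attr(classify_improvement(all_one), "n_improved"), 0L)

  two <- tibble::tibble(strain = c("a", "b"), effective_fold = c(0.5, 2.0))
  cls2 <- classify_improvement(two)
  # brute-force enumeration over the list
  expect_identical(attr(cls2, "n_improved"),
                   sum(vapply(two$effective_fold, function(f) f > 1,
                              logical(1))))
  expect_identical(attr(cls2, "n_improved"), 1L)
})

test_that("serial-dilution generation arithmetic is log2 of the dilution factor", {
  expect_equal(generations_elapsed(64, 1), 6)
  expect_equal(generations_elapsed(64, 50), 300)
  expect_equal(generations_elapsed(2, 1), 1)
  expect_error(generations_elapsed(1, 10), class = "xylevo_parameter_error")
  expect_error(generations_elapsed(0.5, 10), class = "xylevo_parameter_error")
})
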