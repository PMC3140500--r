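test_that("a pure sine trace yields its known peaks and 180 s periods", {
  t <- seq(0, 1800, by = 10)
  a <- 100 + 20 * sin(2 * pi * t / 180)
  det <- detect_pulses(t, a, smooth_window = 30, min_prominence = 0.1)
  expect_equal(length(det$peak_times), 10)
  gaps <- diff(det$peak_times)
  expect_true(all(abs(gaps - 180) <= 10))
  # peaks and troughs strictly alternate
  ev <- sort(c(det$peak_times, det$trough_times))
  types <- ifelse(ev %in% det$peak_times, "p", "t")
  expect_true(all(types[-1] != types[-length(types)]))
})

test_that("monotone and flat traces contain no pulses", {
  t <- seq(0, 1000, by = 10)
  det <- detect_pulses(t, 100 - 0.05 * t)
  expect_length(det$peak_times, 0)
  det2 <- detect_pulses(t, rep(100, length(t)))
  expect_length(det2$peak_times, 0)
  expect_error(detect_pulses(t, 100 - 0.05 * t, smooth_window = 2000),
               "window")
})

test_that("period detection is invariant to affine rescaling of the trace", {
  sim <- simulate_amnioserosa_traces(preset_pulsation("wt"), seed = 4)
  tr <- sim$traces[sim$traces$cell_id == 2, ]
  d1 <- detect_pulses(tr$t_s, tr$area_um2)
  d2 <- detect_pulses(tr$t_s, 3.7 * tr$area_um2 + 55)
  expect_equal(d1$peak_idx, d2$peak_idx)
  expect_equal(d1$trough_idx, d2$trough_idx)
})

test_that("degenerate period distribution gives exactly regular true gaps", {
  p <- pulsation_preset(period_mean = 180, period_sd = 0, n_cells = 2,
                        n_cycles_total = 10)
  sim <- simulate_amnioserosa_traces(p, seed = 1)
  gaps <- unlist(tapply(sim$truth$peak_time_s, sim$truth$cell_id, diff))
  expect_true(all(abs(gaps - 180) < 1e-9))
})

test_that("oscillation-off preset yields a monotone trace with no true peaks", {
  p <- pulsation_preset(amplitude = 0, n_cells = 2, n_cycles_total = 6,
                        contraction_rate = 5e-5)
  sim <- simulate_amnioserosa_traces(p, seed = 1)
  expect_null(sim$truth)
  tr <- sim$traces[sim$traces$cell_id == 1, ]
  expect_true(all(diff(tr$area_um2) < 0))
})

test_that("wild-type preset truth pools 85 cycles with mean near 191 s", {
  sim <- simulate_amnioserosa_traces(preset_pulsation("wt"), seed = 1)
  gaps <- unlist(tapply(sim$truth$peak_time_s, sim$truth$cell_id, diff))
  expect_length(gaps, 85)
  se <- 77 / sqrt(85)
  expect_lt(abs(mean(gaps) - 191), 2 * se)
})

test_that("detected peaks match generator truth and recover the mean period", {
  # detector recovery across seeds: >= 90% of true peaks found within one
  # frame interval, and the pooled mean period tracks the true gap mean
  for (seed in c(1, 5, 9)) {
    sim <- simulate_amnioserosa_traces(preset_pulsation("wt"), seed = seed)
    match_rates <- vapply(split(sim$traces, sim$traces$cell_id),
                          function(tr) {
      d <- detect_pulses(tr$t_s, tr$area_um2)
      tp <- sim$truth$peak_time_s[sim$truth$cell_id == tr$cell_id[1]]
      mean(vapply(tp, function(p) any(abs(d$peak_times - p) <= 10),
                  logical(1)))
    }, numeric(1))
    expect_gt(mean(match_rates), 0.9)
    ps <- summarize_pulsation(sim)
    true_gaps <- unlist(tapply(sim$truth$peak_time_s, sim$truth$cell_id,
                               diff))
    expect_lt(abs(ps$period_mean - mean(true_gaps)), 10)
  }
})

test_that("pulsation summaries follow their closed forms", {
  # single cell with exact 180 s gaps (4 interior peaks -> 3 gaps)
  t <- seq(0, 790, by = 10)
  a <- 100 + 20 * cos(2 * pi * t / 180)
  s1 <- summarize_pulsation(data.frame(cell_id = 1, t_s = t, area_um2 = a))
  expect_equal(s1$n_periods, 3)
  expect_equal(s1$period_mean, 180, tolerance = 0.06)
  expect_lt(s1$period_sd, 1e-9)
  expect_gte(s1$maxima_mean, s1$minima_mean)
  # hand-computed sample sd for gaps {160, 200}
  expect_equal(stats::sd(c(160, 200)), 28.28427, tolerance = 1e-6)
  # flat traces: flagged summary with n = 0
  s0 <- summarize_pulsation(data.frame(cell_id = 1, t_s = t,
                                       area_um2 = rep(100, length(t))))
  expect_true(s0$no_pulses)
  expect_equal(s0$n_periods, 0)
})

test_that("tissue contraction reproduces known decay curves", {
  t <- seq(0, 1000, by = 10)
  traces <- do.call(rbind, lapply(1:5, function(i)
    data.frame(cell_id = i, t_s = t, area_um2 = 100 * (1 - 0.0005 * t))))
  tc <- tissue_contraction(traces, n_bins = 10)
  expect_equal(nrow(tc), 10)
  expect_lt(abs(tc$mean_norm_area[10] - 0.5) , 0.03)
  expect_true(all(tc$sd_norm_area < 1e-12))
  expect_true(all(diff(tc$mean_norm_area) < 0))
  # contraction off: flat at 1
  flat <- do.call(rbind, lapply(1:3, function(i)
    data.frame(cell_id = i, t_s = t, area_um2 = rep(80, length(t)))))
  tcf <- tissue_contraction(flat, n_bins = 5)
  expect_true(all(abs(tcf$mean_norm_area - 1) < 1e-12))
  expect_error(tissue_contraction(traces[traces$cell_id == 1, ]),
               "2 cells")
})

test_that("a pulsatile preset with 30% net contraction ends near 0.7", {
  p <- pulsation_preset(period_mean = 191, period_sd = 77,
                        amplitude = 0.1, n_cells = 20,
                        n_cycles_total = 120, contraction_rate = 2e-4)
  sim <- simulate_amnioserosa_traces(p, seed = 2)
  tc <- tissue_contraction(sim$traces, n_bins = 10)
  # shortest traces end around 1500 s: compare the bin at ~1400-1500 s
  expected <- 1 - 2e-4 * tc$t_mid_s[10]
  expect_lt(abs(tc$mean_norm_area[10] - expected),
            2 * tc$sd_norm_area[10] / sqrt(max(tc$n_cells[10], 1)) + 0.05)
})
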