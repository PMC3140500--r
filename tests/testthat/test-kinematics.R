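test_that("fit_velocity recovers an exactly linear height decay", {
  t <- seq(0, 6000, by = 300)
  fr <- data.frame(frame = seq_along(t), t_s = t, W_um = 240,
                   H_um = 60 - 0.008 * t,
                   theta_rad = 2 * atan((60 - 0.008 * t) / 240),
                   closed = FALSE)
  vf <- fit_velocity(as_traj(fr))
  expect_equal(vf$v, 0.008, tolerance = 1e-12)
  expect_lt(vf$rms, 1e-10)
})

test_that("constant height yields v = 0 with a warning", {
  t <- seq(0, 6000, by = 300)
  fr <- data.frame(frame = seq_along(t), t_s = t, W_um = 240, H_um = 50,
                   theta_rad = 2 * atan(50 / 240), closed = FALSE)
  # window needs H < 0.9*Hmax; constant H means no early exclusion applies
  fr$H_um <- fr$H_um + c(10, rep(0, length(t) - 1))  # one high first frame
  expect_warning(vf <- fit_velocity(as_traj(fr)), "non-negative")
  expect_equal(vf$v, 0, tolerance = 1e-12)
  expect_true(vf$slope_nonnegative)
})

test_that("too few usable frames is a fit failure", {
  fr <- data.frame(frame = 1:3, t_s = c(0, 300, 600), W_um = 240,
                   H_um = c(50, 45, 40), theta_rad = 0.4, closed = FALSE)
  expect_error(fit_velocity(as_traj(fr)), "fewer than 4")
})

test_that("fit_zipping matches theory and a brute-force grid oracle", {
  traj <- simulate_closure_trajectory(
    closure_params(0.008, 0.004, 60, 240, frame_interval = 300))
  zf <- fit_zipping(traj)
  expect_equal(zf$k_z, 0.004, tolerance = 0.02)
  expect_gt(zf$r_squared, 0.99)
  k_grid <- kz_grid_oracle(traj)
  expect_lt(abs(zf$k_z - k_grid), 1e-5 + 1e-12)
})

test_that("fit_zipping returns ~0 for a zipping-free trajectory", {
  traj <- simulate_closure_trajectory(
    closure_params(0.008, 0, 60, 240, frame_interval = 300))
  zf <- fit_zipping(traj)
  expect_lt(abs(zf$k_z), 1e-6)
})

test_that("flat-arc trajectories are rejected by fit_zipping", {
  fr <- data.frame(frame = 1:10, t_s = seq(0, 2700, by = 300), W_um = 240,
                   H_um = seq(5, 2.5, length.out = 10),
                   theta_rad = 2 * atan(seq(5, 2.5, length.out = 10) / 240),
                   closed = FALSE)
  expect_error(fit_zipping(as_traj(fr)), "flat-arc")
})

test_that("compute_fz follows its closed forms and scale invariance", {
  expect_equal(compute_fz(0.008, 0)$f_z, 0)
  expect_equal(compute_fz(0.008, 0.008)$f_z, 1)
  expect_equal(compute_fz(0.008, 0.004)$f_z, 0.5)
  expect_error(compute_fz(0, 0.004), "undefined")
  # over-unity ratios are clipped with the raw value retained
  over <- compute_fz(0.004, 0.006)
  expect_equal(over$f_z, 1)
  expect_equal(over$f_z_raw, 1.5)
  # multiplying both rates by any c > 0 leaves f_z unchanged
  for (c_scale in c(0.1, 1, 17.3)) {
    expect_equal(compute_fz(0.008 * c_scale, 0.0035 * c_scale)$f_z,
                 compute_fz(0.008, 0.0035)$f_z, tolerance = 1e-12)
  }
})

test_that("phenotype classification separates normal, Group I and Group II", {
  rp <- render_params(noise_sd = 0.02)
  sim_one <- function(v, k_z, H0, W0, seed) {
    traj <- simulate_closure_trajectory(
      closure_params(v, k_z, H0, W0, frame_interval = 600))
    suppressWarnings(measure_stack(render_closure_movie(traj, rp,
                                                        seed = seed)))
  }
  refs <- lapply(1:3, function(i) sim_one(0.008, 0.004, 60, 240, i))
  fits <- lapply(refs, fit_closure)
  ref <- build_reference(refs, fits)

  wt <- sim_one(0.008, 0.004, 60, 240, 11)
  call_wt <- classify_phenotype(wt, fit_closure(wt), ref)
  expect_equal(call_wt$group, "normal")

  # 4-fold reduced zipping: low f_z and a narrowed (low-aspect) hole
  arf <- sim_one(0.008, 0.001, 60, 240, 12)
  call_arf <- classify_phenotype(arf, fit_closure(arf), ref)
  expect_equal(call_arf$group, "group_II")
  expect_true(all(c("low_fz", "narrowed") %in% call_arf$flags))

  # round hole: circularity flag
  pbl <- sim_one(0.008, 0.004, 70, 80, 13)
  call_pbl <- classify_phenotype(pbl, fit_closure(pbl), ref)
  expect_equal(call_pbl$group, "group_II")
  expect_true("circular_hole" %in% call_pbl$flags)

  # a stalled hole that is still clearly open at movie end is Group I
  stall <- sim_one(0.0008, 0, 60, 240, 14)
  call_st <- classify_phenotype(stall, NULL, ref)
  expect_equal(call_st$group, "group_I")
  expect_equal(call_st$flags, "not_closed")

  expect_error(classify_phenotype(wt, NULL, NULL), "reference")
})

test_that("round-trip recovery holds across the (v, k_z) grid", {
  # noiseless renders: v and k_z within 5%
  for (v in c(0.004, 0.016)) for (r in c(0.25, 0.5)) {
    k_z <- v * r
    traj <- simulate_closure_trajectory(
      closure_params(v, k_z, 60, 240, frame_interval = 240))
    mv <- render_closure_movie(traj, render_params(noise_sd = 0), seed = 1)
    fit <- fit_closure(suppressWarnings(measure_stack(mv)))
    expect_lt(abs(fit$v - v) / v, 0.05)
    expect_lt(abs(fit$k_z - k_z) / k_z, 0.05)
  }
})
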