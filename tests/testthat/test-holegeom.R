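test_that("rectangle mask extents follow the pixel-extent convention", {
  m <- matrix(FALSE, 200, 400)
  m[61:140, 41:360] <- TRUE  # 80 x 320 px
  g <- measure_hole(m, 0.5)
  expect_equal(g$W_um, 160)
  expect_equal(g$H_um, 40)
  expect_equal(g$theta_rad, 2 * atan(0.25))
  expect_equal(g$area_um2, 80 * 320 * 0.25)
  # canthus plateau midpoint: vertical runs resolve to their centre
  expect_equal(g$canthus_left_y, (60 + 139) / 2)
})

test_that("a square mask gives theta = pi/2", {
  m <- matrix(FALSE, 120, 120)
  m[21:100, 21:100] <- TRUE
  g <- measure_hole(m, 1)
  expect_equal(g$theta_rad, pi / 2)
})

test_that("an empty mask reports a closed hole", {
  g <- measure_hole(matrix(FALSE, 50, 50), 0.5)
  expect_true(g$closed)
  expect_equal(g$W_um, 0)
  expect_equal(g$H_um, 0)
})

test_that("noiseless render measures within 1 px of generator truth", {
  # shallow, screen-like holes: the regime of the kinematic grid
  for (wh in list(c(160, 40), c(240, 60), c(200, 30))) {
    mv <- render_closure_movie(frame_traj(wh[1], wh[2]),
                               render_params(um_per_px = 0.5, noise_sd = 0))
    meas <- measure_stack(mv)
    expect_lt(abs(meas$frames$W_um - wh[1]) / 0.5, 1.001,
              label = sprintf("W error for %dx%d", wh[1], wh[2]))
    expect_lt(abs(meas$frames$H_um - wh[2]) / 0.5, 1.001,
              label = sprintf("H error for %dx%d", wh[1], wh[2]))
  }
  # steep, near-circular holes carry about a pixel more width uncertainty
  # at the canthi; they only feed shape metrics, not the kinematic fits
  for (wh in list(c(100, 60), c(80, 70))) {
    mv <- render_closure_movie(frame_traj(wh[1], wh[2]),
                               render_params(um_per_px = 0.5, noise_sd = 0))
    meas <- measure_stack(mv)
    expect_lt(abs(meas$frames$W_um - wh[1]) / 0.5, 2,
              label = sprintf("W error for %dx%d", wh[1], wh[2]))
    expect_lt(abs(meas$frames$H_um - wh[2]) / 0.5, 1.001,
              label = sprintf("H error for %dx%d", wh[1], wh[2]))
  }
})

test_that("mask area matches the true arc-bounded area within 3%", {
  mv <- render_closure_movie(frame_traj(160, 40),
                             render_params(um_per_px = 0.5, noise_sd = 0))
  seg <- segment_hole(mv$frames[[1]], 0.5)
  g <- measure_hole(seg$mask, 0.5, edge_halfwidth_px = seg$edge_halfwidth_px,
                    closing_radius_px = seg$closing_radius_px)
  W <- 160; s <- 20
  R <- ((W / 2)^2 + s^2) / (2 * s)
  al <- asin((W / 2) / R)
  lens <- 2 * R^2 * (al - sin(al) * cos(al))
  expect_lt(abs(g$area_um2 - lens) / lens, 0.03)
})

test_that("measured noisy frames stay within 2 px of truth on average", {
  traj <- simulate_closure_trajectory(
    closure_params(0.008, 0.004, 60, 240, frame_interval = 240))
  mv <- render_closure_movie(traj, render_params(noise_sd = 0.08), seed = 5)
  meas <- suppressWarnings(measure_stack(mv))
  fr <- meas$frames[meas$frames$reliable & !meas$frames$closed, ]
  tru <- traj$frames[match(fr$frame, traj$frames$frame), ]
  expect_lt(mean(abs(fr$W_um - tru$W_um)) / 0.5, 2)
  expect_lt(mean(abs(fr$H_um - tru$H_um)) / 0.5, 2)
})

test_that("pure-noise frames raise a 'no signal' error distinct from closed", {
  set.seed(99)
  noise <- matrix(stats::rnorm(100 * 100, 0.1, 0.02), 100, 100)
  expect_error(segment_hole(noise, 0.5), class = "closuredyn_no_signal")
  # a rendered closed frame is NOT an error: empty mask, closed flag
  traj <- frame_traj(160, 40)
  traj$frames$closed <- TRUE
  mv <- render_closure_movie(traj, render_params(noise_sd = 0.02), seed = 2)
  seg <- segment_hole(mv$frames[[1]], 0.5)
  expect_true(seg$closed)
  expect_false(any(seg$mask))
})

test_that("segmentation is invariant to affine intensity rescaling", {
  mv <- render_closure_movie(frame_traj(160, 40),
                             render_params(noise_sd = 0.02), seed = 3)
  img <- mv$frames[[1]]
  seg1 <- segment_hole(img, 0.5)
  seg2 <- segment_hole(0.5 * img + 0.12, 0.5)
  expect_identical(seg1$mask, seg2$mask)
  g1 <- measure_hole(seg1$mask, 0.5, edge_halfwidth_px = seg1$edge_halfwidth_px)
  g2 <- measure_hole(seg2$mask, 0.5, edge_halfwidth_px = seg2$edge_halfwidth_px)
  expect_equal(g1$W_um, g2$W_um)
  expect_equal(g1$H_um, g2$H_um)
})

test_that("disc masks are circular and symmetric; flat-bottomed masks are not", {
  m <- disc_mask(40)
  sm <- shape_metrics(m, um_per_px = 1)
  expect_gt(sm$circularity, 0.95)
  expect_lt(sm$asymmetry, 0.02)
  expect_lt(sm$eccentricity, 0.2)
  # two-arc lens with H/W = 0.25 is strongly elongated
  mv <- render_closure_movie(frame_traj(160, 40),
                             render_params(um_per_px = 0.5, noise_sd = 0))
  seg <- segment_hole(mv$frames[[1]], 0.5)
  sm2 <- shape_metrics(seg$mask, um_per_px = 0.5)
  expect_gt(sm2$eccentricity, 0.9)
  # flatten the lower half: asymmetry exceeds 0.2
  half <- m
  ctr <- (nrow(m) + 1) / 2
  half[(ctr + 8):nrow(m), ] <- FALSE
  canthi <- c(10, ctr - 1, 90, ctr - 1)
  sm3 <- shape_metrics(half, canthi = canthi, um_per_px = 1)
  expect_gt(sm3$asymmetry, 0.2)
})

test_that("masks touching the border are rejected by shape_metrics", {
  m <- matrix(FALSE, 50, 50)
  m[1:30, 10:40] <- TRUE
  expect_error(shape_metrics(m, um_per_px = 1), "border")
})

test_that("geometry tables survive a CSV round trip", {
  traj <- simulate_closure_trajectory(
    closure_params(0.008, 0.004, 30, 120, frame_interval = 1200,
                   duration = 3600))
  mv <- render_closure_movie(traj, render_params(noise_sd = 0.02), seed = 1)
  meas <- measure_stack(mv)
  path <- tempfile(fileext = ".csv")
  write_geometry_csv(meas, path)
  back <- read_geometry_csv(path, um_per_px = 0.5, frame_interval = 1200)
  expect_equal(back$frames$W_um, meas$frames$W_um)
  expect_equal(back$frames$closed, meas$frames$closed)
})
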