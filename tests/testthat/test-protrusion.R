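test_that("a flat baseline is recovered within a pixel", {
  fr <- render_protrusion_frame(numeric(0), numeric(0), baseline_row = 100,
                                height_px = 150, seed = 1)
  bl <- extract_edge_baseline(fr$image)
  expect_true(all(abs(bl$baseline - 100) <= 1))
})

test_that("the baseline is robust to a lamellipodium sitting on it", {
  fr <- render_protrusion_frame(numeric(0), 20, baseline_row = 110,
                                seed = 2)
  bl <- extract_edge_baseline(fr$image)
  cols <- round(fr$truth$x_px) + seq(-15, 15)
  expect_true(all(abs(bl$baseline[cols] - 110) <= 2))
})

test_that("a blank image has no dominant edge", {
  set.seed(1)
  img <- matrix(stats::rnorm(100 * 200, 0.05, 0.01), 100, 200)
  expect_error(extract_edge_baseline(img), "no dominant edge")
})

test_that("a single straight spur measures its drawn length", {
  # 5 um = 20 px at 0.25 um/px, near-vertical
  for (sd in 1:50) {
    fr <- render_protrusion_frame(5, numeric(0), seed = sd)
    if (abs(fr$truth$angle_rad[1]) < 0.1) break
  }
  lens <- measure_filopodia(fr$image)
  expect_length(lens, 1)
  expect_lt(abs(lens - 5), 0.25)
})

test_that("angled spurs measure within 10% (diagonal geometry)", {
  # find a ~45-degree spur of axial length 10*sqrt(2)*0.25 um = 3.54 um
  L <- 10 * sqrt(2) * 0.25
  for (sd in 1:300) {
    fr <- render_protrusion_frame(L, numeric(0), seed = sd)
    if (abs(abs(fr$truth$angle_rad[1]) - pi / 4) < 0.05) break
  }
  lens <- measure_filopodia(fr$image)
  expect_length(lens, 1)
  expect_lt(abs(lens - L) / L, 0.1)
})

test_that("a half-disc flap measures its closed-form area", {
  # half-disc of radius 10 px: area pi*100/2 px^2 = 9.82 um^2 at 0.25 um/px
  A <- pi * 100 / 2 * 0.0625
  fr <- render_protrusion_frame(numeric(0), A, seed = 5)
  # force the half-disc aspect: rendered as half-ellipse with k ~ U(0.5,0.9);
  # tolerance covers the rasterized truth
  areas <- measure_lamellipodia(fr$image)
  expect_length(areas, 1)
  expect_lt(abs(areas - fr$truth$value) / fr$truth$value, 0.08)
})

test_that("an empty frame yields an empty protrusion list", {
  fr <- render_protrusion_frame(numeric(0), numeric(0), seed = 1)
  m <- measure_protrusions(fr$image)
  expect_equal(nrow(m), 0)
  expect_length(measure_filopodia(fr$image), 0)
  expect_length(measure_lamellipodia(fr$image), 0)
})

test_that("every beyond-baseline component gets exactly one type", {
  sim <- simulate_protrusion_frames(preset_protrusion("wt"), seed = 2)
  for (fi in c(1, 5, 9)) {
    m <- measure_protrusions(sim$frames[[fi]])
    expect_true(all(m$type %in% c("filopodium", "lamellipodium")))
    expect_equal(nrow(m),
                 sum(m$type == "filopodium") +
                   sum(m$type == "lamellipodium"))
  }
})

test_that("measurements are invariant to intensity rescaling", {
  fr <- render_protrusion_frame(c(5, 4), 15, seed = 6)
  m1 <- measure_protrusions(fr$image)
  m2 <- measure_protrusions(0.4 * fr$image + 0.2)
  expect_equal(m1$value, m2$value)
  expect_equal(m1$type, m2$type)
})

test_that("wild-type preset objects are detected with >= 90% recall", {
  for (seed in c(1, 4)) {
    sim <- simulate_protrusion_frames(preset_protrusion("wt"), seed = seed)
    found <- 0L; total <- 0L
    for (fi in unique(sim$truth$frame)) {
      tru <- sim$truth[sim$truth$frame == fi, ]
      m <- measure_protrusions(sim$frames[[fi]])
      for (k in seq_len(nrow(tru))) {
        total <- total + 1L
        hit <- any(m$type == tru$type[k] &
                     abs(m$x_px - tru$x_px[k]) <= 12)
        found <- found + as.integer(hit)
      }
    }
    expect_gt(found / total, 0.9)
  }
})

test_that("preset recovery: filopodium and lamellipodium statistics", {
  sim <- simulate_protrusion_frames(preset_protrusion("wt"), seed = 1)
  ps <- summarize_protrusions(sim)
  tru_f <- sim$truth$value[sim$truth$type == "filopodium"]
  expect_lt(abs(ps$fil_mean - mean(tru_f)) / mean(tru_f), 0.1)
  lam <- sim$truth[sim$truth$type == "lamellipodium", ]
  lam_max <- tapply(lam$value, lam$frame, max)
  expect_lt(abs(ps$lam_max_mean - mean(lam_max)) / mean(lam_max), 0.15)
})
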