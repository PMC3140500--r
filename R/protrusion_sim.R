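#' Leading-edge protrusion presets
#'
#' Distributions of filopodium lengths and lamellipodium areas drawn at
#' the leading edge. The named presets encode the published morphometrics:
#' wild type filopodia 4.8 +/- 1.4 um (n = 58) and lamellipodium protrusive
#' area 14.5 +/- 4.0 um^2 (n = 13 frames); pbl mutant filopodia
#' 7.1 +/- 1.7 um (n = 52) and lamellipodia 26.6 +/- 7.3 um^2 (n = 12
#' frames). Lamellipodium n counts frames (the statistic is the per-frame
#' maximal protrusive area), so each synthetic frame carries one dominant
#' lamellipodium drawn from the preset distribution plus smaller ones.
#'
#' @param fil_mean,fil_sd filopodium length distribution, um (truncated at
#'   the minimum measurable length).
#' @param fil_n total number of filopodia across the frame set.
#' @param lam_mean,lam_sd dominant lamellipodium area distribution, um^2.
#' @param lam_n_frames number of frames (one dominant lamellipodium each).
#' @param fil_per_frame filopodia drawn per frame.
#' @param lam_extra_per_frame additional sub-dominant lamellipodia per frame.
#' @param um_per_px pixel size, um.
#' @return Object of class `protrusion_preset`.
#' @export
protrusion_preset <- function(fil_mean = 4.8, fil_sd = 1.4, fil_n = 58,
                              lam_mean = 14.5, lam_sd = 4.0,
                              lam_n_frames = 13, fil_per_frame = 6,
                              lam_extra_per_frame = 1, um_per_px = 0.25) {
  assert_number(fil_mean, "fil_mean", lower = 1e-9)
  assert_number(fil_sd, "fil_sd", lower = 0)
  assert_count(fil_n, "fil_n", 0L)
  assert_number(lam_mean, "lam_mean", lower = 1e-9)
  assert_number(lam_sd, "lam_sd", lower = 0)
  assert_count(lam_n_frames, "lam_n_frames", 0L)
  assert_count(fil_per_frame, "fil_per_frame", 1L)
  assert_count(lam_extra_per_frame, "lam_extra_per_frame", 0L)
  assert_number(um_per_px, "um_per_px", lower = 1e-9)
  structure(as.list(environment()), class = "protrusion_preset")
}

#' @rdname protrusion_preset
#' @param genotype `"wt"` or `"pbl"`.
#' @export
preset_protrusion <- function(genotype = c("wt", "pbl")) {
  switch(match.arg(genotype),
         wt = protrusion_preset(fil_mean = 4.8, fil_sd = 1.4, fil_n = 58,
                                lam_mean = 14.5, lam_sd = 4.0,
                                lam_n_frames = 13),
         pbl = protrusion_preset(fil_mean = 7.1, fil_sd = 1.7, fil_n = 52,
                                 lam_mean = 26.6, lam_sd = 7.3,
                                 lam_n_frames = 12))
}

# occupied-interval bookkeeping for non-overlapping placement along x
place_interval <- function(occupied, half_w, x_lo, x_hi, max_retry = 100L) {
  for (r in seq_len(max_retry)) {
    x0 <- stats::runif(1, x_lo + half_w, x_hi - half_w)
    if (!any(occupied$lo < x0 + half_w & occupied$hi > x0 - half_w))
      return(list(x0 = x0,
                  occupied = rbind(occupied,
                                   data.frame(lo = x0 - half_w,
                                              hi = x0 + half_w))))
  }
  stop("could not place protrusion without overlap (retry limit reached)")
}

#' Render one synthetic leading-edge frame
#'
#' Draws a bright horizontal leading-edge band, filopodia as 1-2 px wide
#' straight spurs at random angles within +/- 60 degrees of the edge
#' normal, and lamellipodia as convex half-ellipse flaps, all extending
#' beyond the edge (toward smaller row indices). Protrusion roots sit on
#' the dorsal face of the band so drawn lengths and areas are entirely
#' beyond the baseline envelope. Overlapping placements are re-drawn up to
#' a retry limit.
#'
#' @param fil_lengths_um filopodium lengths to draw, um.
#' @param lam_areas_um2 lamellipodium areas to draw, um^2.
#' @param um_per_px pixel size, um.
#' @param width_px,height_px frame size.
#' @param baseline_row row (0-based) of the leading-edge band center.
#' @param edge_thickness_px band thickness.
#' @param edge_intensity,background,noise_sd,psf_sigma_px optics/noise.
#' @param seed integer seed or `NULL`.
#' @return List: `image`, `truth` (data frame: `type`, `value` in um or
#'   um^2, `x_px`, `angle_rad`), geometry metadata.
#' @export
render_protrusion_frame <- function(fil_lengths_um, lam_areas_um2,
                                    um_per_px = 0.25, width_px = 640L,
                                    height_px = 160L, baseline_row = 110,
                                    edge_thickness_px = 3,
                                    edge_intensity = 0.8, background = 0.05,
                                    noise_sd = 0.01, psf_sigma_px = 1,
                                    seed = NULL) {
  with_seed(seed, {
    img <- matrix(0, height_px, width_px)
    # 0-based band rows; the band's dorsal face is at y_face
    band_lo <- ceiling(baseline_row - edge_thickness_px / 2 - 1e-9)
    band_hi <- floor(baseline_row + edge_thickness_px / 2 + 1e-9)
    img[(band_lo:band_hi) + 1L, ] <- edge_intensity
    y_face <- band_lo - 0.5
    occupied <- data.frame(lo = numeric(0), hi = numeric(0))
    truth <- list()
    for (A in lam_areas_um2) {
      A_px <- A / um_per_px^2
      k <- stats::runif(1, 0.5, 0.9)
      a <- sqrt(2 * A_px / (pi * k))
      b <- k * a
      pl <- place_interval(occupied, a + 3, 0, width_px - 1)
      occupied <- pl$occupied
      x0 <- pl$x0
      drawn <- 0L
      for (x in max(0, floor(x0 - a)):min(width_px - 1, ceiling(x0 + a))) {
        dx <- (x - x0) / a
        if (abs(dx) > 1) next
        yr <- b * sqrt(1 - dx^2)
        top <- ceiling(y_face - yr)
        if (top > band_lo - 1L) next
        rows <- seq(max(0L, top), band_lo - 1L)
        img[rows + 1L, x + 1L] <- edge_intensity
        drawn <- drawn + length(rows)
      }
      truth[[length(truth) + 1L]] <-
        data.frame(type = "lamellipodium", value = drawn * um_per_px^2,
                   x_px = x0, angle_rad = NA_real_)
    }
    for (L in fil_lengths_um) {
      L_px <- L / um_per_px
      phi <- stats::runif(1, -pi / 3, pi / 3)  # from the edge normal
      half_w <- abs(L_px * sin(phi)) / 2 + 3
      pl <- place_interval(occupied, half_w, 0, width_px - 1)
      occupied <- pl$occupied
      x0 <- pl$x0 - L_px * sin(phi) / 2  # root so the spur stays in its slot
      ss <- seq(0, L_px, by = 0.25)
      xs <- x0 + ss * sin(phi)
      ys <- y_face - ss * cos(phi)
      img <- stamp_points(img, xs, ys, 0.75, edge_intensity)
      truth[[length(truth) + 1L]] <-
        data.frame(type = "filopodium", value = L, x_px = x0,
                   angle_rad = phi)
    }
    if (psf_sigma_px > 0)
      img <- EBImage::filter2(img, gaussian_kernel(psf_sigma_px),
                              boundary = "replicate")
    img <- img + background
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(type = character(0), value = numeric(0),
                 x_px = numeric(0), angle_rad = numeric(0))
    list(image = matrix(pmin(pmax(img, 0), 1), height_px, width_px),
         truth = truth, um_per_px = um_per_px, baseline_row = baseline_row,
         edge_thickness_px = edge_thickness_px)
  })
}

#' Simulate a set of leading-edge frames from a protrusion preset
#'
#' Distributes `fil_n` filopodia over `max(lam_n_frames,
#' ceiling(fil_n / fil_per_frame))` frames; each of the first
#' `lam_n_frames` frames carries one dominant lamellipodium drawn from the
#' preset area distribution plus `lam_extra_per_frame` sub-dominant ones at
#' 30-70% of the dominant area. Ground truth records every object.
#'
#' @param preset a [protrusion_preset()].
#' @param seed integer seed or `NULL`.
#' @param ... frame geometry/noise overrides passed to
#'   [render_protrusion_frame()].
#' @return Object of class `protrusion_sim`: `frames` (list of images),
#'   `truth` (data frame with `frame` column), and the preset.
#' @export
simulate_protrusion_frames <- function(preset = preset_protrusion("wt"),
                                       seed = NULL, ...) {
  stopifnot(inherits(preset, "protrusion_preset"))
  p <- preset
  n_frames <- max(p$lam_n_frames, ceiling(p$fil_n / p$fil_per_frame))
  with_seed(seed, {
    fil_left <- p$fil_n
    frames <- vector("list", n_frames)
    truths <- vector("list", n_frames)
    for (fi in seq_len(n_frames)) {
      nf <- min(p$fil_per_frame, fil_left)
      fil_left <- fil_left - nf
      lens <- if (nf > 0) rnorm_trunc(nf, p$fil_mean, p$fil_sd, 0.5) else
        numeric(0)
      areas <- numeric(0)
      if (fi <= p$lam_n_frames) {
        dom <- rnorm_trunc(1, p$lam_mean, p$lam_sd, 1)
        # sub-dominant flaps stay at >= half the dominant area: smaller
        # flaps are not resolvable against blurred spurs at this pixel size
        extra <- if (p$lam_extra_per_frame > 0)
          stats::runif(p$lam_extra_per_frame, 0.5, 0.8) * dom else numeric(0)
        areas <- c(dom, extra)
      }
      fr <- render_protrusion_frame(lens, areas, um_per_px = p$um_per_px,
                                    ...)
      frames[[fi]] <- fr$image
      if (nrow(fr$truth) > 0)
        truths[[fi]] <- cbind(frame = fi, fr$truth,
                              dominant = c(fr$truth$type == "lamellipodium" &
                                             seq_len(nrow(fr$truth)) == 1))
    }
    truth <- do.call(rbind, truths[!vapply(truths, is.null, logical(1))])
    rownames(truth) <- NULL
    structure(list(frames = frames, truth = truth, preset = p,
                   um_per_px = p$um_per_px), class = "protrusion_sim")
  })
}
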