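#' Segment the dorsal hole from a leading-edge frame
#'
#' The bright leading edge is isolated by Gaussian smoothing and Otsu
#' thresholding, morphologically closed to seal the canthi, and the hole is
#' taken as the largest background component fully enclosed by edge pixels
#' (i.e. not touching the image border). An empty hole mask means the hole
#' has closed; a frame with no detectable edge signal raises a "no signal"
#' error (condition class `closuredyn_no_signal`), which is distinct from a
#' closed hole.
#'
#' @param frame single-channel intensity matrix.
#' @param um_per_px pixel size, um.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param min_snr minimum (peak - median) / mad contrast required to accept
#'   that the frame contains signal.
#' @param closing_brush diameter (px, odd) of the disc used to
#'   morphologically close the edge and seal the canthi.
#' @param min_obj_px bright components smaller than this are treated as
#'   noise speckle and removed before closing.
#' @return List with `mask` (logical matrix), `edge` (logical matrix),
#'   `edge_halfwidth_px` (estimated half-thickness of the segmented edge
#'   band, used to correct extents to the arc centerline),
#'   `closing_radius_px`, `threshold`, and `closed`.
#' @export
segment_hole <- function(frame, um_per_px, smooth_sigma = 1, min_snr = 5,
                         closing_brush = 5, min_obj_px = 50) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  assert_number(um_per_px, "um_per_px", lower = 1e-9)
  sm <- if (smooth_sigma > 0)
    EBImage::filter2(frame, gaussian_kernel(smooth_sigma),
                     boundary = "replicate") else frame
  med <- stats::median(sm)
  noise <- stats::mad(sm)
  if (noise < 1e-12) noise <- 1e-12
  if ((max(sm) - med) / noise < min_snr)
    stop(structure(class = c("closuredyn_no_signal", "error", "condition"),
                   list(message = "no signal: no bright leading edge detected above background",
                        call = sys.call())))
  rng <- range(sm)
  smn <- (sm - rng[1]) / max(rng[2] - rng[1], 1e-12)
  thr <- EBImage::otsu(EBImage::Image(smn))
  edge <- smn > thr
  # drop speckle: noise pixels above threshold inside the hole fragment
  # the background component near the canthi
  el <- EBImage::bwlabel(EBImage::Image(edge * 1))
  el <- as.integer(el); dim(el) <- dim(frame)
  if (max(el) > 1L) {
    sizes <- tabulate(el[el > 0L])
    edge <- matrix(el %in% which(sizes >= min_obj_px), nrow(frame))
  }
  edge_closed <- EBImage::closing(EBImage::Image(edge * 1),
                                  EBImage::makeBrush(closing_brush,
                                                     "disc")) > 0.5
  bg <- EBImage::bwlabel(EBImage::Image((!edge_closed) * 1))
  labs <- as.integer(bg)
  dim(labs) <- dim(frame)
  border_labs <- unique(c(labs[1, ], labs[nrow(labs), ],
                          labs[, 1], labs[, ncol(labs)]))
  inner <- setdiff(setdiff(unique(as.vector(labs)), 0L), border_labs)
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  if (length(inner) > 0L) {
    sizes <- tabulate(labs[labs %in% inner], nbins = max(inner))
    best <- which.max(sizes)
    mask <- labs == best
  }
  hw <- estimate_edge_halfwidth(edge_closed, mask)
  # x-extent of the largest edge component: the band ends sit at the canthi
  el2 <- EBImage::bwlabel(EBImage::Image(edge_closed * 1))
  el2 <- as.integer(el2); dim(el2) <- dim(frame)
  edge_extent <- 0
  edge_cols <- integer(0)
  if (max(el2) > 0L) {
    big <- which.max(tabulate(el2[el2 > 0L]))
    edge_cols <- which(colSums(el2 == big) > 0)
    edge_extent <- diff(range(edge_cols)) + 1
  }
  list(mask = mask, edge = edge_closed, edge_halfwidth_px = hw,
       closing_radius_px = closing_brush / 2,
       edge_extent_px = edge_extent,
       edge_col_range = if (length(edge_cols)) range(edge_cols) - 1L else
         c(NA_integer_, NA_integer_),
       threshold = thr * (rng[2] - rng[1]) + rng[1],
       closed = !any(mask))
}

# Median per-column edge thickness across the middle of the hole span; each
# such column crosses both arcs, so half-thickness is count/4.
estimate_edge_halfwidth <- function(edge, mask) {
  if (!any(mask)) {
    cols <- which(colSums(edge) > 0)
    if (length(cols) == 0L) return(0)
    counts <- colSums(edge[, cols, drop = FALSE])
    return(stats::median(counts) / 2)
  }
  cols <- range(which(colSums(mask) > 0))
  span <- cols[2] - cols[1]
  sel <- seq(cols[1] + round(0.25 * span), cols[1] + round(0.75 * span))
  counts <- colSums(edge[, sel, drop = FALSE])
  stats::median(counts) / 4
}

#' Measure dorsal-hole geometry from a segmented mask
#'
#' Width `W` is the maximal extent of the mask along the anterior-posterior
#' (x) axis, height `H` the maximal extent along the dorsoventral (y) axis,
#' using the pixel-extent convention `max index - min index + 1`. The canthi
#' are the extremal mask points along x (plateaus resolved to their midpoint
#' pixel). The canthus angle is derived from the arc relation
#' `theta = 2*atan(H/W)`. When the segmented edge band half-width is
#' supplied, extents and area are corrected from the mask (inner) boundary
#' to the arc centerline.
#'
#' Near the canthi the two arcs converge at the canthus angle, so the
#' segmented interior ends where a disc of the closing radius still fits
#' between the two edge bands; the width correction per side follows from
#' the intersection of the arc circles offset inward by
#' `halfwidth + closing_radius` (solved by fixed-point iteration, capped
#' at a quarter of the raw extent on near-degenerate flat arcs).
#'
#' @param mask logical hole mask.
#' @param um_per_px pixel size, um.
#' @param t frame time, s.
#' @param edge_halfwidth_px half-thickness of the bounding edge band, px.
#' @param closing_radius_px half the diameter of the structuring element
#'   used to close the edge during segmentation, px.
#' @return One-row data frame of class `hole_geometry`: `t_s`, `W_um`,
#'   `H_um`, `theta_rad`, `area_um2`, canthus pixel coordinates (0-based),
#'   `closed`.
#' @export
measure_hole <- function(mask, um_per_px, t = NA_real_,
                         edge_halfwidth_px = 0, closing_radius_px = 0) {
  stopifnot(is.matrix(mask), is.logical(mask))
  assert_number(um_per_px, "um_per_px", lower = 1e-9)
  hw <- edge_halfwidth_px
  if (!any(mask)) {
    out <- data.frame(t_s = t, W_um = 0, H_um = 0, theta_rad = 0,
                      area_um2 = 0, canthus_left_x = NA_real_,
                      canthus_left_y = NA_real_, canthus_right_x = NA_real_,
                      canthus_right_y = NA_real_, closed = TRUE,
                      reliable = TRUE)
    class(out) <- c("hole_geometry", class(out))
    return(out)
  }
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1] - 1L  # 0-based
  xs <- idx[, 2] - 1L
  ext_W <- diff(range(xs)) + 1
  # +0.5: the threshold crossing sits half a pixel beyond the outermost
  # interior pixel on each side (validated on noiseless renders)
  H_px <- diff(range(ys)) + 1 + 2 * (hw + if (hw > 0) 0.5 else 0)
  # Canthus correction: the interior mask ends where a disc of the closing
  # radius still fits between the two edge bands, i.e. at the intersection
  # of the arc circles offset inward by (halfwidth + closing radius), plus
  # the closing radius itself. Fixed-point iteration on W; the correction
  # is capped at a quarter of the raw extent for near-degenerate flat arcs.
  off <- hw + closing_radius_px
  W_px <- ext_W + 2 * hw
  if (off > 0) {
    for (it in 1:3) {
      w_half <- W_px / 2
      s <- H_px / 2
      R <- (w_half^2 + s^2) / (2 * s)
      x_off <- sqrt(max((R - off)^2 - (R - s)^2, 0)) + closing_radius_px
      corr <- min(max(w_half - x_off, 0), 0.25 * ext_W)
      W_px <- ext_W + 2 * corr
    }
  }
  # plateau of extremal x: take the midpoint of the pixel run
  canthus_y <- function(at_x) {
    yy <- ys[xs == at_x]
    (min(yy) + max(yy)) / 2
  }
  side <- (W_px - ext_W) / 2
  cl <- c(min(xs) - side, canthus_y(min(xs)))
  cr <- c(max(xs) + side, canthus_y(max(xs)))
  perim <- mask_perimeter(mask)
  area_px <- nrow(idx) + perim * hw + pi * hw^2
  W <- W_px * um_per_px
  H <- H_px * um_per_px
  # a slit whose height is within ~4x the band + closing scale cannot be
  # segmented accurately (the blurred bands invade the interior wedge);
  # flag so fits can exclude such terminal frames
  reliable <- off <= 0 || H_px >= 4 * off
  out <- data.frame(t_s = t, W_um = W, H_um = H,
                    theta_rad = 2 * atan(H / W),
                    area_um2 = area_px * um_per_px^2,
                    canthus_left_x = cl[1], canthus_left_y = cl[2],
                    canthus_right_x = cr[1], canthus_right_y = cr[2],
                    closed = FALSE, reliable = reliable)
  class(out) <- c("hole_geometry", class(out))
  out
}

# Contour perimeter by boundary tracing. Raw chain length (1 / sqrt(2)
# steps) overestimates smooth digital boundaries by up to ~8%, so the
# standard Kulpa weights (0.948 axial, 1.340 diagonal) are used.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) return(0)
  per <- 0
  for (ct in oc) {
    if (nrow(ct) < 2L) next
    st <- abs(ct - ct[c(2:nrow(ct), 1), , drop = FALSE])
    diag <- st[, 1] > 0 & st[, 2] > 0
    per <- per + 0.948 * sum(!diag) + 1.340 * sum(diag)
  }
  per
}

#' Shape metrics of a hole mask
#'
#' Computes aspect ratio H/W, circularity `4*pi*area/perimeter^2`
#' (contour-traced perimeter), eccentricity of the moment-equivalent
#' ellipse, and an asymmetry index: the absolute difference between mask
#' area dorsal and ventral of the line through the two canthi, as a
#' fraction of total area. A mask touching the image border (truncated
#' hole) is an error.
#'
#' @param mask logical hole mask (non-empty).
#' @param canthi numeric length-4 vector or 2x2 matrix of the two canthus
#'   points (x, y), 0-based pixel coordinates; defaults to the extremal
#'   points of the mask.
#' @param um_per_px pixel size, um.
#' @return One-row data frame: `aspect`, `circularity`, `eccentricity`,
#'   `asymmetry`.
#' @export
shape_metrics <- function(mask, canthi = NULL, um_per_px = 1) {
  stopifnot(is.matrix(mask), is.logical(mask), any(mask))
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("hole mask touches the image border (truncated hole)")
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1] - 1; xs <- idx[, 2] - 1
  if (is.null(canthi)) {
    g <- measure_hole(mask, um_per_px)
    canthi <- c(g$canthus_left_x, g$canthus_left_y,
                g$canthus_right_x, g$canthus_right_y)
  }
  canthi <- as.numeric(canthi)
  area <- length(xs)
  per <- mask_perimeter(mask)
  circ <- min(1, 4 * pi * area / per^2)
  cv <- stats::cov(cbind(xs, ys)) + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE)$values
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  line_y <- (canthi[2] + canthi[4]) / 2
  above <- sum(ys < line_y - 1e-9)
  below <- sum(ys > line_y + 1e-9)
  asym <- abs(above - below) / area
  W <- (diff(range(xs)) + 1) * um_per_px
  H <- (diff(range(ys)) + 1) * um_per_px
  data.frame(aspect = H / W, circularity = circ, eccentricity = ecc,
             asymmetry = asym)
}

#' Measure hole geometry across a movie
#'
#' Runs [segment_hole()] and [measure_hole()] (plus [shape_metrics()] on
#' open frames) on every frame of a stack. Frames whose hole touches the
#' image border are skipped with a warning rather than failing the movie.
#'
#' @param movie a `closure_movie`, a list of matrices, or a path to a
#'   multi-page TIFF.
#' @param um_per_px pixel size, um (taken from the movie object if present).
#' @param frame_interval frame interval, s (idem).
#' @param smooth_sigma smoothing sigma passed to [segment_hole()].
#' @return A measured `closure_trajectory` whose `frames` data frame also
#'   carries `area_um2`, `aspect`, `circularity`, `eccentricity`,
#'   `asymmetry` and the canthus coordinates.
#' @export
measure_stack <- function(movie, um_per_px = NULL, frame_interval = NULL,
                          smooth_sigma = 1) {
  if (is.character(movie)) movie <- read_movie_tiff(movie)
  if (inherits(movie, "closure_movie")) {
    if (is.null(um_per_px)) um_per_px <- movie$um_per_px
    if (is.null(frame_interval)) frame_interval <- movie$frame_interval
    movie <- movie$frames
  }
  if (is.null(um_per_px) || is.null(frame_interval))
    stop("um_per_px and frame_interval are required")
  segs <- lapply(movie, segment_hole, um_per_px = um_per_px,
                 smooth_sigma = smooth_sigma)
  # the band half-width is a property of the optics and label, constant
  # over a movie: pool the per-frame estimates to stabilize the canthus
  # correction against frame-to-frame quantization jitter
  hws <- vapply(segs, function(s)
    if (s$closed) NA_real_ else s$edge_halfwidth_px, numeric(1))
  hw_movie <- stats::median(hws, na.rm = TRUE)
  if (!is.finite(hw_movie)) hw_movie <- 0
  rows <- vector("list", length(movie))
  for (i in seq_along(movie)) {
    t <- (i - 1) * frame_interval
    seg <- segs[[i]]
    geom <- measure_hole(seg$mask, um_per_px, t = t,
                         edge_halfwidth_px = hw_movie,
                         closing_radius_px = seg$closing_radius_px)
    if (!geom$closed && seg$edge_extent_px > 0) {
      # Width from the ends of the leading-edge band itself ("maximal
      # distance between zippering ends"): unlike the interior extent,
      # its bias does not depend on the canthus angle. The band end is a
      # point-like cap whose threshold crossing sits inside the lateral
      # band half-width by about two-thirds of the blur sigma; the 1.2 px
      # end-cap calibration is validated on noiseless renders.
      cap <- max(hw_movie - 1.2, 0)
      W_edge <- (seg$edge_extent_px - 2 * cap) * um_per_px
      if (W_edge >= geom$W_um) {
        geom$W_um <- W_edge
        geom$theta_rad <- 2 * atan(geom$H_um / geom$W_um)
        geom$canthus_left_x <- seg$edge_col_range[1] + cap
        geom$canthus_right_x <- seg$edge_col_range[2] - cap
      }
    }
    if (!geom$closed) {
      sm <- tryCatch(
        shape_metrics(seg$mask,
                      canthi = c(geom$canthus_left_x, geom$canthus_left_y,
                                 geom$canthus_right_x, geom$canthus_right_y),
                      um_per_px = um_per_px),
        error = function(e) {
          warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(sm)) next
    } else {
      sm <- data.frame(aspect = NA_real_, circularity = NA_real_,
                       eccentricity = NA_real_, asymmetry = NA_real_)
    }
    rows[[i]] <- cbind(frame = i, geom[, c("t_s", "W_um", "H_um",
                                           "theta_rad", "area_um2")],
                       sm, geom[, c("canthus_left_x", "canthus_left_y",
                                    "canthus_right_x", "canthus_right_y",
                                    "closed", "reliable")])
  }
  frames <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(frames) <- NULL
  structure(list(frames = frames, um_per_px = um_per_px,
                 frame_interval = frame_interval, source = "measured"),
            class = "closure_trajectory")
}

#' Write / read per-frame geometry tables
#'
#' @param traj measured `closure_trajectory`.
#' @param path CSV path.
#' @return `path` (write) or a `closure_trajectory` (read).
#' @export
write_geometry_csv <- function(traj, path) {
  stopifnot(inherits(traj, "closure_trajectory"))
  utils::write.csv(traj$frames, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @param frame_interval,um_per_px acquisition metadata to attach on read.
#' @export
read_geometry_csv <- function(path, um_per_px = NA_real_,
                              frame_interval = NA_real_) {
  frames <- utils::read.csv(path)
  structure(list(frames = frames, um_per_px = um_per_px,
                 frame_interval = frame_interval, source = "measured"),
            class = "closure_trajectory")
}
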