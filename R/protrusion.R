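#' Extract the leading-edge baseline of a protrusion frame
#'
#' Per-column ridge position of the dominant bright edge band (median row
#' of above-threshold pixels), robustified with a cross-column running
#' median wide enough to ignore individual protrusions, then lightly
#' smoothed. Also estimates the band half-thickness and returns the
#' thresholded mask that [measure_protrusions()] works from.
#'
#' @param image intensity matrix.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param median_window running-median window, columns (odd).
#' @param min_snr contrast test as in [segment_hole()].
#' @return List: `baseline` (0-based row per column), `halfwidth_px`,
#'   `mask` (thresholded image), `threshold`.
#' @export
extract_edge_baseline <- function(image, smooth_sigma = 1,
                                  median_window = 121, min_snr = 5) {
  stopifnot(is.matrix(image))
  sm <- if (smooth_sigma > 0)
    EBImage::filter2(image, gaussian_kernel(smooth_sigma),
                     boundary = "replicate") else image
  med <- stats::median(sm)
  noise <- max(stats::mad(sm), 1e-12)
  if ((max(sm) - med) / noise < min_snr)
    stop("no dominant edge detected in the frame")
  rng <- range(sm)
  smn <- (sm - rng[1]) / max(rng[2] - rng[1], 1e-12)
  thr <- EBImage::otsu(EBImage::Image(smn))
  bw <- smn > thr
  nc <- ncol(bw)
  ridge <- rep(NA_real_, nc)
  counts <- integer(nc)
  for (j in seq_len(nc)) {
    rows <- which(bw[, j])
    counts[j] <- length(rows)
    if (length(rows) > 0L) ridge[j] <- stats::median(rows) - 1  # 0-based
  }
  if (all(is.na(ridge))) stop("no dominant edge detected in the frame")
  ridge <- stats::approx(seq_len(nc), ridge, xout = seq_len(nc),
                         rule = 2)$y
  k <- min(median_window, nc - (1 - nc %% 2))
  if (k %% 2L == 0L) k <- k - 1L
  base <- stats::runmed(ridge, k, endrule = "median")
  base <- moving_average(base, 5L)
  halfwidth <- stats::median(counts[counts > 0]) / 2
  list(baseline = base, halfwidth_px = halfwidth, mask = bw,
       threshold = thr * (rng[2] - rng[1]) + rng[1])
}

# Zhang-Suen thinning of a logical matrix to a 1-px skeleton.
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  m <- pad
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      idx <- which(m, arr.ind = TRUE)
      idx <- idx[idx[, 1] > 1 & idx[, 1] < nrow(m) &
                   idx[, 2] > 1 & idx[, 2] < ncol(m), , drop = FALSE]
      if (nrow(idx) == 0L) break
      r <- idx[, 1]; c <- idx[, 2]
      p2 <- m[cbind(r - 1, c)];     p3 <- m[cbind(r - 1, c + 1)]
      p4 <- m[cbind(r, c + 1)];     p5 <- m[cbind(r + 1, c + 1)]
      p6 <- m[cbind(r + 1, c)];     p7 <- m[cbind(r + 1, c - 1)]
      p8 <- m[cbind(r, c - 1)];     p9 <- m[cbind(r - 1, c - 1)]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- rowSums(seqs[, 1:8, drop = FALSE] == 0 &
                     seqs[, 2:9, drop = FALSE] == 1)
      if (phase == 1L) {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[idx[cond, , drop = FALSE]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nr + 1L), 2:(nc + 1L)]
}

# Geodesic length over a skeleton: Dijkstra over 8-neighbors (diagonal
# steps count sqrt(2)) from the attachment pixel (largest row = closest to
# the baseline). Returns the largest finite distance (to the tip), the
# attachment and tip coordinates, and the straight chord between them.
skeleton_geodesic_length <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 1L) return(list(len = 0, chord = 0))
  key <- paste(pts[, 1], pts[, 2])
  id <- seq_len(n); names(id) <- key
  start <- which.max(pts[, 1])
  dist <- rep(Inf, n); dist[start] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0L) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      k <- paste(pts[u, 1] + dr, pts[u, 2] + dc)
      v <- id[k]
      if (is.na(v) || done[v]) next
      w <- if (dr != 0L && dc != 0L) sqrt(2) else 1
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  tip <- which.max(ifelse(is.finite(dist), dist, -Inf))
  list(len = max(dist[is.finite(dist)]),
       chord = sqrt(sum((pts[tip, ] - pts[start, ])^2)),
       from = pts[start, ], to = pts[tip, ])
}

#' Measure leading-edge protrusions in a frame
#'
#' Thresholded signal beyond the edge band (everything a morphological
#' opening with a long horizontal line removes) is labeled into
#' 8-connected components. Every component is assigned exactly one type by
#' its core width (maximal inscribed disc diameter minus the blur halo):
#' filopodium if at most `w_f` px, else lamellipodium. Filopodium length
#' is measured along the skeleton from the band-face attachment to the
#' geodesically farthest tip (diagonal steps sqrt(2) in the geodesic; the
#' reported length uses the attachment-tip chord since filopodia are
#' straight), in um; components shorter than `l_min` are dropped.
#' Lamellipodium area is the component pixel count times the pixel area.
#'
#' @param image intensity matrix.
#' @param baseline optional result of [extract_edge_baseline()]; computed
#'   if `NULL`.
#' @param um_per_px pixel size, um.
#' @param w_f width threshold separating filopodia from lamellipodia, px,
#'   applied to the halo-corrected (core) width.
#' @param l_min minimum filopodium length, um.
#' @param halo_px apparent widening of thresholded structures caused by
#'   the point-spread function plus measurement smoothing (roughly twice
#'   the combined blur sigma). Subtracted from apparent widths before
#'   classification, and used to anchor the protrusion envelope at the
#'   band's true face rather than its blurred threshold boundary.
#' @return Data frame: `type`, `value` (length um or area um^2), `x_px`
#'   (component centroid column, 0-based), `width_px` (core width).
#' @export
measure_protrusions <- function(image, baseline = NULL, um_per_px = 0.25,
                                w_f = 4, l_min = 1, halo_px = 2.8) {
  if (is.null(baseline)) baseline <- extract_edge_baseline(image)
  bw <- baseline$mask
  # The edge band is the only structure that survives opening with a
  # horizontal line longer than any single protrusion, so the beyond-
  # baseline signal is simply what the opening removes. This respects the
  # band's local blurred boundary, unlike a global half-width envelope.
  line <- matrix(1, nrow = 1, ncol = 63)
  band <- EBImage::opening(EBImage::Image(bw * 1), line) > 0.5
  beyond <- bw & !band
  # the blurred band top overstates the true face by about half the halo;
  # a filopodium root sits that far below the first beyond-band pixel
  root_gap <- halo_px / 2
  if (!any(beyond))
    return(data.frame(type = character(0), value = numeric(0),
                      x_px = numeric(0), width_px = numeric(0)))
  lab <- EBImage::bwlabel(EBImage::Image(beyond * 1))
  labs <- as.integer(lab); dim(labs) <- dim(beyond)
  out <- list()
  for (l in seq_len(max(labs))) {
    idx <- which(labs == l, arr.ind = TRUE)
    if (nrow(idx) < 4L) next
    sub <- labs[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
                drop = FALSE] == l
    area_px <- nrow(idx)
    skel <- skeletonize(sub)
    geo <- skeleton_geodesic_length(skel)
    glen <- geo$len
    # thinning erodes the skeleton ends; recover the eroded span from the
    # component's own row extremes
    sk_rows <- range(which(skel, arr.ind = TRUE)[, 1])
    end_ext <- (nrow(sub) - sk_rows[2]) + (sk_rows[1] - 1)
    # core width = maximal inscribed disc diameter minus the blur halo
    pad <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
    pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
    dm <- EBImage::distmap(EBImage::Image(pad * 1))
    width <- 2 * max(dm) - halo_px
    x_c <- mean(idx[, 2]) - 1
    if (width <= w_f) {
      # Length runs from the band face to the tip: the attachment-to-tip
      # chord (filopodia are straight, and the chord avoids the
      # orientation-dependent overcount of digital path sums), the end
      # spans eroded by thinning, and the root gap down to the band face,
      # minus the blurred-tip extension (half the halo).
      len_um <- (geo$chord + end_ext + root_gap + 0.5 - halo_px / 2) *
        um_per_px
      if (len_um < l_min) next
      out[[length(out) + 1L]] <- data.frame(
        type = "filopodium", value = len_um, x_px = x_c, width_px = width)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        type = "lamellipodium", value = area_px * um_per_px^2,
        x_px = x_c, width_px = width)
    }
  }
  if (length(out) == 0L)
    return(data.frame(type = character(0), value = numeric(0),
                      x_px = numeric(0), width_px = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname measure_protrusions
#' @export
measure_filopodia <- function(image, baseline = NULL, um_per_px = 0.25,
                              w_f = 4, l_min = 1, halo_px = 2.8) {
  m <- measure_protrusions(image, baseline, um_per_px, w_f, l_min, halo_px)
  m$value[m$type == "filopodium"]
}

#' @rdname measure_protrusions
#' @export
measure_lamellipodia <- function(image, baseline = NULL, um_per_px = 0.25,
                                 w_f = 4, l_min = 1, halo_px = 2.8) {
  m <- measure_protrusions(image, baseline, um_per_px, w_f, l_min, halo_px)
  m$value[m$type == "lamellipodium"]
}

#' Summarize protrusion morphometrics over a frame set
#'
#' Filopodium lengths are pooled over all frames (mean +/- sd, n objects).
#' The lamellipodium "protrusive area" statistic is the per-frame maximal
#' area, summarized as mean +/- sd over frames that contain at least one
#' lamellipodium (n frames) - matching published counts where n equals the
#' number of frames, not blobs.
#'
#' @param frames a `protrusion_sim`, or list of intensity matrices.
#' @param um_per_px pixel size, um (taken from the object if present).
#' @param ... passed to [measure_protrusions()].
#' @return Object of class `protrusion_summary` with per-object table and
#'   pooled statistics.
#' @export
summarize_protrusions <- function(frames, um_per_px = NULL, ...) {
  if (inherits(frames, "protrusion_sim")) {
    if (is.null(um_per_px)) um_per_px <- frames$um_per_px
    frames <- frames$frames
  }
  if (is.null(um_per_px)) um_per_px <- 0.25
  per <- lapply(seq_along(frames), function(i) {
    m <- measure_protrusions(frames[[i]], um_per_px = um_per_px, ...)
    if (nrow(m) > 0) cbind(frame = i, m) else NULL
  })
  tab <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  fil <- tab$value[tab$type == "filopodium"]
  lam <- tab[tab$type == "lamellipodium", , drop = FALSE]
  lam_max <- if (nrow(lam) > 0)
    tapply(lam$value, lam$frame, max) else numeric(0)
  structure(list(
    objects = tab,
    fil_lengths_um = fil,
    fil_mean = if (length(fil)) mean(fil) else NA_real_,
    fil_sd = if (length(fil) > 1) stats::sd(fil) else NA_real_,
    fil_n = length(fil),
    lam_frame_max_um2 = as.numeric(lam_max),
    lam_max_mean = if (length(lam_max)) mean(lam_max) else NA_real_,
    lam_max_sd = if (length(lam_max) > 1) stats::sd(lam_max) else NA_real_,
    lam_n_frames = length(lam_max)), class = "protrusion_summary")
}

#' @export
print.protrusion_summary <- function(x, ...) {
  cat(sprintf(
    "<protrusion_summary> filopodia %.2f +/- %.2f um (n = %d); lamellipodia %.1f +/- %.1f um^2 (n = %d frames)\n",
    x$fil_mean, x$fil_sd, x$fil_n, x$lam_max_mean, x$lam_max_sd,
    x$lam_n_frames))
  invisible(x)
}
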