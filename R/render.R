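#' Rendering parameters for synthetic leading-edge movies
#'
#' Controls rasterization of the bright leading-edge arcs that bound the
#' dorsal hole (emulating a protein-trap label restricted to the first row
#' of epithelial cells), the optical blur, and the camera noise.
#'
#' @param um_per_px pixel size, um (> 0).
#' @param width_px,height_px image size in pixels; `NULL` auto-sizes the
#'   frame to the largest hole in the trajectory plus a margin.
#' @param edge_intensity peak intensity of the leading edge (0-1 scale).
#' @param edge_thickness_px drawn arc thickness, px.
#' @param psf_sigma_px Gaussian point-spread sigma, px.
#' @param background background level (0-1 scale).
#' @param noise_sd additive Gaussian noise sigma (0-1 scale).
#' @param poisson if `TRUE`, apply Poisson shot noise before read noise.
#' @param photons_per_unit photon count corresponding to intensity 1.0,
#'   used only when `poisson = TRUE`.
#' @return An object of class `render_params`.
#' @export
render_params <- function(um_per_px = 0.5, width_px = NULL, height_px = NULL,
                          edge_intensity = 0.8, edge_thickness_px = 3,
                          psf_sigma_px = 1.5, background = 0.1,
                          noise_sd = 0.02, poisson = FALSE,
                          photons_per_unit = 200) {
  assert_number(um_per_px, "um_per_px", lower = 1e-9)
  assert_number(edge_intensity, "edge_intensity", lower = 0)
  assert_number(edge_thickness_px, "edge_thickness_px", lower = 0.5)
  assert_number(psf_sigma_px, "psf_sigma_px", lower = 0)
  assert_number(background, "background", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(width_px)) assert_count(width_px, "width_px", 8L)
  if (!is.null(height_px)) assert_count(height_px, "height_px", 8L)
  structure(list(um_per_px = um_per_px, width_px = width_px,
                 height_px = height_px, edge_intensity = edge_intensity,
                 edge_thickness_px = edge_thickness_px,
                 psf_sigma_px = psf_sigma_px, background = background,
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 photons_per_unit = photons_per_unit),
            class = "render_params")
}

# Stamp discs of radius r (px) at sub-pixel sample points into an intensity
# matrix (rows = y, cols = x; 0-based pixel centers at integer coordinates).
stamp_points <- function(img, xs, ys, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  off <- expand.grid(dx = seq(-ceiling(r), ceiling(r)),
                     dy = seq(-ceiling(r), ceiling(r)))
  off <- off[off$dx^2 + off$dy^2 <= (r + 0.5)^2, , drop = FALSE]
  px <- as.vector(outer(round(xs), off$dx, `+`))
  py <- as.vector(outer(round(ys), off$dy, `+`))
  keep <- px >= 0 & px < nc & py >= 0 & py < nr
  idx <- unique(cbind(py[keep] + 1L, px[keep] + 1L))
  img[idx] <- pmax(img[idx], value)
  img
}

# Rasterize one frame: two circular arcs of chord W and sagitta H/2 meeting
# at the canthi on the anterior-posterior (x) axis. H = 0 degenerates to a
# single seam line between the canthi. Geometry in pixels, 0-based.
draw_arc_frame <- function(W_px, H_px, cx, cy, nrow_px, ncol_px, thickness,
                           value) {
  img <- matrix(0, nrow_px, ncol_px)
  r <- thickness / 2
  if (W_px <= 0) return(img)
  half_w <- W_px / 2
  if (H_px <= 1e-9) {
    xs <- seq(cx - half_w, cx + half_w, by = 0.25)
    return(stamp_points(img, xs, rep(cy, length(xs)), r, value))
  }
  s <- H_px / 2
  R <- (half_w^2 + s^2) / (2 * s)
  alpha <- asin(min(1, half_w / R))
  for (bulge in c(-1, 1)) {
    # circle center lies opposite the bulge direction
    yc <- cy - bulge * (R - s)
    ang <- seq(-alpha, alpha, length.out = max(16L, ceiling(4 * R * alpha)))
    xs <- cx + R * sin(ang)
    ys <- yc + bulge * R * cos(ang)
    img <- stamp_points(img, xs, ys, r, value)
  }
  img
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  sz <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  g <- stats::dnorm(seq(-(sz %/% 2), sz %/% 2), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Render a closure trajectory as a synthetic fluorescence movie
#'
#' Each frame draws the two leading-edge arcs for the frame's (W, H),
#' convolves with a Gaussian PSF, adds background, optional Poisson shot
#' noise and Gaussian read noise. Ground truth (frame geometry and canthus
#' pixel coordinates, 0-based, x = anterior-posterior axis) is returned
#' alongside the image stack.
#'
#' @param traj a simulated [closure_trajectory].
#' @param rp a [render_params()] object.
#' @param seed integer seed for the noise generator, or `NULL`.
#' @return An object of class `closure_movie`: list with `frames` (list of
#'   intensity matrices in `[0, 1]`), `truth` (per-frame data frame) and the
#'   rendering parameters.
#' @export
render_closure_movie <- function(traj, rp = render_params(), seed = NULL) {
  stopifnot(inherits(traj, "closure_trajectory"),
            inherits(rp, "render_params"))
  fr <- traj$frames
  if (nrow(fr) == 0L) stop("empty trajectory")
  scale <- rp$um_per_px
  margin <- 20 + rp$edge_thickness_px + 4 * rp$psf_sigma_px
  need_w <- ceiling(max(fr$W_um) / scale + 2 * margin)
  need_h <- ceiling(max(fr$H_um) / scale + 2 * margin)
  ncol_px <- if (is.null(rp$width_px)) need_w else rp$width_px
  nrow_px <- if (is.null(rp$height_px)) need_h else rp$height_px
  too_big <- which(fr$W_um / scale + 2 * margin > ncol_px |
                   fr$H_um / scale + 2 * margin > nrow_px)
  if (length(too_big) > 0L)
    stop(sprintf("hole does not fit in the %dx%d px frame at frame %d",
                 ncol_px, nrow_px, fr$frame[too_big[1]]))
  cx <- (ncol_px - 1) / 2
  cy <- (nrow_px - 1) / 2
  kern <- gaussian_kernel(rp$psf_sigma_px)
  with_seed(seed, {
    frames <- vector("list", nrow(fr))
    for (i in seq_len(nrow(fr))) {
      W_px <- fr$W_um[i] / scale
      H_px <- if (fr$closed[i]) 0 else fr$H_um[i] / scale
      img <- draw_arc_frame(W_px, H_px, cx, cy, nrow_px, ncol_px,
                            rp$edge_thickness_px, rp$edge_intensity)
      if (rp$psf_sigma_px > 0)
        img <- EBImage::filter2(img, kern, boundary = "replicate")
      img <- img + rp$background
      if (rp$poisson)
        img <- stats::rpois(length(img), pmax(img, 0) * rp$photons_per_unit) /
          rp$photons_per_unit
      if (rp$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, rp$noise_sd)
      frames[[i]] <- matrix(pmin(pmax(img, 0), 1), nrow_px, ncol_px)
    }
    truth <- cbind(fr,
                   canthus_left_x = cx - fr$W_um / scale / 2,
                   canthus_right_x = cx + fr$W_um / scale / 2,
                   canthus_y = cy)
    structure(list(frames = frames, truth = truth, render_params = rp,
                   um_per_px = scale,
                   frame_interval = traj$params$frame_interval),
              class = "closure_movie")
  })
}

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' @param frames a `closure_movie`, or a list of numeric matrices in `[0,1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(frames, path) {
  if (inherits(frames, "closure_movie")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) > 0L)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a list of intensity matrices
#'
#' @param path TIFF file path.
#' @return List of numeric matrices scaled to `[0, 1]`.
#' @export
read_movie_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) {
    if (length(dim(im)) == 3L) im <- im[, , 1]
    im
  })
}
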