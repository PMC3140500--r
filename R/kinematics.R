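# Frames a fit may use: measured trajectories carry a `reliable` flag for
# frames whose slit height exceeds the segmentation scale.
usable_frames <- function(traj) {
  fr <- traj$frames
  if (!is.null(fr$reliable)) fr <- fr[fr$reliable, , drop = FALSE]
  fr
}

#' Fit the sheet translocation velocity v
#'
#' `v` is minus the ordinary-least-squares slope of hole height `H` against
#' time over the fit window. The default window keeps open frames with
#' `eps_H < H < hmax_frac * max(H)`: the earliest frames (germ-band
#' retraction remnants, H near its maximum) and the terminal flat-arc
#' frames violate the constant-velocity assumption and are excluded.
#'
#' @param traj a `closure_trajectory` (simulated or measured).
#' @param eps_H closure threshold, um.
#' @param hmax_frac upper window bound as a fraction of the maximal height.
#' @return List: `v` (um/s), `rms` residual RMS (um), `window` (frame
#'   indices used), `slope_nonnegative` flag.
#' @export
fit_velocity <- function(traj, eps_H = 1, hmax_frac = 0.9) {
  fr <- usable_frames(traj)
  sel <- which(!fr$closed & fr$H_um > eps_H &
                 fr$H_um < hmax_frac * max(fr$H_um))
  if (length(sel) < 4L)
    stop("fit failure: fewer than 4 usable frames for the velocity fit")
  fit <- stats::lm(H_um ~ t_s, data = fr[sel, ])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    warning("non-negative H slope: hole is not converging", call. = FALSE)
  list(v = -slope, rms = sqrt(mean(stats::resid(fit)^2)),
       window = fr$frame[sel], slope_nonnegative = slope >= 0)
}

#' Fit the zipping rate constant k_z
#'
#' Under the arc model `dW/dt = -k_z / tan(theta)`, so `k_z` is minus the
#' slope of the no-intercept least-squares regression of the
#' central-difference estimate of `dW/dt` on `1 / tan(theta)`. Frames with
#' `tan(theta) <= tan_min` are excluded (the zipping term blows up on flat
#' arcs). An intercept variant is returned as a diagnostic only.
#'
#' @param traj a `closure_trajectory`.
#' @param eps_H closure threshold, um.
#' @param tan_min window bound on `tan(theta)`.
#' @return List: `k_z` (um/s), `r_squared` of the no-intercept regression,
#'   `window` (frame indices), `intercept_diag` (slope and intercept of the
#'   with-intercept variant).
#' @export
fit_zipping <- function(traj, eps_H = 1, tan_min = 0.05) {
  fr <- usable_frames(traj)
  open <- fr[!fr$closed & fr$H_um > eps_H, ]
  n <- nrow(open)
  if (n < 3L) stop("fit failure: fewer than 3 open frames")
  t <- open$t_s; W <- open$W_um
  dWdt <- numeric(n)
  dWdt[1] <- (W[2] - W[1]) / (t[2] - t[1])
  dWdt[n] <- (W[n] - W[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    dWdt[i] <- (W[i + 1] - W[i - 1]) / (t[i + 1] - t[i - 1])
  }
  tt <- tan(open$theta_rad)
  keep <- which(tt > tan_min)
  if (length(keep) == 0L)
    stop("fit failure: flat-arc trajectory (all tan(theta) below threshold)")
  if (length(keep) < 5L)
    stop("fit failure: fewer than 5 frames with tan(theta) above threshold")
  x <- 1 / tt[keep]; y <- dWdt[keep]
  slope <- sum(x * y) / sum(x * x)
  ss_res <- sum((y - slope * x)^2)
  r2 <- if (sum(y^2) > 0) 1 - ss_res / sum(y^2) else NA_real_
  ifit <- stats::lm(y ~ x)
  list(k_z = -slope, r_squared = r2, window = open$frame[keep],
       intercept_diag = list(slope = unname(stats::coef(ifit)[2]),
                             intercept = unname(stats::coef(ifit)[1])))
}

#' Fractional contribution of zipping to closure speed
#'
#' `f_z = k_z / v`. Under the constant-curvature arc geometry the zipping
#' term contributes rate `k_z` to `-dH/dt`, so the ratio is the fraction of
#' the closure velocity attributable to zippering at the canthi. Values
#' above 1 are clipped to 1 with the raw ratio retained.
#'
#' @param v sheet velocity, um/s (> 0).
#' @param k_z zipping rate constant, um/s (>= 0).
#' @return List: `f_z` (clipped to `[0, 1]`), `f_z_raw`.
#' @export
compute_fz <- function(v, k_z) {
  assert_number(v, "v")
  assert_number(k_z, "k_z", lower = 0)
  if (v <= 0) stop("f_z is undefined for v <= 0")
  raw <- k_z / v
  list(f_z = min(1, max(0, raw)), f_z_raw = raw)
}

#' Full kinematic fit of a closure trajectory
#'
#' Convenience wrapper running [fit_velocity()], [fit_zipping()] and
#' [compute_fz()].
#'
#' @inheritParams fit_velocity
#' @inheritParams fit_zipping
#' @return Object of class `kinematic_fit`.
#' @export
fit_closure <- function(traj, eps_H = 1, hmax_frac = 0.9, tan_min = 0.05) {
  vf <- fit_velocity(traj, eps_H = eps_H, hmax_frac = hmax_frac)
  zf <- fit_zipping(traj, eps_H = eps_H, tan_min = tan_min)
  fz <- compute_fz(vf$v, max(0, zf$k_z))
  structure(list(v = vf$v, k_z = zf$k_z, f_z = fz$f_z,
                 f_z_raw = fz$f_z_raw, rms_H = vf$rms,
                 r_squared_zip = zf$r_squared,
                 window_v = vf$window, window_z = zf$window,
                 intercept_diag = zf$intercept_diag),
            class = "kinematic_fit")
}

#' @export
print.kinematic_fit <- function(x, ...) {
  cat(sprintf("<kinematic_fit> v = %.5f um/s, k_z = %.5f um/s, f_z = %.3f\n",
              x$v, x$k_z, x$f_z))
  cat(sprintf("  H-fit RMS = %.3f um, zipping R^2 = %.4f\n",
              x$rms_H, x$r_squared_zip))
  invisible(x)
}

#' Build a wild-type reference distribution for phenotype calls
#'
#' Summarizes at least three wild-type runs into the reference used by
#' [classify_phenotype()]: mean and sd of `v` and `f_z`, and per-frame mean
#' and sd trajectories of circularity and aspect (frames aligned by index,
#' truncated to the shortest open run). Standard deviations are floored at
#' `sd_floor_frac` of the mean (absolute `sd_floor_frac` for `f_z`) so that
#' a tight reference set of few runs does not produce degenerate z-scores.
#'
#' @param trajs list of measured `closure_trajectory` objects.
#' @param fits list of matching `kinematic_fit` objects.
#' @param sd_floor_frac relative floor on reference sds.
#' @return Object of class `wt_reference`.
#' @export
build_reference <- function(trajs, fits, sd_floor_frac = 0.05) {
  stopifnot(length(trajs) >= 3L, length(trajs) == length(fits))
  vs <- vapply(fits, function(f) f$v, numeric(1))
  fzs <- vapply(fits, function(f) f$f_z, numeric(1))
  open <- lapply(trajs, function(tr) tr$frames[!tr$frames$closed, ])
  n_min <- min(vapply(open, nrow, integer(1)))
  circ <- sapply(open, function(fr) fr$circularity[seq_len(n_min)])
  asp <- sapply(open, function(fr) fr$aspect[seq_len(n_min)])
  floor_vec <- function(m, s, abs_floor = NULL) {
    pmax(s, if (is.null(abs_floor)) sd_floor_frac * abs(m) else abs_floor)
  }
  structure(list(
    n_runs = length(trajs), n_frames = n_min,
    v_mean = mean(vs), v_sd = floor_vec(mean(vs), stats::sd(vs)),
    fz_mean = mean(fzs),
    fz_sd = floor_vec(mean(fzs), stats::sd(fzs), sd_floor_frac),
    circ_mean = rowMeans(circ),
    circ_sd = floor_vec(rowMeans(circ), apply(circ, 1, stats::sd)),
    aspect_mean = rowMeans(asp),
    aspect_sd = floor_vec(rowMeans(asp), apply(asp, 1, stats::sd))),
    class = "wt_reference")
}

#' Classify the closure phenotype of an embryo
#'
#' Group I: the hole never closes (final height above `eps_H` at movie
#' end). Group II: closure completes but with abnormal dynamics, flagged by
#' any of: circularity z-score above `z_star` sustained over at least
#' `sustain` of the compared frames (`circular_hole`); `f_z` z-score below
#' `-z_star` (`low_fz`); aspect (H/W) z-score below `-z_star` sustained
#' (`narrowed` - inefficient zipping leaves the hole a long, abnormally
#' narrow slit, so its aspect runs low against the wild-type trajectory);
#' asymmetry above `a_star` sustained (`asymmetric`). Otherwise normal.
#'
#' @param traj measured `closure_trajectory`.
#' @param fit `kinematic_fit` for the same embryo (may be `NULL` if the
#'   trajectory never closed).
#' @param reference a [build_reference()] object.
#' @param z_star z-score threshold.
#' @param a_star asymmetry threshold.
#' @param eps_H closure threshold, um.
#' @param sustain fraction of frames over which a shape flag must hold.
#' @return Object of class `phenotype_call`: `group` in
#'   `{"normal", "group_I", "group_II"}` and a character vector of flags.
#' @export
classify_phenotype <- function(traj, fit, reference, z_star = 2,
                               a_star = 0.2, eps_H = 1, sustain = 0.25) {
  if (is.null(reference) || !inherits(reference, "wt_reference"))
    stop("a wild-type reference (build_reference) is required")
  fr <- traj$frames
  last <- fr[nrow(fr), ]
  flags <- character(0)
  if (!last$closed && last$H_um > eps_H) {
    flags <- "not_closed"
    return(structure(list(group = "group_I", flags = flags),
                     class = "phenotype_call"))
  }
  open <- fr[!fr$closed, ]
  n <- min(nrow(open), reference$n_frames)
  idx <- seq_len(n)
  zc <- (open$circularity[idx] - reference$circ_mean[idx]) /
    reference$circ_sd[idx]
  za <- (open$aspect[idx] - reference$aspect_mean[idx]) /
    reference$aspect_sd[idx]
  frac <- function(x) mean(x, na.rm = TRUE)
  if (frac(zc > z_star) >= sustain) flags <- c(flags, "circular_hole")
  if (frac(za < -z_star) >= sustain) flags <- c(flags, "narrowed")
  if (frac(open$asymmetry[idx] > a_star) >= sustain)
    flags <- c(flags, "asymmetric")
  if (!is.null(fit)) {
    zf <- (fit$f_z - reference$fz_mean) / reference$fz_sd
    if (zf < -z_star) flags <- c(flags, "low_fz")
  }
  group <- if (length(flags) > 0L) "group_II" else "normal"
  structure(list(group = group, flags = flags), class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s%s\n", x$group,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}
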