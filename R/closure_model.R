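#' Parameters of the dorsal-closure kinematic model
#'
#' The dorsal hole is modeled as the area between two circular leading-edge
#' arcs of chord `W` (width, anterior-posterior distance between the two
#' canthi) and sagitta `H/2` each (so `H` is the maximal dorsoventral
#' distance between the converging epithelial sheets). The canthus angle
#' `theta` is the tangent-chord angle of the arcs, `theta = 2*atan(H/W)`.
#' Closure dynamics follow
#' \deqn{dH/dt = -v, \qquad dW/dt = -k_z / \tan\theta,}
#' where `v` is the epithelial sheet translocation velocity and `k_z` the
#' zipping rate constant. The fractional contribution of zipping to closure
#' speed is `f_z = k_z / v`.
#'
#' @param v sheet translocation velocity, um/s (>= 0).
#' @param k_z zipping rate constant, um/s (>= 0).
#' @param H0 initial hole height, um (> 0).
#' @param W0 initial hole width, um (> 0).
#' @param frame_interval acquisition interval, s (> 0). The default emulates
#'   screen-mode imaging at one frame per 12 minutes.
#' @param duration total imaging time, s (> 0); default 13 h.
#' @return An object of class `closure_params`.
#' @export
closure_params <- function(v, k_z, H0 = 60, W0 = 240,
                           frame_interval = 720, duration = 46800) {
  assert_number(v, "v", lower = 0)
  assert_number(k_z, "k_z", lower = 0)
  assert_number(H0, "H0", lower = 1e-9)
  assert_number(W0, "W0", lower = 1e-9)
  assert_number(frame_interval, "frame_interval", lower = 1e-9)
  assert_number(duration, "duration", lower = 1e-9)
  structure(list(v = v, k_z = k_z, H0 = H0, W0 = W0,
                 frame_interval = frame_interval, duration = duration),
            class = "closure_params")
}

# One RK4 step of the closure ODE. The zipping term diverges as theta -> 0,
# so the per-step change in W is capped at the current W (the hole then
# zips shut rather than producing a non-finite width).
closure_step <- function(H, W, v, k_z, h) {
  dW <- function(H, W) {
    if (W <= 0 || H <= 0) return(0)
    -k_z / tan(2 * atan(H / W))
  }
  k1 <- dW(H, W)
  k2 <- dW(H - v * h / 2, W + k1 * h / 2)
  k3 <- dW(H - v * h / 2, W + k2 * h / 2)
  k4 <- dW(H - v * h, W + k3 * h)
  dWh <- h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  if (!is.finite(dWh) || -dWh > W) dWh <- -W
  c(H = max(H - v * h, 0), W = max(W + dWh, 0))
}

#' Simulate a ground-truth closure trajectory
#'
#' Integrates the closure model (see [closure_params()]) with a fixed-step
#' RK4 scheme at sub-frame resolution and samples the state at the frame
#' interval. The trajectory terminates at the first frame at which
#' `H <= eps_H` (hole closed) or `W <= eps_W` (hole zipped shut before the
#' sheets met); that terminal frame is included and flagged.
#'
#' @param params a [closure_params()] object.
#' @param eps_H,eps_W closure thresholds, um.
#' @return An object of class `closure_trajectory`: a list with a `frames`
#'   data frame (`frame`, `t_s`, `W_um`, `H_um`, `theta_rad`, `closed`),
#'   the parameters, a `zipped_shut` flag, and `source = "simulated"`.
#' @export
simulate_closure_trajectory <- function(params, eps_H = 1, eps_W = 1) {
  stopifnot(inherits(params, "closure_params"))
  assert_number(eps_H, "eps_H", lower = 0)
  assert_number(eps_W, "eps_W", lower = 0)
  dt <- params$frame_interval
  h <- min(1, dt / 60)
  n_sub <- max(1L, ceiling(dt / h))
  h <- dt / n_sub
  n_frames <- floor(params$duration / dt) + 1L
  H <- params$H0; W <- params$W0
  rows <- vector("list", n_frames)
  zipped <- FALSE
  for (i in seq_len(n_frames)) {
    t <- (i - 1L) * dt
    closed <- H <= eps_H || W <= eps_W
    if (closed && W <= eps_W && H > eps_H) zipped <- TRUE
    theta <- if (W > 0) 2 * atan(H / W) else pi / 2
    rows[[i]] <- data.frame(frame = i, t_s = t, W_um = W, H_um = H,
                            theta_rad = theta, closed = closed)
    if (closed) { rows <- rows[seq_len(i)]; break }
    for (s in seq_len(n_sub)) {
      st <- closure_step(H, W, params$v, params$k_z, h)
      H <- st[["H"]]; W <- st[["W"]]
      if (H <= eps_H || W <= eps_W) break
    }
  }
  frames <- do.call(rbind, rows)
  rownames(frames) <- NULL
  structure(list(frames = frames, params = params, eps_H = eps_H,
                 eps_W = eps_W, zipped_shut = zipped, source = "simulated"),
            class = "closure_trajectory")
}

#' @export
print.closure_trajectory <- function(x, ...) {
  fr <- x$frames
  cat(sprintf("<closure_trajectory> %s, %d frames, dt = %gs\n", x$source,
              nrow(fr), if (nrow(fr) > 1) diff(fr$t_s[1:2]) else NA))
  cat(sprintf("  W: %.1f -> %.1f um; H: %.1f -> %.1f um; %s\n",
              fr$W_um[1], fr$W_um[nrow(fr)], fr$H_um[1], fr$H_um[nrow(fr)],
              if (any(fr$closed)) "closed" else "open at end"))
  invisible(x)
}
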