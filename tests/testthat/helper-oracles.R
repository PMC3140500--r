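# Independent oracles and small fixture builders used across tests.

# Fine-step explicit-Euler integration of the closure ODEs, written
# independently of the package's RK4 integrator.
euler_oracle <- function(v, k_z, H0, W0, frame_interval, duration,
                         h = 0.01, eps_H = 1, eps_W = 1) {
  n_frames <- floor(duration / frame_interval) + 1L
  H <- H0; W <- W0
  out <- data.frame(t_s = numeric(0), W_um = numeric(0), H_um = numeric(0))
  t <- 0
  for (i in seq_len(n_frames)) {
    out <- rbind(out, data.frame(t_s = t, W_um = W, H_um = H))
    if (H <= eps_H || W <= eps_W) break
    t_next <- t + frame_interval
    while (t < t_next - h / 2) {
      theta <- 2 * atan(H / W)
      dW <- if (tan(theta) > 0) -k_z / tan(theta) else 0
      W <- max(W + h * dW, 0)
      H <- max(H - h * v, 0)
      t <- t + h
      if (H <= eps_H || W <= eps_W) break
    }
    t <- t_next
    if (H <= eps_H || W <= eps_W) {
      out <- rbind(out, data.frame(t_s = t, W_um = W, H_um = H))
      break
    }
  }
  out
}

# Brute-force grid search for the zipping rate constant on the same
# derivative/angle data the regression uses.
kz_grid_oracle <- function(traj, eps_H = 1, tan_min = 0.05,
                           k_grid = seq(0, 0.02, by = 1e-5)) {
  fr <- traj$frames
  if (!is.null(fr$reliable)) fr <- fr[fr$reliable, , drop = FALSE]
  open <- fr[!fr$closed & fr$H_um > eps_H, ]
  n <- nrow(open)
  t <- open$t_s; W <- open$W_um
  dWdt <- numeric(n)
  dWdt[1] <- (W[2] - W[1]) / (t[2] - t[1])
  dWdt[n] <- (W[n] - W[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  dWdt[i] <- (W[i + 1] - W[i - 1]) / (t[i + 1] - t[i - 1])
  tt <- tan(open$theta_rad)
  keep <- tt > tan_min
  x <- 1 / tt[keep]; y <- dWdt[keep]
  ss <- vapply(k_grid, function(k) sum((y + k * x)^2), numeric(1))
  k_grid[which.min(ss)]
}

# wrap a frames data frame as a trajectory object
as_traj <- function(frames) {
  structure(list(frames = frames, source = "measured"),
            class = "closure_trajectory")
}

# single-frame trajectory for rendering fixtures
frame_traj <- function(W, H, frame_interval = 60) {
  structure(list(frames = data.frame(frame = 1, t_s = 0, W_um = W,
                                     H_um = H, theta_rad = 2 * atan(H / W),
                                     closed = FALSE),
                 params = list(frame_interval = frame_interval)),
            class = "closure_trajectory")
}

# disc mask fixture
disc_mask <- function(r = 40, pad = 10) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- TRUE
  m
}
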