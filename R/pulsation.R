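#' Detect pulsation peaks and troughs in an apical-area trace
#'
#' The trace is smoothed with a centered moving average (window given in
#' seconds), local extrema are found on the smoothed trace, extrema whose
#' prominence falls below `min_prominence` times the smoothed trace range
#' are discarded, and peaks/troughs are pruned to strict alternation (the
#' weaker of two consecutive same-type extrema is dropped). Detection is
#' invariant to affine intensity changes of the trace because prominence is
#' taken relative to the trace range.
#'
#' @param t sample times, s (strictly increasing).
#' @param area apical area samples, um^2.
#' @param smooth_window smoothing window, s.
#' @param min_prominence prominence threshold as a fraction of trace range.
#' @return List: `peak_times`, `trough_times`, `peak_idx`, `trough_idx`,
#'   `smoothed`.
#' @export
detect_pulses <- function(t, area, smooth_window = 30,
                          min_prominence = 0.1) {
  stopifnot(length(t) == length(area), length(t) >= 3L,
            all(diff(t) > 0))
  dt <- stats::median(diff(t))
  if (smooth_window >= (t[length(t)] - t[1]))
    stop("smoothing window must be shorter than the trace span")
  k <- max(1L, round(smooth_window / dt))
  s <- moving_average(area, k)
  rng <- diff(range(s))
  empty <- list(peak_times = numeric(0), trough_times = numeric(0),
                peak_idx = integer(0), trough_idx = integer(0), smoothed = s)
  if (rng <= 0) return(empty)
  pk <- local_extrema(s, maxima = TRUE)
  tr <- local_extrema(s, maxima = FALSE)
  pk <- pk[extremum_prominence(s, pk, maxima = TRUE) >=
             min_prominence * rng]
  tr <- tr[extremum_prominence(s, tr, maxima = FALSE) >=
             min_prominence * rng]
  alt <- enforce_alternation(s, pk, tr)
  list(peak_times = t[alt$peaks], trough_times = t[alt$troughs],
       peak_idx = alt$peaks, trough_idx = alt$troughs, smoothed = s)
}

# indices of local maxima/minima; plateaus collapse to their midpoint
local_extrema <- function(s, maxima = TRUE) {
  if (!maxima) s <- -s
  d <- sign(diff(s))
  # carry the last nonzero slope sign through plateaus
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  out <- integer(0)
  runs <- which(d[-1] < 0 & d[-length(d)] > 0) + 1L
  runs
}

# topological prominence: height above the higher of the two bounding
# saddles toward the nearest higher extremum on each side
extremum_prominence <- function(s, idx, maxima = TRUE) {
  if (!maxima) s <- -s
  vapply(idx, function(i) {
    h <- s[i]
    left <- s[seq_len(i - 1)]
    right <- if (i < length(s)) s[(i + 1):length(s)] else numeric(0)
    lmin <- saddle_min(left, h, from_right = TRUE)
    rmin <- saddle_min(right, h, from_right = FALSE)
    h - max(lmin, rmin)
  }, numeric(1))
}

# minimum of the values between the extremum and the nearest strictly
# higher value on that side (whole side if none)
saddle_min <- function(side, h, from_right) {
  if (length(side) == 0L) return(-Inf)
  if (from_right) side <- rev(side)
  higher <- which(side > h)
  stop_at <- if (length(higher) == 0L) length(side) else higher[1]
  min(side[seq_len(stop_at)])
}

enforce_alternation <- function(s, peaks, troughs) {
  ev <- data.frame(i = c(peaks, troughs),
                   type = rep(c(1, -1), c(length(peaks), length(troughs))))
  ev <- ev[order(ev$i), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  j <- 0L
  for (k in seq_len(nrow(ev))) {
    if (j == 0L) { j <- k; next }
    if (ev$type[k] == ev$type[j]) {
      # two consecutive same-type extrema: keep the stronger
      better_k <- if (ev$type[k] == 1) s[ev$i[k]] > s[ev$i[j]] else
        s[ev$i[k]] < s[ev$i[j]]
      if (better_k) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
    } else j <- k
  }
  ev <- ev[keep, , drop = FALSE]
  list(peaks = ev$i[ev$type == 1], troughs = ev$i[ev$type == -1])
}

#' Summarize pulsation statistics over a set of cell traces
#'
#' Periods are successive peak-to-peak intervals pooled over all cells
#' (mirroring pooled pulse counts such as "n = 85 pulsations"), reported as
#' mean +/- sample sd (n-1 denominator) with n. Per-pulse maxima and
#' minima are the raw trace values at detected peaks and troughs, averaged
#' over all pulses; the overall mean area is the dashed-line average.
#'
#' @param traces data frame with `cell_id`, `t_s`, `area_um2` (or a
#'   `pulsation_sim` object, whose traces are used).
#' @param smooth_window,min_prominence passed to [detect_pulses()].
#' @return Object of class `pulsation_summary`: pooled `periods_s`,
#'   `period_mean`, `period_sd`, `n_periods`, `maxima_mean`, `minima_mean`,
#'   `mean_area`, per-cell pulse counts, and `no_pulses` flag.
#' @export
summarize_pulsation <- function(traces, smooth_window = 30,
                                min_prominence = 0.1) {
  if (inherits(traces, "pulsation_sim")) traces <- traces$traces
  stopifnot(all(c("cell_id", "t_s", "area_um2") %in% names(traces)))
  cells <- split(traces, traces$cell_id)
  periods <- numeric(0)
  maxima <- numeric(0)
  minima <- numeric(0)
  counts <- integer(length(cells))
  names(counts) <- names(cells)
  for (ci in seq_along(cells)) {
    tr <- cells[[ci]]
    det <- detect_pulses(tr$t_s, tr$area_um2, smooth_window, min_prominence)
    counts[ci] <- length(det$peak_idx)
    if (length(det$peak_idx) >= 2L)
      periods <- c(periods, diff(det$peak_times))
    maxima <- c(maxima, tr$area_um2[det$peak_idx])
    minima <- c(minima, tr$area_um2[det$trough_idx])
  }
  n <- length(periods)
  structure(list(
    periods_s = periods,
    period_mean = if (n > 0) mean(periods) else NA_real_,
    period_sd = if (n > 1) stats::sd(periods) else NA_real_,
    n_periods = n,
    maxima_mean = if (length(maxima)) mean(maxima) else NA_real_,
    minima_mean = if (length(minima)) mean(minima) else NA_real_,
    mean_area = mean(traces$area_um2),
    pulse_counts = counts,
    no_pulses = n == 0L), class = "pulsation_summary")
}

#' @export
print.pulsation_summary <- function(x, ...) {
  if (x$no_pulses) cat("<pulsation_summary> no pulses detected\n")
  else cat(sprintf(
    "<pulsation_summary> period %.0f +/- %.0f s (n = %d); maxima %.1f, minima %.1f um^2\n",
    x$period_mean, x$period_sd, x$n_periods, x$maxima_mean, x$minima_mean))
  invisible(x)
}

#' Tissue-level apical contraction curve
#'
#' Normalizes each cell's trace to its initial area and reports the mean
#' and sd of the normalized area across cells in time bins, for wild-type
#' versus mutant comparison of net amnioserosa contraction.
#'
#' @param traces data frame with `cell_id`, `t_s`, `area_um2`.
#' @param n_bins number of equal-width time bins.
#' @return Data frame: `t_mid_s`, `mean_norm_area`, `sd_norm_area`,
#'   `n_cells`.
#' @export
tissue_contraction <- function(traces, n_bins = 10) {
  if (inherits(traces, "pulsation_sim")) traces <- traces$traces
  cells <- split(traces, traces$cell_id)
  if (length(cells) < 2L) stop("at least 2 cells are required")
  norm <- lapply(cells, function(tr) {
    a0 <- tr$area_um2[which.min(tr$t_s)]
    if (a0 <= 0) {
      warning("trace with zero initial area excluded", call. = FALSE)
      return(NULL)
    }
    data.frame(cell_id = tr$cell_id, t_s = tr$t_s,
               norm_area = tr$area_um2 / a0)
  })
  norm <- do.call(rbind, norm[!vapply(norm, is.null, logical(1))])
  brk <- seq(min(norm$t_s), max(norm$t_s), length.out = n_bins + 1L)
  bin <- cut(norm$t_s, brk, include.lowest = TRUE)
  per_cell_bin <- stats::aggregate(norm_area ~ cell_id + bin, norm, mean)
  agg_m <- stats::aggregate(norm_area ~ bin, per_cell_bin, mean)
  agg_s <- stats::aggregate(norm_area ~ bin, per_cell_bin, stats::sd)
  agg_n <- stats::aggregate(norm_area ~ bin, per_cell_bin, length)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  data.frame(t_mid_s = mid[match(agg_m$bin, levels(bin))],
             mean_norm_area = agg_m$norm_area,
             sd_norm_area = agg_s$norm_area,
             n_cells = agg_n$norm_area)
}

#' Write / read trace tables
#' @param traces data frame (`cell_id`, `t_s`, `area_um2`) or
#'   `pulsation_sim`.
#' @param path CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "pulsation_sim")) traces <- traces$traces
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) utils::read.csv(path)
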