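#' Amnioserosa pulsation presets
#'
#' Parameters of the synthetic apical-area traces. Each cell's area is
#' \deqn{A(t) = A_0 (1 - c t)(1 + a\,\mathrm{osc}(t)),}
#' a slow linear net contraction modulated by a raised-cosine oscillation
#' whose successive peak-to-peak intervals are drawn i.i.d. from a normal
#' period distribution truncated above twice the frame interval.
#'
#' The named presets encode the published period statistics: wild type
#' 191 +/- 77 s pooled over 85 pulsations of 18 cells, and the pbl mutant
#' 163 +/- 71 s over 106 pulsations of 17 cells (pulsing more frequently
#' and with lower amplitude). Baseline areas, amplitude fractions and the
#' net contraction rate are not published and are set to values typical of
#' amnioserosa cells.
#'
#' @param period_mean,period_sd peak-to-peak period distribution, s.
#' @param amplitude oscillation amplitude as a fraction of baseline (0-1).
#' @param baseline_area initial apical area, um^2.
#' @param contraction_rate net contraction, fraction of area per s.
#' @param n_cells number of cells.
#' @param n_cycles_total pooled peak-to-peak cycles across all cells.
#' @param frame_interval sampling interval, s.
#' @return Object of class `pulsation_preset`.
#' @export
pulsation_preset <- function(period_mean = 191, period_sd = 77,
                             amplitude = 0.15, baseline_area = 120,
                             contraction_rate = 5e-5, n_cells = 18,
                             n_cycles_total = 85, frame_interval = 10) {
  assert_number(period_mean, "period_mean", lower = 1e-9)
  assert_number(period_sd, "period_sd", lower = 0)
  # amplitude 0 is the oscillation-off limiting case (pure trend)
  assert_number(amplitude, "amplitude", lower = 0, upper = 1 - 1e-9)
  assert_number(baseline_area, "baseline_area", lower = 1e-9)
  assert_number(contraction_rate, "contraction_rate", lower = 0)
  assert_count(n_cells, "n_cells", 1L)
  assert_count(n_cycles_total, "n_cycles_total", 1L)
  assert_number(frame_interval, "frame_interval", lower = 1e-9)
  structure(as.list(environment()), class = "pulsation_preset")
}

#' @rdname pulsation_preset
#' @param genotype `"wt"` or `"pbl"`.
#' @export
preset_pulsation <- function(genotype = c("wt", "pbl")) {
  switch(match.arg(genotype),
         wt = pulsation_preset(period_mean = 191, period_sd = 77,
                               amplitude = 0.15, baseline_area = 120,
                               n_cells = 18, n_cycles_total = 85),
         pbl = pulsation_preset(period_mean = 163, period_sd = 71,
                                amplitude = 0.08, baseline_area = 100,
                                n_cells = 17, n_cycles_total = 106))
}

#' Simulate amnioserosa apical-area traces with known peak times
#'
#' Cycles are distributed as evenly as possible over the cells so that the
#' pooled ground-truth peak-to-peak intervals total exactly
#' `n_cycles_total`. The oscillation is a raised cosine between successive
#' ground-truth peaks, so peak positions are exactly controllable; the slow
#' contraction trend shifts the realized area maxima by well under a frame
#' interval.
#'
#' @param preset a [pulsation_preset()].
#' @param seed integer seed or `NULL`.
#' @return List of class `pulsation_sim`: `traces` data frame (`cell_id`,
#'   `t_s`, `area_um2`), `truth` data frame (`cell_id`, `peak_time_s`), and
#'   the preset.
#' @export
simulate_amnioserosa_traces <- function(preset = preset_pulsation("wt"),
                                        seed = NULL) {
  stopifnot(inherits(preset, "pulsation_preset"))
  p <- preset
  base_cycles <- p$n_cycles_total %/% p$n_cells
  extra <- p$n_cycles_total %% p$n_cells
  cycles <- rep(base_cycles, p$n_cells) + c(rep(1L, extra),
                                            rep(0L, p$n_cells - extra))
  with_seed(seed, {
    traces <- vector("list", p$n_cells)
    truths <- vector("list", p$n_cells)
    for (ci in seq_len(p$n_cells)) {
      nc <- cycles[ci]
      if (nc == 0L) next
      gaps <- rnorm_trunc(nc, p$period_mean, p$period_sd,
                          2 * p$frame_interval)
      first <- stats::runif(1, 0.25, 0.75) * p$period_mean
      peaks <- first + cumsum(c(0, gaps))
      # extend half a cycle beyond each end so osc is defined everywhere
      ext <- c(peaks[1] - gaps[1], peaks, peaks[length(peaks)] +
                 gaps[length(gaps)])
      # run half a cycle past the last peak so its falling flank is sampled
      t_end <- peaks[length(peaks)] + gaps[length(gaps)] / 2
      tt <- seq(0, t_end, by = p$frame_interval)
      seg <- findInterval(tt, ext, rightmost.closed = TRUE)
      seg <- pmin(pmax(seg, 1L), length(ext) - 1L)
      u <- (tt - ext[seg]) / (ext[seg + 1L] - ext[seg])
      osc <- cos(2 * pi * u)
      trend <- 1 - p$contraction_rate * tt
      if (any(trend <= 0))
        stop("contraction drives area to zero within the trace")
      area <- p$baseline_area * trend * (1 + p$amplitude * osc)
      traces[[ci]] <- data.frame(cell_id = ci, t_s = tt, area_um2 = area)
      if (p$amplitude > 0)
        truths[[ci]] <- data.frame(cell_id = ci, peak_time_s = peaks)
    }
    structure(list(traces = do.call(rbind, traces),
                   truth = do.call(rbind, truths), preset = p),
              class = "pulsation_sim")
  })
}
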