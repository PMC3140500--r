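---
title: "Quantifying dorsal closure dynamics: models, measurements, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dorsal closure dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(closuredyn)
```

## The closure model and its assumptions

Dorsal closure is modeled as two circular leading-edge arcs of chord $W$
(the width: the anterior–posterior distance between the two canthi, where
the opposing sheets meet and zipper) and sagitta $H/2$ each, so $H$ is
the maximal dorsoventral distance between the converging sheets. For a
circular arc the tangent–chord angle at the canthus is

$$\theta = 2\arctan(H/W),$$

and the dynamics are

$$\frac{dH}{dt} = -v, \qquad \frac{dW}{dt} = -\frac{k_z}{\tan\theta},$$

with $v$ the sheet translocation velocity and $k_z$ the zipping rate
constant, both in µm/s. Under this constant-curvature geometry the
zipping term contributes rate $k_z$ to $-dH/dt$, so the fraction of the
closure speed attributable to zippering is $f_z = k_z / v$; we adopt this
ratio as the operational definition and clip reported values into
$[0, 1]$ while retaining the raw ratio. Assumptions worth keeping in
mind: $v$ and $k_z$ are constants (no time dependence), the arcs stay
circular, and the geometry is meaningful only while the hole is wider
than tall ($H < W$, i.e. $\theta < \pi/2$) — as $\theta \to \pi/2$ the
zipping term vanishes, and the model cannot drive $W$ below $H$.

The model's two degenerate regimes are handled explicitly. As
$\theta \to 0$ (flat arcs, the end of closure) $dW/dt$ diverges; the
integrator caps each step's $|\Delta W|$ at the current $W$, so an
extreme zipping step zips the hole shut (flagged `zipped_shut`) rather
than producing a non-finite width. A hole is declared closed at the first
frame with $H \le \varepsilon_H$ (default 1 µm) or
$W \le \varepsilon_W$.

## Numerical choices

The forward model is integrated with fixed-step RK4 at step
$\min(1\,\mathrm{s}, \Delta t/60)$: the zipping term stiffens as
$\theta \to 0$, and this step keeps trajectories within $10^{-3}$ µm of a
0.01 s reference integration (tested against an independently written
Euler oracle). $dW/dt$ for the zipping fit is estimated by central
differences (forward/backward at the ends) — simple and directly
testable against a brute-force grid search over $k_z$, which the
regression matches to one grid step ($10^{-5}$ µm/s).

The velocity fit window keeps frames with
$\varepsilon_H < H < 0.9\,H_{\max}$: the earliest frames still carry
germ-band-retraction remnants and the terminal flat-arc frames violate
the model. The zipping window additionally requires
$\tan\theta > 0.05$, and the no-intercept form reflects the model's lack
of an offset term (an intercept variant is logged as a diagnostic only).

## What the synthetic generator emulates

No live-embryo movies can ship with the package, so every input is
synthesized with known ground truth.

**Closure movies.** Two arcs of the model geometry are rasterized as a
bright band (default thickness 3 px, intensity 0.8 on a 0.1 background),
blurred with a Gaussian PSF (σ = 1.5 px), with additive Gaussian read
noise and optional Poisson shot noise. The default pixel size is
0.5 µm/px and the default screen-mode acquisition is one frame per
12 min over 13 h; the quantitative kinematic analyses use a 4-minute
interval, which gives the central-difference derivative estimates enough
frames across the full velocity grid while keeping per-point derivative
noise low. The movies' µm/px scale and the high-resolution frame
intervals are package choices — realistic for a 10× screening objective
and a confocal follow-up — not values with an external source.

**Pulsation traces.** Each amnioserosa cell's apical area is
$A(t) = A_0 (1 - ct)(1 + a\,\mathrm{osc}(t))$ with a raised-cosine
oscillation between ground-truth peaks, whose successive peak-to-peak
intervals are i.i.d. normal (truncated above twice the frame interval).
The wild-type preset uses 191 ± 77 s over 85 pooled cycles in 18 cells;
the pbl-mutant preset 163 ± 71 s over 106 cycles in 17 cells, with a
lower amplitude (0.08 vs 0.15 of baseline) matching the mutant's weaker
pulsing. Baseline areas (120 / 100 µm²), the amplitude fractions and the
slow net contraction rate (5·10⁻⁵ per s) are typical amnioserosa values
chosen once; no published numbers exist for them. Cycles are distributed
over cells so the pooled truth count is exact, and each trace runs half a
cycle past its last peak so the final peak has a falling flank to detect.
The raised cosine makes true peak positions exactly controllable; the
contraction trend shifts realized maxima by well under one frame.

**Protrusion frames.** A horizontal bright band (the leading edge) with
filopodia as 1–2 px straight spurs at angles within ±60° of the edge
normal, lengths drawn from the preset distribution (wild type
4.8 ± 1.4 µm, n = 58; mutant 7.1 ± 1.7 µm, n = 52), and lamellipodia as
half-ellipse flaps. Published lamellipodium counts (n = 13 / 12) match
frame numbers, not blob numbers, so the statistic is per-frame maximal
protrusive area: each frame draws one dominant flap from the preset
distribution (14.5 ± 4.0 / 26.6 ± 7.3 µm²) plus one sub-dominant flap at
50–80% of it. Flaps below roughly half that size are deliberately not
generated: at 0.25 µm/px with a ~1 px PSF, a 4–5 µm² flap is optically
indistinguishable from a blurred spur, and no classifier threshold can
separate what the optics have merged. Protrusions are placed in disjoint
column slots; overlapping placements are redrawn up to a retry limit.

**Screen tables.** Abnormal counts are binomial draws per replicate at
each dsRNA's true penetrance, with 21 embryos scored per replicate (the
screen's average imaging yield).

What the generator does *not* emulate — embryo curvature, stage drift,
label photobleaching, cell-level texture of the amnioserosa, apoptotic
extrusions, protrusion dynamics in time — bounds what passing tests
mean: they validate the measurement pipeline's geometry, detection and
statistics, not its robustness to every artifact of live imaging.

## Measurement design

**Hole segmentation.** Gaussian smoothing (σ = 1 px), Otsu threshold,
removal of sub-50 px speckle, morphological closing (5 px disc) to seal
the canthi; the hole is the largest background component not touching
the border. A frame whose contrast (max − median)/MAD falls below 5 is a
"no signal" error, distinct from a closed hole.

**Extent corrections.** The mask measures the hole's *interior*, but the
model's $W$ and $H$ are defined on the arc centerlines. Height is
corrected by the band half-width (estimated from per-column band pixel
counts) plus a half-pixel boundary term, validated to within 1 px on
noiseless renders. Width is harder: near the canthi the arcs converge at
angle $\theta$ and the band plus the morphological closing swallow the
interior wedge. Two estimators are used: (i) the interior extent plus an
offset-circle correction (the interior ends where a disc of the closing
radius still fits between the bands), and (ii) the x-extent of the edge
band itself — the band ends *are* the zippering ends — minus a
calibrated end-cap term (the band end is a point-like cap whose
threshold crossing sits ~1.2 px inside the lateral band crossing). The
edge-based estimator's bias is independent of $\theta$, which matters
because the zipping regression differentiates $W(t)$; it is preferred
whenever it is at least as large as the interior estimate. Frames whose
interior height is within ~4× the band-plus-closing scale are flagged
unreliable (the blurred bands invade the slit) and excluded from fits.
The band half-width is pooled across the movie — it is a property of the
optics and label, not of the frame — which removes quantization jitter
that the canthus correction would otherwise amplify.

**Shape metrics.** Circularity $4\pi A/P^2$ with a Kulpa-weighted
contour perimeter (0.948 axial / 1.340 diagonal steps; raw chain length
overestimates smooth digital boundaries by up to 8%, which would push a
perfect disc to ~0.91), moment-based eccentricity, and an asymmetry
index: the area imbalance across the line through the two canthi. The
asymmetry index is this package's proxy for the published "misalignment"
phenotype, whose original quantification was never stated.

**Phenotype calls.** Group I when the final height stays above
$\varepsilon_H$ at movie end. Group II flags are z-scores against a
reference built from ≥ 3 wild-type runs: circularity above, aspect
below, each sustained over ≥ 25% of compared frames; $f_z$ below; plus
an absolute asymmetry threshold (0.2). The *narrowed* flag fires on
**low** aspect $H/W$: inefficient zipping leaves $W$ large while $H$
shrinks normally, so the hole becomes a long, abnormally narrow slit and
its aspect runs below the wild-type trajectory — this is the direction
the reduced-$k_z$ phenotype actually produces. Reference standard
deviations are floored at 5% of the mean (0.05 absolute for $f_z$) so a
tight reference set cannot produce degenerate z-scores. Thresholds
($z^* = 2$, $a^* = 0.2$) are defaults; no published numeric criteria
exist.

**Pulse detection.** Moving-average smoothing (30 s window), local
extrema with topological prominence at least 0.1 of the smoothed range,
and alternation pruning (the weaker of two consecutive same-type extrema
is dropped). Periods are successive peak-to-peak intervals pooled over
cells — pooling mirrors published pulse counts of the form "n = 85
pulsations" — with sample standard deviations (n−1) throughout. The
smoothing window and prominence fraction are package defaults; the
original criteria were never stated.

**Protrusion measurement.** The band is removed by morphological opening
with a 63 px horizontal line (longer than any single protrusion), so the
beyond-edge signal is exactly what the opening removes, respecting the
band's local blurred boundary. Components are classified by core width —
maximal inscribed disc diameter minus a blur halo (2.8 px ≈ twice the
combined PSF + smoothing sigma) — with the filopodium/lamellipodium
boundary at 4 px: calibrated between the apparent core width of the
thickest spurs (~3.2 px) and the thinnest generated flaps (~7 px). Every
component is assigned exactly one type. Filopodium length runs from the
band face to the tip: the chord between the skeleton's attachment and
its geodesically farthest point (filopodia are straight; the chord
avoids the orientation-dependent overcount of digital path sums, while
the geodesic with √2 diagonal steps still selects the tip), plus the
spans the thinning erodes at each end and the half-halo root gap, minus
the half-halo tip extension. Single-spur calibration holds vertical
spurs within 0.25 µm and 45° spurs within 10%. Lamellipodium area is the
component pixel count — the blur gain along the free boundary
compensates the strip lost at the base, verified to a few percent on
rendered flaps. Curved filopodia would be underestimated by the chord;
the generator draws straight ones, and real curved spurs are a known
limitation.

**Screen statistics.** Penetrance is kept at full precision and rounded
half-up only for display (21 of 24 → 87.5 → "88"). "Reproducibly
exceeded 30%" is read literally: strict `> 30` on the unrounded value,
for every replicate of a dsRNA; a gene is a candidate when one dsRNA
passes and confirmed when two distinct dsRNAs (targeting different
regions) pass. Whether published per-gene standard deviations run across
injection replicates or across dsRNAs is not stated; replicates are
assumed.

## Problem sizes and determinism

The validation suite uses the velocity grid
$v \in \{0.004, 0.008, 0.016\}$ µm/s with $k_z/v \in \{0, 0.25, 0.5\}$,
rendered noiselessly and at 10% edge-intensity noise, at 4-minute frame
intervals on 0.5 µm/px images — recovery within 5% (noiseless) and 15%
(noisy). Pulsation and protrusion recovery use the published pooled
sample sizes (85/106 cycles, 58/52 filopodia, 13/12 frames). All
stochastic stages draw from R's generator under an explicit seed and are
byte-reproducible; the end-to-end demo report contains no timestamps so
a same-seed rerun is byte-identical.

## Known limitations

The kinematic fit assumes constant $v$ and $k_z$; time-resolved rates
and force inference are out of scope. Width measurement degrades when
the slit height approaches the band width — those terminal frames are
flagged and excluded rather than rescued. Near-circular holes
($H \approx W$) carry about one extra pixel of width uncertainty at the
canthi; they feed shape metrics, not the kinematic grid. The asymmetry
proxy is not the published misalignment measure. Pulsation analysis
assumes pre-extracted area traces (cell segmentation and tracking are
out of scope), and protrusion measurements are per-frame (no temporal
tracking of individual protrusions).
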