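# closuredyn

Quantitative phenotyping of *Drosophila* embryonic dorsal closure from
time-lapse fluorescence movies, for groups running live-imaging RNAi
screens or mutant characterization. During dorsal closure two lateral
epithelial sheets migrate toward the dorsal midline, converge over the
amnioserosa, and zipper together at the two canthi. With the leading edge
fluorescently labeled, the dorsal hole appears as the region bounded by
two bright circular arcs, and the whole process can be reduced to a small
set of kinematic and morphometric numbers.

## The model at the core

The hole is described by its width `W` (maximal distance between the
zippering ends, along the anterior–posterior axis) and height `H`
(maximal distance between the converging sheets). For arcs of chord `W`
and sagitta `H/2`, the canthus angle is `θ = 2·arctan(H/W)`, and closure
follows

    dH/dt = −v            (epithelial sheet translocation)
    dW/dt = −k_z / tan θ  (zippering at the canthi)

with `v` the sheet velocity (µm/s) and `k_z` the zipping rate constant
(µm/s). The fractional contribution of zippering to closure speed is
`f_z = k_z / v`. The package fits `v` by ordinary least squares on
`H(t)`, `k_z` by a no-intercept regression of the central-difference
`dW/dt` on `1/tan θ`, and classifies embryos as normal, Group I (hole
never closes), or Group II (closes with abnormal dynamics: circular hole,
low `f_z`, narrowed hole, asymmetry) against a wild-type reference.

Around that core sit three more quantifications from the same screen:
amnioserosa apical-area pulsation statistics (peak detection, pooled
peak-to-peak periods), leading-edge protrusion morphometrics (filopodium
lengths by skeletonization, lamellipodium areas, per-frame maxima), and
RNAi screen penetrance statistics (per-replicate penetrance, the strict
all-replicates-above-30% candidate rule, second-dsRNA confirmation).

Because live-embryo movies cannot be redistributed, a synthetic-data
generator produces every input with known ground truth: rendered closure
movies (arcs, PSF blur, Gaussian/Poisson noise), pulsatile area traces,
protrusion images, and screen count tables. Every measurement stage is
validated by parameter recovery against that truth.

## Worked example

```r
library(closuredyn)

# simulate a wild-type-like embryo and measure it back
traj <- simulate_closure_trajectory(
  closure_params(v = 0.008, k_z = 0.004, H0 = 60, W0 = 240,
                 frame_interval = 240))
movie <- render_closure_movie(traj, render_params(noise_sd = 0.02), seed = 1)
fit <- fit_closure(measure_stack(movie))
fit
#> <kinematic_fit> v = 0.00806 um/s, k_z = 0.00398 um/s, f_z = 0.493
#>   H-fit RMS = 0.257 um, zipping R^2 = 0.9958
```

The true parameters were `v = 0.008`, `k_z = 0.004`, `f_z = 0.5`: the
movie-level pipeline recovers them within about 1%. The pulsation side:

```r
s <- summarize_pulsation(
  simulate_amnioserosa_traces(preset_pulsation("wt"), seed = 1))
s
#> <pulsation_summary> period 189 +/- 66 s (n = 86); maxima 134.2, minima 100.0 um^2
```

i.e. a pooled mean peak-to-peak period of 189 s over 86 detected cycles,
against a generating distribution of 191 ± 77 s — within two standard
errors.

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate.R` … `06_screen.R`) that generate the synthetic study data
and write all tables under `results/`.

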