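# cellmotion

Quantitative analysis of cell morphodynamics for migration studies:
shape volatility from time-lapse movies, focal-adhesion (FA) turnover from
TIRF microscopy, cortical signal distribution metrics, chemotaxis
statistics, and Young's modulus from AFM force curves. The package is
aimed at cell biologists and image analysts who have mask/intensity
movies (multi-page TIFF), outline tables, or force-distance curves, and
want the published quantities computed reproducibly — plus synthetic-data
generators with recorded ground truth so every estimator can be validated
end to end.

## The statistics at its core

**Shape volatility.** Each frame's cell outline is reduced to the aspect
ratio AR (major/minor axis of the moment-equivalent ellipse, ≥ 1). The
per-interval shape change is the relative increment

    ΔAR_n = AR_n / AR_(n−1) − 1

and the shape volatility of a cell is the sample standard deviation of
its hourly shape changes, σ_AR = sd(ΔAR) — a scale-free measure of
morphological fluctuation, adapted from the volatility of finance.
Migration speed is centroid path length over elapsed time; directional
persistence is displacement over path length; chemotaxis endpoint sets
are tested for uniformity with the Rayleigh test (Z = nR̄², Zar's
finite-n p-value).

**FA dynamics.** TIRF movies are segmented with a 10-px median filter,
Otsu threshold, 3-px binary opening and hole filling; segments are linked
into tracks by pixel overlap. A *stable* adhesion keeps area and
integrated intensity within 10% of their initial values over the whole
movie; the stable fraction is stable/total tracks. Pattern turnover is
the per-frame 2-D correlation with the first frame, summarized by a
double-exponential decay fit A₁e^(−t/τ₁) + A₂e^(−t/τ₂); apparent
assembly/disassembly rates are semi-log slopes of total intensity.

**AFM elasticity.** Approach curves are fitted with the Sneddon conical
model F = (2/π)·tan(α)·E/(1−ν²)·δ², α = 18°, ν = 0.5, from contact to the
1.5 nN trigger, with the cantilever-bending correction δ = (z−z₀) − F/k.

## Worked example

```r
library(cellmotion)

# a synthetic 18-h migration movie with known shape noise and speed
sim <- make_shape_movie(n_frames = 37, ar_noise_sd = 0.1,
                        speed_um_per_h = 10, heading_rad = 0.7, seed = 42)
tr  <- track_shape(sim$movie)
shape_volatility(tr, sampling_interval_h = 1)
#> shape volatility sigma_AR = 0.1703 over 18 intervals of 1 h
migration_speed(tr)          # 10.0 um/h   (generated: 10)
directional_persistence(tr)  # 1.00        (straight heading)

# focal-adhesion stable fraction on a synthetic TIRF movie (truth: 0.4)
fa  <- make_fa_movie(n_stable = 10, n_dynamic = 15, n_frames = 31,
                     intensity_snr = 10, seed = 1)
seg <- segment_adhesions(fa$movie)
stable_fraction(link_tracks(seg), n_frames(fa$movie))$fraction
#> [1] 0.4

# Young's modulus from a generated Sneddon curve (truth: 1000 Pa)
fit_young_modulus(make_force_curve(E_pa = 1000, seed = 1)$curve)
#> Sneddon fit: E = 1000 Pa, z0 = 0.75 um, rms 9.8e-08 nN over 358 samples
```

The hourly volatility of 0.17 on a movie generated with per-frame
(30-min) noise 0.1 is expected: sampling every second frame compounds two
independent multiplicative innovations (√2 × 0.1 ≈ 0.14), plus the
sampling spread of an 18-interval standard deviation.

A command-line front end covering the same pipelines (subcommands
`shape`, `adhesion`, `cortex`, `afm`, `simulate`) is installed at
`system.file("cli", "cellmotion.R", package = "cellmotion")`.

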