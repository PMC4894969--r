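---
title: "Quantifying cell-shape volatility, focal-adhesion dynamics and cortical mechanics with cellmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-shape volatility, focal-adhesion dynamics and cortical mechanics with cellmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmotion)
```

Migrating cells — mesenchymal tumour cells such as MDA-MB-231 are the
motivating system — continuously remodel their outline as protrusions
extend and retract. `cellmotion` quantifies this morphodynamic behaviour
from time-lapse microscopy, together with the focal-adhesion turnover that
accompanies it in TIRF movies, the spatial organization of cortical
signals, and cortical stiffness from AFM indentation. Every analysis has a
matching synthetic-data generator with recorded ground truth, so the whole
pipeline can be exercised and validated without any external data.

## Shape volatility

A cell outline is summarized per frame by the aspect ratio (AR) of its
moment-equivalent ellipse — the ellipse sharing the region's normalized
second central moments, the same construction as ImageJ's *Fit Ellipse*.
AR = major/minor axis is dimensionless and at least 1. The per-interval
shape change is the relative increment

$$\Delta AR_n = \frac{AR_n}{AR_{n-1}} - 1,$$

a construction adapted from the volatility measure of finance, and the
**shape volatility** of a cell is the sample standard deviation
($n-1$ denominator, the spreadsheet *StdDev* convention) of the hourly
$\Delta AR$ series over the experiment:
$\sigma_{AR} = \mathrm{sd}(\Delta AR)$. Because $\Delta AR$ is a ratio,
$\sigma_{AR}$ is invariant to rescaling the AR series by any positive
constant.

Shape movies are conventionally acquired at 2 frames per hour for 18 h
(37 frames). The wording "hourly shape changes" leaves open whether every
frame or every second frame enters the difference; `shape_volatility()`
therefore exposes `sampling_interval_h` (default 1 h, i.e. every second
frame of a 30-min movie) and requires it to be an integer multiple of the
frame spacing. Note that when shape noise acts per frame, hourly sampling
of a 30-min movie measures the one-hour innovation, which for independent
multiplicative per-frame noise is $\sqrt{2}$ times the per-frame scale —
the statistic always refers to its sampling interval.

```{r volatility}
shape_volatility(c(1, 2, 1, 2), sampling_interval_h = 1)
```

Migration kinematics come from the ellipse centroid: `migration_speed()`
divides the total centroid path length by elapsed time (no smoothing is
applied — none is part of the protocol), and `directional_persistence()`
is net displacement over path length, 1 for a straight monotone path. A
zero-length path has no direction; persistence is returned as `NA` with a
warning rather than a silent 0.

Cohort-level coupling between volatility and speed uses Pearson
correlation by default (`volatility_speed_correlation()`); the published
scatter does not state the correlation flavour, so Spearman is available
as an option.

Chemotaxis endpoint sets are tested for directional uniformity with the
Rayleigh test on the mean resultant length $\bar R$: $Z = n\bar R^2$, and
the p-value uses Zar's finite-$n$ correction
$p = \exp\!\left(\sqrt{1 + 4n + 4(n^2 - nZ)} - (1 + 2n)\right)$ (clamped
to $(0,1]$), which behaves better at the $n = 45$ cells per group of the
reference design than the asymptotic $e^{-Z}$; both are reported.

## Focal-adhesion dynamics from TIRF movies

Paxillin-eGFP TIRF movies (30-s intervals, 61 frames in the reference
acquisition) are segmented per frame with the standard recipe:

1. 2-D running median filter, **10-px square window** by default. Even
   windows are applied exactly as specified, with the window spanning
   `floor((w-1)/2)` pixels before and the rest after the centre — a
   documented half-pixel shift; an 11-px window gives the symmetric
   variant.
2. Otsu threshold computed on the exact empirical histogram. The
   threshold is computed **once from the whole filtered time series** by
   default: a per-frame threshold (available via
   `global_threshold = FALSE`) shifts every segment boundary whenever
   other adhesions brighten or fade, which makes genuinely constant
   adhesions appear to change area.
3. Binary opening with a **3-px square kernel**, hole filling, and
   4-connected labelling; segments below `min_area` (default 4 px², a
   single-pixel-noise guard that is not part of the published recipe and
   is configurable) are dropped.

Tracks are formed by linking segments in consecutive frames by pixel
overlap (threshold 0.3), with the overlap measured **relative to the
smaller segment**. Intersection-over-union is available
(`criterion = "iou"`), but it severs the birth and death frames of a
growing adhesion — whose first detected patch is much smaller than its
grown successor — into spurious one-frame tracks, which corrupts the
stable-fraction denominator; overlap-over-smaller is the convention of
dedicated focal-adhesion tracking tools. There is no gap closing and no
split/merge handling, consistent with the dense 30-s sampling.

A track is a **stable adhesion** when it spans the entire movie and
neither its area nor its integrated intensity ever deviates more than 10%
(inclusive) from the initial value. The stable fraction divides the
number of stable adhesions by **all tracks ever observed** — the
denominator wording in the field is ambiguous, so the choice is recorded
in the result object.

Pattern turnover is summarized by correlating each binary adhesion mask
with the first frame (`mask_autocorrelation()`; intensities are also
accepted) and fitting $A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ without an
offset — a correlation decays to 0 at long lag — by bounded
Levenberg-Marquardt least squares with multi-start initialization over a
grid of time-scale pairs, components returned with
$\tau_1 \le \tau_2$. Non-decaying input is flagged (`no_decay`), never an
error. Apparent assembly/disassembly rates come from the slopes of the
semi-logarithmic total-intensity plot: the series is median-smoothed
(window 5, ends kept), the smoothed maximum located, and
$k_a$/$k_d$ fitted on the rising/falling windows excluding the smoothing
plateau around the peak, whose samples the running median distorts. A
monotone series reports the absent phase as `NA`, not 0.

## Cortical signal metrics

`edge_positive_fraction()` reconstructs the "proportion of cell edge
positive for a signal" measurement, for which no published recipe exists:
boundary pixels (mask pixels with a background 4-neighbour) are scored by
the mean signal in the inward band (default width 1 µm) around them and
called positive above a threshold — Otsu over all band pixels by default,
which makes the fraction invariant to positive rescaling of the signal;
an absolute threshold is available. `edge_distance_profile()` bins signal
by the exact Euclidean distance to the cell edge up to 15 µm (default),
reporting per-bin mean intensity and pixel counts; normalization to the
whole-cell mean is optional because the published axis normalization is
unspecified.

Kymographs sample intensity along a fixed line per frame (bilinear
interpolation, averaged across the line width).
`protrusion_period()` extracts the boundary position per time point with
sub-pixel interpolation of the threshold crossing, removes a linear
drift, and accepts the first positive-lag autocorrelation maximum above
the white-noise band $1.96/\sqrt{n}$. Residual oscillations below 1 px
are ignored: a smooth sub-pixel drift otherwise leaves a periodic
pixel-rounding sawtooth that is an imaging artifact, not a
protrusion-retraction cycle.

## AFM elasticity

Cortical stiffness is estimated from approach force curves with the
Sneddon solution for a rigid cone indenting an elastic half-space,

$$F(\delta) = \frac{2}{\pi} \tan(\alpha)\, \frac{E}{1-\nu^2}\, \delta^2,$$

with tip half-angle $\alpha = 18°$, Poisson ratio $\nu = 0.5$ and a
0.06 N/m cantilever by default, fitted from contact to the trigger force
(1.5 nN; 0.6–3.0 nN are meaningful settings). Indentation is the piezo
travel minus the cantilever bending, $\delta = (z - z_0) - F/k$ — the
correction can be disabled to mirror analyses that fit the raw
separation. The contact point $z_0$ minimizes the joint residual of a
zero baseline before contact and the Sneddon quadratic after, scanned
over the sample grid and then refined continuously between grid points.
Given $z_0$, $E$ follows from a no-intercept linear regression of $F$ on
$\delta^2$ — exact for the Sneddon form and fully deterministic. A fit is
flagged poor when its residual RMS exceeds
$3\max(\text{baseline noise SD},\ 0.5\%\ \text{trigger})$, e.g. when the
curve follows spherical (Hertz) rather than conical contact.

```{r sneddon}
sneddon_force(1, E_pa = 1000)  # nN at 1 um indentation
fit_young_modulus(make_force_curve(E_pa = 1000, seed = 1)$curve)
```

## The synthetic-data generators

Each generator returns its data plus a `synthetic_truth` record (and can
serialize it as `truth.json`); regeneration from the same seed is
bit-identical and the caller's RNG stream is untouched.

* `make_shape_movie()` rasterizes an ellipse of constant area whose AR
  follows the multiplicative random walk
  $AR_n = AR_{n-1}(1+\varepsilon_n)$,
  $\varepsilon_n \sim N(0, \sigma)$ truncated above $-0.9$ — chosen so
  the innovations are exactly the $\Delta AR$ series and the target
  volatility is analytic — with optional sinusoidal modulation, while
  the centroid translocates at constant speed. The realized AR is
  clamped to $[1, 8]$ so the cell stays rasterizable; the truth records
  the realized series, so recovery tests are unaffected by clamping.
  Defaults (37 frames at 2/h, 1000 µm² area, 10 µm/h, 0.65 µm/px) mirror
  a phase-contrast migration assay at 10x magnification.
* `make_fa_movie()` places non-overlapping disk adhesions on a jittered
  grid: stable spots keep constant intensity; dynamic spots appear at
  staggered onsets, grow exponentially ($k_a$, default 0.3/min) to a
  peak and decay ($k_d$, default 0.15/min), so the population intensity
  shows distinct assembly and disassembly phases over the 30-min movie.
  Pixel values are integer camera counts; noise SD is amplitude/SNR.
* `make_chemotaxis_tracks()` draws i.i.d. von Mises step headings
  (Best-Fisher sampler) about the gradient direction for 45 cells by
  default; $\kappa = 0$ is the isotropic null, $\kappa \to \infty$ gives
  straight paths with persistence 1.
* `make_force_curve()` inverts the cantilever-bending relation exactly,
  so the generated curve satisfies $F = c\,((z-z_0) - F/k)^2$ and the
  noiseless fit is self-consistent by construction.
* `make_cortex_image()` paints a boundary band over a known arc fraction
  and/or an interior ring at a known depth on a disk cell.

What these generators deliberately do **not** emulate: point-spread
blurring, camera gain and shot noise, multi-cell scenes, adhesion
splitting/merging, and hand-traced outline irregularity. Passing
recovery tests therefore demonstrates that the estimators invert their
own forward models at realistic noise levels — not that segmentation or
tracking is robust to every artifact of real microscopy.

## Numerical choices and problem sizes

* Otsu thresholds use the exact value histogram (no binning); foreground
  is strictly above the threshold, ties resolve to the smallest
  maximizer. A constant sample has no threshold (`NA`), handled
  explicitly at every call site.
* The even-window median filter and the morphological border conventions
  (erosion ignores out-of-image positions; hole filling floods the
  4-connected background from the border) are fixed and tested against
  brute-force set-operation references on small images.
* The double-exponential fit bounds amplitudes to $[0, 2]$ and time
  scales to $[10^{-4}, 10^{3}] \times$ the observation window; a fit
  whose time scales exceed 10 times the window is reported as
  non-decaying.
* Validation suites run at desk scale: 1000-interval AR series for
  volatility recovery, one 61-frame ~240-px TIRF movie per
  stable-fraction check, 50-cell cohorts for the volatility-speed
  correlation, 50 seeded replicates for noisy rate and modulus recovery,
  and 1000 isotropic cohorts of 45 endpoints for the Rayleigh
  calibration. These sizes give standard errors comfortably inside the
  documented tolerances.

## Known limitations

* Cells are assumed pre-segmented (binary masks); no phase-contrast
  segmentation is provided, matching a workflow where outlines are
  hand-traced.
* One cell per movie (the largest component per frame); colliding cells
  are out of scope.
* Track linking has no gap closing: an adhesion that drops below
  threshold for one frame starts a new track.
* The protrusion-period detector reports the first significant
  autocorrelation peak; strongly aperiodic protrusive activity yields
  `NULL` rather than a spectrum.
* Movie TIFF storage is 16-bit unsigned (8-bit for masks): integer
  counts round-trip exactly, arbitrary floats are rounded to counts.
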