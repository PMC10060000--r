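---
title: "Models and methods behind desimrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind desimrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desimrm)
```

desimrm processes targeted DESI mass spectrometry imaging data acquired in
multiple reaction monitoring (MRM) mode on a triple quadrupole: per-transition
chronograms recorded line by line are turned into ion images, corrected for
line-to-line jitter, summarised per region of interest, and classified per
pixel. Because such data sets are rarely public, the package also ships a
mechanistic simulator of the desorption/ionization process, so every stage of
the chain can be exercised — and tested — against synthetic data with known
ground truth. This vignette records the models, the tunable parameters, and
the design decisions.

## Acquisition timing and geometry

An MRM cycle visits every transition once. We model its period as

$$T = \sum_i (d_i + o_t) + o_s,$$

with $d_i$ the per-transition dwell time, $o_t$ a per-transition switching
overhead and $o_s$ a fixed per-cycle overhead (all in ms). Instrument
overheads are rarely printed; the default $o_t = 3.25$ ms, $o_s = 0$ was
chosen once so that a 16-transition method at 3 ms dwell cycles at exactly
10 scans/s, consistent with the standard dwell-to-rate pairing for such
methods (59/27/9/3 ms for 1/2/5/10 pixels per second). Both overheads are
ordinary config fields: a 50-transition method at 4 ms dwell cycling at
2 pixels/s implies $o_t = 6$ ms, and users with such methods simply set it.
With a moving stage one cycle is one pixel, so the pixel width is stage speed
times cycle period (100 μm at 100 μm/s and 1 scan/s); the pixel height is the
line spacing. Pixel (0,0) sits at the top-left of the first line, x along
stage motion, y across lines, with half-open pixel intervals.

Intensities are stored as non-negative floats with no saturation model.
Dwell-time normalization divides accumulated counts by the dwell time in
seconds; the operation is flagged on the data set and a second application is
an error, because double-normalized images are a classic silent mistake.

## The desorption/ionization model

The simulator reduces the desorption/ionization process to three coupled
stages with a single solvent state:

* **Solvent film.** The spray maintains a film $V$ on the surface:
  $dV/dt = \text{solvent\_in} - k_{\text{removal}} V$. Dissolution requires
  rehydration: it is enabled only above the wetting threshold $V_{\text{wet}}$,
  with saturating gain $s(V) = \max(0, V-V_{\text{wet}}) /
  (K_{\text{sat}} + \max(0, V-V_{\text{wet}}))$.
* **Dissolution.** Surface analyte $A_i$ enters the film at
  $k_{\text{diss},i}\, A_i\, s(V)$ — the rate constant is the property that
  separates fast-dissolving small-molecule drugs from slow structural
  lipids.
* **Droplet transfer.** Dissolved analyte $D_i$ is carried into secondary
  droplets at $k_{\text{des}} D_i$; the detected rate is
  $\eta_i k_{\text{des}} D_i$, integrated over each transition's dwell
  window to per-scan counts, optionally with a Poisson draw per scan.

An optional charge-competition step caps the total detected rate at a shared
ion budget $I_{\max}$: each analyte is scaled by
$\min(1, I_{\max} / \sum_j w_j\, \text{raw}_j)$. It is off by default
(`i_max = Inf`).

### Frozen defaults and their calibration

Class defaults are $k_{\text{diss}} = 3.0$/s (drug), $0.8$/s (lipid),
$1.5$/s (other), $k_{\text{des}} = 5$/s, $\eta = 10^4$ counts/amount. The
spray constants (`solvent_in` 1.0/s, `k_removal` 0.25/s, `v_wet` 0.5,
`k_sat` 1.6, in arbitrary film-volume units) were calibrated **once**, by a
coarse grid search over physically plausible values, to place the static
phase structure where targeted DESI-MRM platforms observe it: a wetting
delay of about 0.5 s, fast-dissolving drugs peaking between 1 and 2 s and
structural lipids between 2 and 3 s at 10 scans/s. They have been frozen
since; the acceptance suite re-measures the peak times from the frozen
defaults rather than the other way around.

```{r static, eval = FALSE}
tr <- transition_table(id = c("drug", "lip"),
                       analyte_class = c("drug", "lipid"),
                       precursor_mz = c(472.3, 760.6),
                       product_mz = c(436.3, 184.1), dwell_ms = 3)
cfg <- acquisition_config(tr, inter_transition_ms = 47)  # 10 scans/s
sim <- simulate_static(spray_model(), kinetics_table(tr), cfg,
                       duration_s = 10)
autoplot(sim)
```

### Integration scheme

The states are advanced on a fixed 1 ms grid (refined to dwell/4 for very
short dwells; a coarser user-supplied step triggers a warning) with
exponential operator splitting: the film relaxation, the dissolution decay
$A \to A e^{-k_{\text{diss}} \int s\,dt}$ and the droplet transfer each use
their exact exponential update within a step, with $s$ evaluated from the
mid-step film volume. Two properties motivated this choice over a classical
fixed-step Runge–Kutta scheme: every transfer moves mass between pools
without creating or destroying it, so the balance
(remaining + dissolved + desorbed = initial) holds to machine precision at
every step rather than to integrator tolerance; and the stiff droplet pool
($k_{\text{des}} = 5$/s) is unconditionally stable. The splitting error is
first order in the step but at 1 ms is far below the 0.1–0.5% level; the
test suite cross-checks the trajectories against an independent fixed-step
RK4 solution (deSolve) at matching times.

### Moving-stage mode

`simulate_image()` moves a uniform-disc footprint (default 150 μm) along
each line at the stage speed. The film is carried with the sprayer and
starts dry at each line start — separate line scans re-wet fresh tissue —
while surface depletion is per tissue cell and persists across lines, so a
footprint wider than the line spacing re-samples partially exhausted tissue
(flagged as cross-line bleed). Internally each cell's coverage interval is
precomputed and its depletion integrated analytically against the film
history, which makes the dynamic mode exact under the splitting scheme and
fast enough for property-based testing.

Two printed regimes anchor the dynamic behaviour. At slow speeds the swept
tissue is exhausted under the footprint, so the per-scan signal is
proportional to the area swept per cycle: doubling the stage speed from 100
to 200 μm/s doubles the signal. With the frozen wetting constants this
complete-extraction regime needs a residence time a 150 μm footprint does
not provide at those speeds, so the doubling check runs with a 600 μm
footprint; the ratio, not the absolute level, is the observable. At high
speeds the per-analyte flux saturates at
$\rho\,w\,k_{\text{diss}}\,s_\infty\,d$ — monotone in speed for any single
analyte — so the observed *decrease* of lipid signal from 500 to
1000 μm/s while drugs still rise cannot be a single-analyte kinetic effect
in this model. It emerges from charge competition: the fast-dissolving
drugs' rising raw signal claims a larger share of a finite ion budget. The
corresponding test therefore enables `i_max`; whether the real instrument's
oscillating and anticorrelated traces reflect competition or spray
instability is not decidable from chronograms alone, and we model only the
competition mechanism.

### Line jitter

Jitter is modelled as the acquisition window starting a whole number of
cycles early or late relative to stage motion: each line's recorded scans
are the true per-position signal shifted by an integer offset drawn
uniformly from $\{-j_{\max},\dots,+j_{\max}\}$. Ground-truth images always
record the unshifted, noise-free expected rates. A single master seed fans
out into named substreams (phantom, jitter, noise, folds) so that toggling
the Poisson noise does not alter the jitter draws.

## Image reconstruction and re-alignment

`reconstruct()` maps scan *i* of line *l* to pixel (row *l*, column *i*),
dwell-normalizes, pads ragged line ends with `NA` and leaves a warning (and
an `NA` row) for transitions missing on a line. Missing values are excluded
from correlation, percentiles and ROI statistics, and render black.

`realign_lines()` estimates each line's integer offset by normalized
cross-correlation of a reference profile — by default the sum of all
channels, a TIC-like trace that stays informative when individual drug
channels are sparse; a single-channel reference is available when one
channel dominates — against a consensus template, the per-pixel median
across lines. The template is rebuilt from the corrected lines and the
estimates refined for up to four rounds, re-centering the offsets on their
median each round so the search range keeps its headroom. The median makes
the template robust to one aberrant line and, because random offsets cancel
in it, approximately anchors the absolute pixel frame. Exact anchoring is
impossible in principle: mutual alignment cannot see a translation applied
to every line at once, so simulated-jitter recovery is scored net of the
median frame shift (`jitter_recovery()`). Correlation ties break toward the
smaller absolute shift, then toward the negative one, which in particular
pins featureless profiles at zero. Shifts reposition pixel values without
changing them. Sub-pixel alignment is deliberately out of scope: the jitter
mechanism is integral cycles, and integer shifts cannot blur.

Relative scaling for display divides by the 99th percentile of the finite
pixels by default (a single hotspot then clamps instead of crushing the
dynamic range; `method = "max"` is available), records the scale, and clamps
to [0, 1]; overlays compose up to three scaled channels additively in RGB.

## ROI statistics

ROIs are boolean masks; `random_rois()` places non-overlapping squares
uniformly at random fully inside a region, deterministically per seed. The
conventional "mean of 36 pixels" sampling unit is realised as a 6 × 6
square by default — the shape is a documented assumption, the count is the
contract. Group comparisons use the two-tailed Mann–Whitney test with
mid-ranks: exact by full enumeration of rank assignments when the smaller
group has at most 8 values (exactness under ties is why we enumerate
ourselves rather than call `wilcox.test()`, which refuses ties in exact
mode; the two agree wherever both are exact), and the tie-corrected normal
approximation with continuity correction otherwise. Fold change is
mean(b)/mean(a), undefined (with a warning) for a zero baseline.
Significance is reported at the conventional 0.05 and 1e-4 thresholds; raw
p values are returned and no multiple-testing correction is applied, since
per-figure raw p values with stated thresholds are the field's reporting
convention here.

## Pixel classification

`mmc_fit()` implements maximum margin criterion projection: channels are
z-scored (parameters stored in the model), the between-class scatter
$S_b$ (class-mean deviations weighted by class size) and pooled
within-class scatter $S_w$ are formed, and the projection is the top-$d$
eigenvectors of the symmetric matrix $S_b - S_w$ — no inversion of $S_w$,
so collinear channels are harmless. $d$ defaults to one less than the
number of classes; eigenvector signs are fixed so each column's
largest-magnitude entry is positive. The criterion defines the projection
but not the classifier, so in the projected space we use the natural
choice: nearest class mean by Mahalanobis distance under the pooled
projected covariance (with a tiny ridge so point-like classes stay
well-defined). A pixel whose smallest squared distance exceeds the 0.999
chi-squared quantile at $d$ degrees of freedom is `"unclassified"` and
renders black in segmentation maps — the published workflow removes such
pixels as background but states no rule, so the chi-squared cutoff is our
documented one.

`pls_da_fit()` is NIPALS PLS2 on z-scored channels against centered one-hot
class codes, with deflation after each component (successive scores are
orthogonal by construction) and prediction by the largest predicted class
code. Two components are the default for a targeted panel of tens of
channels; requests beyond the rank truncate with a warning.

`crossvalidate()` supports the two fold schemes used for tissue
classification: `random_subset` stratifies pixel folds by class
(within-sample validation), `by_sample` assigns whole samples to folds
(inter-sample validation). With fewer samples than folds — e.g. a 5-sample
cohort under 10-fold CV — only as many non-empty test folds exist as
samples, and accuracy pools over those; this is how a "10-fold inter-sample"
protocol degenerates on small cohorts, and we report it as such. Pooled
accuracy counts correctly labeled, non-rejected test pixels; rejected
pixels are excluded from the denominator and reported separately, so both
conventions (including or excluding rejections) can be recovered from the
result object. If a training fold loses a class entirely, the model is
refit on the remaining classes with a warning; a single-class training fold
predicts that class.

## What the synthetic data do and do not show

The phantoms emulate the spatial contrasts of the intended applications —
periportal versus centrilobular zonation for drug distribution, concentric
kidney regions, blob-shaped tumor nests in stroma, and plain labeled pixel
tables with controlled class separation, per-channel effect sizes,
within-region coefficient of variation, and (for cohorts) sample-level
random mean shifts. They deliberately omit: chemical noise and isobaric
background, matrix effects varying with tissue type, spatial
autocorrelation of biological variation beyond region structure,
instrument drift within a run, and any H&E-registration error in the
annotations. Passing tests therefore demonstrate that the algorithms are
correct against their own data model — e.g. that jitter re-alignment
recovers injected offsets, or that cross-validated accuracy reaches the
Bayes ceiling of the configured separation — not that real tissue data will
reach the same figures. One consequence worth naming: at a class-mean
separation of 3 within-class SD on 3 of 14 channels, the two-class Bayes
error is about 0.5%, so a correct classifier scores ~99.5%, not 100%;
exact 100% requires genuinely separable classes, which the suite checks
with a larger separation.

## Problem sizes and runtime choices

The test and acceptance runs use desk-scale configurations chosen to keep
the whole suite fast while leaving each effect measurable: static runs of
10–30 s at 10 scans/s; image simulations of 1–25 lines at 12–100 μm pixel
pitch; jitter recovery on 25 lines (the published line count for the
dwell-time series) with offsets up to ±4 px; classification on 500–1500
pixels per class over 14 channels. The dynamic-mode doubling check uses a
single line of 4 mm with a 600 μm footprint; the high-speed contrast uses
25 mm lines so the film reaches quasi-steady state within the measured
window at both speeds.

## Known limitations

* The kinetic model is deliberately minimal: no electrospray physics, no
  solvent-composition effects, no lateral diffusion in tissue, a hard
  wetting threshold rather than a rehydration continuum, and a single
  global dissolved pool per analyte in dynamic mode.
* The film is reset at each line start; any persistent wetness between
  adjacent lines is ignored except through surface depletion.
* Oscillations in dynamic traces are reproduced only insofar as charge
  competition plus surface heterogeneity produce them; no dedicated
  oscillator term exists, and spray instability is not modelled.
* Re-alignment is integer-pixel and one-dimensional; co-registration to
  histology and interpolation to finer grids are out of scope.
* Ion images and ground truth export as plain CSV grids and PNG overlays
  plus a JSON sidecar; no imzML writer is included.
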