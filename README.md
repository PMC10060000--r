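# desimrm

Targeted DESI mass spectrometry imaging on a triple quadrupole trades full
spectra for a handful of MRM transitions — one precursor→product pair per
analyte — and buys speed: with short dwell times the instrument cycles at up
to 10 pixels per second while the stage scans the tissue line by line. The
raw data are *chronograms* (intensity versus time per transition per line),
and turning them into interpretable ion images takes a small processing
chain: acquisition timing and geometry, dwell-time normalization,
chronogram-to-image reconstruction, correction of the line-to-line jitter
that de-synchronized stage starts introduce, region-of-interest statistics,
and supervised pixel classification into tissue types.

desimrm implements that chain for R, tidyverse-style (tibbles in and out,
`autoplot()` for every result type, broom-style `tidy()`/`glance()` for
fitted models), together with a mechanistic simulator of the
desorption/ionization process itself, so the whole pipeline runs — and is
tested — without instrument data.

## The models in brief

**Timing/geometry.** A scan cycle visits every transition once:
`T = Σ(dwell + inter_transition) + per_scan` (ms). One cycle = one pixel, so
pixel width = stage speed × `T` (100 μm at 100 μm/s and 1 scan/s); pixel
height = line spacing.

**Desorption kinetics.** A solvent film `V` builds on the tissue
(`dV/dt = solvent_in − k_removal·V`); above a wetting threshold, surface
analyte dissolves at `k_diss·A·s(V)` with saturating gain `s(V)`, and the
dissolved pool transfers into secondary droplets at `k_des·D`; detected
signal is `η·k_des·D`, integrated per dwell window, with optional Poisson
counting noise and optional charge competition against a shared ion budget.
Fast-dissolving drugs (`k_diss` = 3.0/s) peak at 1–2 s under a static spray;
structural lipids (0.8/s) at 2–3 s.

**Re-alignment.** Integer-pixel normalized cross-correlation of each line's
TIC-like profile against an iterated across-line median template; shifts
reposition pixels, never change them.

**Statistics & classification.** Exact (enumerated, tie-safe) two-tailed
Mann–Whitney tests with fold changes for ROI comparisons; maximum margin
criterion projection (eigenvectors of `S_b − S_w`) with Mahalanobis
nearest-class-mean assignment and chi-squared background rejection; NIPALS
PLS-DA; k-fold cross-validation with pixel-stratified or whole-sample folds.

## Worked example

Static-spray kinetics with the frozen class defaults, sampled at 10 scans/s:

```r
library(desimrm)
library(dplyr)

tr0 <- transition_table(id = c("drug", "lip"),
                        analyte_class = c("drug", "lipid"),
                        precursor_mz = c(472.3, 760.6),
                        product_mz = c(436.3, 184.1), dwell_ms = 3)
cfg0 <- acquisition_config(tr0, inter_transition_ms = 47)  # 10 scans/s
sim0 <- simulate_static(spray_model(), kinetics_table(tr0), cfg0,
                        duration_s = 10)
as_tibble(sim0) |> group_by(transition_id) |>
  summarise(peak_s = time_s[which.max(intensity)])
#>   transition_id peak_s
#> 1 drug            1.50
#> 2 lip             2.25
```

The drug-like channel peaks at 1.50 s and the lipid-like channel at 2.25 s:
dissolution speed, not abundance, sets the phase timing, which is why stage
speed can be tuned for or against each analyte class.

A full imaging run on a synthetic liver lobule phantom — drug-like signal
periportal, lipid-like centrilobular — with line jitter and counting noise:

```r
ph  <- make_phantom("zonated_liver",
                    params = list(width_um = 2000, height_um = 1600,
                                  grid_um = 50, lobule_um = 500), seed = 42)
tr  <- transition_table(id = c("drugA", "lipB"),
                        analyte_class = c("drug", "lipid"),
                        precursor_mz = c(472.3, 786.6),
                        product_mz = c(436.3, 184.1), dwell_ms = 9)
cfg <- acquisition_config(tr, stage_speed_um_s = 500, line_spacing_um = 100,
                          line_length_um = 2000, n_lines = 16)
sim <- simulate_image(spray_model(), kinetics_table(tr), ph, cfg,
                      jitter_px_max = 3, noise = TRUE, seed = 42)
al  <- realign_lines(reconstruct(sim$lineset), max_shift_px = 5)
jitter_recovery(al$offsets, sim$injected_jitter_px)
#>   frame_shift_px recovery_rate
#> 1              0             1
```

All 16 injected line offsets are recovered exactly. Zone statistics on the
re-aligned drug image (zone 1 = periportal, zone 3 = centrilobular):

```r
z1 <- al$images$drugA$grid[sim$labels == 1]
z3 <- al$images$drugA$grid[sim$labels == 3]
compare_groups(z3[is.finite(z3)], z1[is.finite(z1)])
#>    n_a   n_b      u  p_value fold_change method        significance
#>  1 864   777 171804 1.27e-65        2.49 normal_approx ***
```

The drug channel is 2.5-fold enriched periportally (p ≈ 1e-65, two-tailed
Mann–Whitney). Finally, cross-validated pixel classification on a
two-class pixel table with 3-SD class separation on 3 of 14 channels:

```r
px <- make_phantom("two_class_pixels",
                   params = list(n_per_class = 500, n_channels = 14,
                                 separation = 3, n_sep_channels = 3),
                   seed = 42)
crossvalidate(px, mmc_fit, k = 10, scheme = "random_subset", seed = 42)
#> <cv_result> random_subset, k = 10 | pooled accuracy 99.7% (1000 test px, 1 rejected)
```

99.7% pooled accuracy is this configuration's Bayes ceiling — the one
rejected pixel is reported separately, not silently counted either way.

A YAML-configured end-to-end pipeline (simulate → reconstruct → align →
ROI stats → classify → report) with a reproducibility manifest is available
as `run_pipeline()`; a ready-made configuration ships at
`system.file("pipeline", "demo.yaml", package = "desimrm")`, and
`inst/scripts/desimrm-pipeline.R` wraps it for the shell.

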