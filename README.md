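# punctascan

Quantification of fluorescent puncta along a neurite from calibrated
micrographs, built for measurements like GLR-1::GFP accumulation in the
*C. elegans* ventral nerve cord, where tagged receptor clusters appear as
bright puncta whose intensity, width and spacing carry the biology.

Given a Z-stack (or single image) and a user-drawn cord path, the
pipeline:

1. collapses the stack by **maximum-intensity projection** and extracts a
   calibrated **linescan** along the path (bilinear sampling, mean over a
   perpendicular band);
2. detects puncta on the linescan by **Gaussian smoothing (σ = 0.5 px)**,
   **Phansalkar local adaptive thresholding** (window radius 2 px) and a
   **minimum-size filter (10 px)** — the published macro settings. The
   Phansalkar threshold on the min–max-rescaled intensity is
   `t = m·(1 + p·e^(−q·m) + k·(s/r − 1))` with k = 0.25, r = 0.5, p = 2,
   q = 10, computed from the local window mean `m` and SD `s`;
3. measures each punctum: peak intensity, **peak-to-bead** ratio (peak
   divided by the session's 0.5 µm calibration-bead intensity, cancelling
   lamp drift), **FWHM** in µm (half level between a background baseline
   and the peak, crossings linearly interpolated), and per animal the
   **density per 10 µm** of cord;
4. compares genotype groups on per-animal values: **Shapiro–Wilk**
   normality gate (reported, never used to switch tests), two-sample
   **Kolmogorov–Smirnov** test (exact p for small groups), percent change
   of means, and wild-type-normalized values for plotting.

A synthetic-data generator (`synthetic_spec()`, `generate_animal()`,
`generate_study()`) renders cords with known planted puncta — Gaussian
bumps with controllable FWHM, amplitude and Poisson density, plus noise
and a bead scalar — so the whole chain is testable without micrographs.

## Worked example

Simulate a study mimicking a wider/brighter/sparser mutant (13 wild-type
vs 28 mutant-like animals; width ×1.5, amplitude ×1.4, density ×0.6),
analyze it, and compare the groups:

```r
library(punctascan)

spec <- synthetic_spec(width_effect = 1.5, amplitude_effect = 1.4,
                       density_effect = 0.6, seed = 1L)
dir <- file.path(tempdir(), "demo")
generate_study(spec, dir)

res <- analyze_study(file.path(dir, "sample_sheet.csv"), run_config())
res$animals[1:3, c("animal_id", "genotype", "n_puncta",
                   "mean_peak_to_bead", "mean_fwhm_um", "density_per_10um")]
#>   animal_id genotype n_puncta mean_peak_to_bead mean_fwhm_um density_per_10um
#> 1 wt_01     wt             18             0.779         1.13             1.80
#> 2 wt_02     wt             14             0.712         1.03             1.40
#> 3 wt_03     wt             13             0.735         1.07             1.30

compare_all_metrics(res$animals, "wt", "mut")[
  , c("metric", "n_wt", "n_mut", "percent_change", "ks_D", "ks_p")]
#>              metric n_wt n_mut percent_change      ks_D         ks_p
#> 1 mean_peak_to_bead   13    28       29.26750 0.9285714 1.191822e-08
#> 2      mean_fwhm_um   13    28       45.78072 0.9230769 1.486940e-08
#> 3  density_per_10um   13    28      -39.07785 0.8873626 5.249693e-08
```

Each animal row is one worm: its punctum count, mean peak-to-bead
intensity ratio, mean punctum width in µm, and puncta per 10 µm of cord.
The comparison rows show the mutant-vs-wild-type percent change of the
per-animal means and the KS statistic/p-value: the planted effects are
recovered in direction (wider and brighter puncta, lower density) and
all three contrasts are significant at these group sizes.

Real data enter through a sample sheet CSV (columns `file, animal_id,
genotype, bead_intensity, cord_path_file, um_per_px`) pointing at
grayscale TIFFs and cord paths (ImageJ `.roi` polylines or `x,y` CSVs);
`analyze_study()` consumes it directly. A thin command-line front end
with `analyze`, `compare`, `simulate` and `calibrate-null` subcommands is
installed at `system.file("cli/punctascan.R", package = "punctascan")`.

See the vignette (`vignettes/puncta-quantification.Rmd`) for the model,
parameter rationale, and what the synthetic validation does and does not
establish.

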