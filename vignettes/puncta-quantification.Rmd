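---
title: "Quantifying fluorescent puncta along the ventral nerve cord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent puncta along the ventral nerve cord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctascan)
```

## The measurement problem

Tagged synaptic proteins such as GLR-1::GFP accumulate in discrete puncta
along the *C. elegans* ventral nerve cord. Three per-animal quantities
summarize that accumulation:

* **peak-to-bead intensity** — the punctum's peak intensity divided by the
  intensity of a 0.5 µm calibration bead imaged in the same session, which
  cancels illumination (arc-lamp) drift between sessions;
* **width** — the full width at half maximum (FWHM) of the punctum along
  the cord, in microns;
* **density** — detected puncta per 10 µm of analyzed cord.

Although micrographs are 2D, every one of these quantities is defined on
the 1D intensity trace along the cord. `punctascan` therefore reduces each
animal to a calibrated linescan and performs detection and measurement in
one dimension. A 2D detection mode is deliberately out of scope.

## From image to linescan

An animal enters the pipeline as a Z-stack (or single image) plus a
user-drawn polyline tracing the cord. The stack is collapsed by
maximum-intensity projection. The polyline is sampled at 1-pixel
arc-length steps; at each step the intensity is the mean of
`line_width_px` bilinear samples taken along the local perpendicular
(1-pixel spacing, centered on the path). Conventions, fixed once to avoid
off-by-one drift: pixel coordinates are 0-based with positions at pixel
centers; arc length is measured in µm from the first vertex; interpolation
is bilinear.

The perpendicular averaging width is not recorded in the original
protocol; the default of 3 px follows common linescan practice and
suppresses single-pixel noise. It matters: at a signal-to-noise ratio of
5, detection recall on rendered 2D images (where the 3-px band averages
noise down by √3) is essentially perfect, while thresholding an
unaveraged trace at the same image-level noise loses roughly one punctum
in ten.

Two small geometric caveats. Reversing the path reverses the profile
exactly only when the total path length is an integer number of pixels
(otherwise the two directions sample different points), and at a polyline
corner the perpendicular direction depends on traversal direction, so the
reversal identity additionally requires `line_width_px = 1` on paths with
corners.

## Detection: smoothing, Phansalkar threshold, size filter

Detection follows the published Fiji macro settings: Gaussian smoothing
with σ = 0.5 px, Phansalkar local adaptive thresholding with window
radius 2 px, and a minimum punctum extent of 10 px. The single smoothed
profile is used both for thresholding and for all downstream measurement.

The profile is first min–max rescaled to [0, 1]. For each sample, the
mean *m* and population standard deviation *s* (divisor = window size) of
the `2·radius + 1` window — reflected at the profile ends — define the
threshold

  *t = m · (1 + p·e^(−q·m) + k·(s/r − 1))*

with the method's standard constants k = 0.25, r = 0.5, p = 2, q = 10.
A sample is foreground iff its rescaled intensity strictly exceeds *t*
(ties are background, which makes the flat-profile case deterministic:
zero dynamic range yields an all-background mask with a warning). The
min–max rescale makes the mask exactly invariant to affine intensity
transforms *aI + b*, *a* > 0.

Maximal foreground runs shorter than `min_size_px` are discarded. The
macro's "size = 10" does not state units; pixels are assumed, consistent
with the radius and σ being pixel-denominated. Runs touching a profile
end are kept but flagged `at_edge`.

## Measurement

Within each segment the peak is the maximum smoothed intensity (ties
break toward the smaller index). The reference level for "half maximal"
is not defined in the original protocol; the default here is the median
intensity of all sub-threshold samples — a robust, global estimate. A
per-punctum alternative (`baseline_method = "local_min"`, the mean of the
two samples flanking the segment) is available in the run configuration.

The FWHM walk starts at the peak and moves left and right to the first
sample *strictly below* the half level
`baseline + (peak − baseline)/2`; each crossing is linearly interpolated
between the straddling samples. If either walk reaches a profile end
first, the width is undefined and the punctum is edge-flagged.

Edge policy: edge-flagged puncta are excluded from the per-animal width
and intensity means (their FWHM is uncomputable) but counted for density
(their existence is real). `edge_policy = "exclude"` drops them entirely
for sensitivity analyses. Animals with no measurable puncta propagate
missing means — never zeros — into the group statistics.

## Group statistics

Statistics operate on per-animal values (one mean per animal), never on
pooled per-punctum values, matching the "per animal" presentation of the
original analysis and avoiding pseudo-replication. Each group is first
gated by a Shapiro–Wilk normality test; the result is reported but never
used to switch tests — the workflow proceeds to a two-sample
Kolmogorov–Smirnov test regardless, mirroring the fixed published
workflow (the per-animal metrics were found non-normal there). KS
p-values are exact when `n_wt · n_mut ≤ 10⁴` — which covers the group
sizes of interest, 13 and 28 — and asymptotic otherwise; the mode used is
recorded in the output. Intensity graphs conventionally show values
normalized to the wild-type mean (the wild-type group then has mean
exactly 1); percent changes are identical whether computed on raw or
normalized means. No multiple-testing correction is applied across the
three metrics; a Bonferroni column is emitted for transparency only.

`calibrate_null()` checks that the exact KS test holds its nominal size
at these group sizes: over 2000 null replicates of 13 vs 28 the
rejection rate at α = 0.05 lands near 0.04–0.05, inside the
discreteness-limited band expected of an exact small-sample test.

## The synthetic generator

No raw micrographs are publicly deposited, so validation rests on a
generator with exact ground truth. Each synthetic animal is a straight
cord of length 100 µm carrying puncta placed by a Poisson process
(default 2 per 10 µm); each punctum is a Gaussian bump with planted FWHM
(σ_g = FWHM/2.3548; default mean 1.0 µm, SD 0.15) and amplitude (default
mean 100, SD 20 arbitrary units) over a constant background (20), plus
i.i.d. additive Gaussian detector noise (default SD 10). The mutant-like
group applies multiplicative shifts to width, amplitude and density. The
2D mode renders the cord with a Gaussian transverse section (SD 2 px)
on a 21-row image and emits a matching cord path.

Defaults worth justifying:

* **Group sizes 13 and 28** reproduce the study design the protocol was
  validated on (13 wild-type vs 28 mutant animals).
* **Pixel size 0.0645 µm** is a 6.45 µm-pixel CCD camera behind a 100×
  objective, the standard ventral-nerve-cord configuration. The choice
  interacts with the macro's fixed `min_size = 10 px`: the
  supra-threshold extent of a Gaussian punctum under the Phansalkar rule
  is only ≈ 1.3 × FWHM, so a ~1 µm punctum must span ≥ ~15 px for the
  10-px filter to be safely clear of it. At coarser samplings (e.g.
  0.108 µm/px) the same punctum spans 9 px and the published filter would
  reject real puncta — inconsistent with the protocol's demonstrated
  reliability, so the finer, instrument-accurate sampling is the default.
* **Gaussian bump shape** makes the FWHM ground truth closed-form.
* **Additive Gaussian noise** models the detector-dominated regime;
  there is no optics (PSF) simulation and no camera-specific noise model.
* **`min_separation_um`** (default 0) enforces a minimum spacing by
  count-preserving rejection placement: the Poisson count is kept and
  positions are redrawn, so the planted density is unchanged. With it
  off, nearby puncta can merge into one supra-threshold segment — a real
  failure mode of the method, deliberately reproducible here. Counting
  benchmarks enable separation so they measure counting rather than
  merging; at a planted 1.5 puncta/10 µm with no separation the merge
  loss alone is ≈ 0.18 puncta/10 µm.

What passing synthetic tests do **not** show: robustness to curved or
mis-traced cords, non-Gaussian punctum shapes, spatially structured
background (gut autofluorescence), shot noise, or focus drift. Results on
real micrographs depend on those factors; the generator validates the
algorithmic chain, not the microscopy.

## Validation summary (computed by the test suite and acceptance script)

Problem sizes were chosen to keep every run light while leaving no
benchmark trivially small: 100 random 64-sample profiles for the
threshold-oracle equivalence; ~170 planted puncta across 18 animals for
the SNR-5 recovery run (recall ≥ 0.9, FDR ≤ 0.1, median width error
< 10%); 50 noiseless animals for density recovery (±0.15 of the planted
1.5/10 µm); 2000 replicates for the KS null calibration; and a full
41-animal study (width ×1.5, amplitude ×1.4, density ×0.6) for the
end-to-end direction test, which reports positive width and intensity
changes, a negative density change, and a width KS p-value far below
0.05.

## Known limitations

* No watershed or peak-splitting of merged puncta; at high density the
  density estimate is biased low and widths of merged pairs are inflated.
* The FWHM walk's "first sample strictly below" rule has a small
  noise-induced inward bias (≈ 8% median at SNR 5); it vanishes as noise
  decreases and is the price of the simple, deterministic definition.
* Widths measured on the smoothed profile are broadened by the σ = 0.5 px
  kernel — negligible (< 0.5%) at the default sampling.
* Only the Phansalkar rule is implemented; alternative local thresholds
  (Otsu, Niblack, Sauvola) are out of scope.
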