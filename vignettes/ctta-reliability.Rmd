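---
title: "Simulated reliability assessment of CT texture metrics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated reliability assessment of CT texture metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `cttaphantom`: the phantom and
scanner models, the texture panel, the percent-absolute-difference (PAD)
reliability framework, and the design decisions taken where several
reasonable choices existed. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The question

CT texture metrics ("radiomics") are sensitive, to different degrees, to
the scanner and to acquisition parameters. The package frames metric
reliability operationally:

* **repeatability** — the metric changes little between two scans of the
  same object at identical settings, minutes apart;
* **robustness** — the metric changes little when one acquisition
  parameter is changed from a baseline protocol;
* **reproducibility** — repeatability and robustness behavior is
  consistent across scanners.

All three are measured with the PAD, `|test − baseline| / |baseline|`, an
intentionally simple signal-change statistic (correlation-based indices
such as ICC/CCC need many heterogeneous objects; a three-insert phantom
supports a difference analysis, not a correlation one). A metric is
**reliable** when every repeatability and robustness PAD is at or below
the reliable band (default 5%) on both scanners. Percentage tallies of
comparisons within a wider 0.15 cutoff are reported alongside as summary
diagnostics, so both thresholds appear in the configuration
(`reliable_band = 0.05`, `tally_cutoff = 0.15`).

Zero-baseline guard: a PAD with `|baseline| < 1e-12` is defined as 0 when
the test value is also ~0 (a metric identically zero under both conditions
carries no instability signal) and as `Inf` (flagged, never reliable)
otherwise.

## The digital phantom

A short cylinder (default 150 mm diameter, 40 mm length) of homogeneous
soft-tissue background (urethane-like, 40 HU) in air (−1000 HU), holding
three 50 × 50 mm square regions whose texture is a **deterministic
periodic binary lattice** of insert material (ABS-like, −40 HU; −80 HU
contrast relative to background) at 10%, 20% and 40% volume fill.

The lattice is built per 2 mm period cell: the cell's `S³` subcells
(`S` = `supersample_factor`; the ground-truth voxel is `2/S` mm) are
ranked by a fixed integer hash, and a fill fraction `f` occupies the
lowest-ranked `⌈f·S³⌋` subcells. This ordered-threshold construction was
chosen over a scaled solid rod because a center-sampled rod quantizes its
cross-section to the sampling grid — at `S = 4` the realized occupancy can
be off by 0.15 or more — whereas the rank-threshold lattice realizes the
requested fill with error at most `1/(2S³)` (< 0.01 at `S = 4`) while
remaining binary, periodic and fully deterministic. Consequences verified
by tests: region occupancy converges to the fill fraction, and the
noise-free acquired mean HU of a region equals
`background + occupancy × (insert − background)` within 1 HU.

The defaults place the three regions 38 mm off-axis at 120° spacing (the
largest symmetric layout whose corners stay strictly inside the
cylinder); overlapping or out-of-cylinder regions are rejected at
construction.

## The virtual scanners

`simulate_acquisition` produces a volume on a `matrix_size²` in-plane grid
(pixel = FOV / matrix) at the setting's slice thickness by, in order:

1. **partial-volume averaging** of ground-truth voxels into target voxels
   (uncovered voxels, outside the phantom support, become air);
2. **contrast scaling**: `(HU − background)` is multiplied by a linear
   kVp factor — 1.0 at 100 kVp, +5% per 20 kVp decrease — a monotone
   stand-in for beam-energy contrast dependence whose magnitude is a free
   simulator parameter;
3. **quantum noise**: additive zero-mean Gaussian noise with
   `σ = σ_ref √(mA_ref / mA)` (the 1/√dose law), seeded per volume;
4. **edge-preserving filtering**: slice-wise bilateral smoothing (5 × 5
   window, spatial σ = 1 pixel, range σ = 20 HU × level), emulating
   iterative-reconstruction strength levels — 6 exposed levels on scanner
   A, 2 ("Mild"/"Strong", strengths 2 and 5) on scanner B;
5. **HU offset**: +0 HU (A) / +4 HU (B), reflecting inter-scanner HU
   calibration differences.

Scanner A is the lower-noise device (σ_ref = 12 HU at 100 mA) with the
richer protocol matrix (3 tube voltages: 80/100/140 kVp), scanner B the
noisier one (σ_ref = 18 HU; 100/135 kVp). Both share the slice-thickness
list 1–5 mm, FOV 125/500 mm and mA 40–100.

**Baseline protocol.** One consistent baseline is used for all
one-factor-at-a-time comparisons: 3 mm slices, 500 mm FOV, 100 kVp,
100 mA, no filtering. Each parameter family enumerates its full value
list as distinct settings (including the value equal to the baseline's),
giving 1 + 5 + 2 + 6 + 3 + 4 = 21 settings on A and
1 + 5 + 2 + 2 + 2 + 4 = 16 on B; every setting is acquired twice with
independent noise seeds (the test-retest pair). Per-volume seeds are
derived deterministically from the master seed, scanner, setting and
repeat indices and recorded in the study manifest.

**What the simulator does not model** (by design): sinogram-domain
reconstruction, beam hardening, scatter, motion, streak artifacts,
non-stationary noise, detector physics. Passing tests therefore
demonstrate the behavior of the *analysis framework* under controlled,
parametric perturbations — not that any particular metric is reliable on
physical scanners. Percentages measured on real devices depend on scanner
internals the simulator does not emulate and are reproduced only
qualitatively (direction, not value).

## ROI sampling and quantization

Spherical ROIs (default radius 16 mm, centered in the three texture
regions) select voxels by center-in-sphere. Voxels below −200 HU are
dropped from the sample — the analogue of excluding air bubbles from a
physical cast. Values are clipped to the 12-bit CT window [−1024, 3071]
and quantized to `n_bins = 20` equal-width bins over the ROI's own
[min, max] (maximum maps to bin 20; a constant sample maps to bin 1). The
12-bit clip and the 20-bin requantization coexist deliberately: the clip
fixes the representable HU range, the 20 bins make co-occurrence and
run-length matrices tractable and ROI-adaptive.

The 2-D analysis plane is the orientation (axial/coronal/sagittal) and
slice maximizing the in-plane mask diameter — the maximum pairwise
distance between in-mask voxel centers in mm. Ties break
axial > coronal > sagittal, then lowest slice, making plane selection
fully deterministic (verified against exhaustive search).

## The 235-metric panel

Eight families in a fixed canonical order (indices in parentheses):

| block | metrics |
|---|---|
| histogram (1–13) | mean, variance, skewness, excess kurtosis, median, min, max, range, p10, p90, mean absolute deviation, 20-bin energy, 20-bin entropy — on raw HU |
| 2-D GLCM+GLDM (14–93) | 15 co-occurrence statistics (Haralick's 13 + autocorrelation + maximum probability) × 4 in-plane directions, + 5 difference statistics × 4 directions |
| 3-D GLCM+GLDM (94–173) | the same 15 + 5 statistics per direction over the 13 unique 3-D directions, aggregated by mean/range/min/max |
| 2-D GLRLM (174–206) | 11 run statistics × {mean, min, max} over 4 directions |
| 3-D GLRLM (207–217) | 11 run statistics, mean over 13 directions |
| FFT (218–235) | 9 statistics each for in-band magnitude and phase |

Numerical conventions: distance 1 voxel for all co-occurrence/difference
matrices; co-occurrence matrices symmetrized then normalized; log base 2
everywhere with `0·log 0 ≡ 0`; zero-variance marginals define
correlation and both information measures of correlation as 0 (flagged
degenerate rather than NaN); directions without valid voxel pairs (ROI
thinner than 2 voxels) are skipped from 3-D aggregation and counted in
provenance. Every matrix family is property-tested against an
independent brute-force enumeration oracle on >100 random images.

The FFT block embeds the bin-level analysis plane (cropped to its mask
bounding box, so the spectrum is invariant to where the ROI sits in the
volume) in the center of a 512 × 512 zero frame, takes the 2-D DFT, and
keeps the annulus between 10% and 90% of the Nyquist frequency — the DC
component and the corner frequencies are excluded by construction.
Magnitude entropy treats normalized magnitudes as probabilities; phase
entropy uses a 64-bin histogram over (−π, π]; radial centroid and spread
are amplitude-weighted. The quantized (not raw-HU) plane is used so that
spectra are comparable across settings with different HU scales.

The canonical name/family manifest ships as
`inst/extdata/feature_manifest.csv` and a test asserts it can never
change silently.

## The reliability assessment

`repeatability_table` pairs repeat-0/repeat-1 values per (scanner,
setting, ROI, feature); `robustness_table` pairs each varied setting with
the baseline per (scanner, ROI, feature) and groups by parameter family.
PADs are computed and kept **per ROI** — pooling across ROIs would hide
which insert drives instability — while tallies are reported both pooled
per scanner and per ROI. With the default matrix this yields, per ROI,
5 × 235 = 1175 slice-thickness and 2 × 235 = 470 FOV robustness
comparisons on scanner A, and 21 × 235 / 16 × 235 repeatability cells on
A/B. `reliable_set` applies the two-scanner conjunction;
`heatmap_export` writes the 235 × settings PAD matrix as CSV (unclipped)
and as a 0–20% blue-to-red image with the 5% band outlined.

**Filter-effect analyses.** Two views are provided. The study-level view
(`filter_effect_contrast`) follows the robustness design: per filter
level, the mean PAD against the baseline scan (each scan with its own
noise), a distribution-free paired sign test against zero change, and a
Spearman trend across levels. This view is intentionally unpaired and
noisy — it is what a physical study can measure. The simulator-level view
(`filter_level_trend`) isolates the filter effect with a paired
Monte-Carlo design: each level is applied to the *same* noisy
acquisition and compared with its unfiltered self, averaged over the
three ROIs and ≥10 replicates. The paired design is used for the
monotonicity property (mean PAD of the noise-sensitive second-order
families strictly increases with level) because in the unpaired view the
level-to-level increments at high strengths are smaller than the PAD
sampling noise: the bilateral range term saturates once
`range σ × level` exceeds the local contrast, so the unpaired curve
flattens and can even dip while the paired curve remains strictly
ordered.

## Problem sizes and tunable parameters

The package's own analyses (tests, `analysis/` scripts,
`scripts/acceptance.R`) run the full acquisition matrix on a 64 × 64
reconstruction grid with supersample factor 2 (1 mm ground truth) — the
structural quantities (setting counts, comparison counts, panel layout)
are grid-independent, and a 74-volume study simulates in seconds while
ROIs keep ≥32 voxels at every setting. The shipped default configuration
(`inst/extdata/default_config.yaml`) specifies the full 512 × 512 matrix;
at that resolution the ground truth should be supersampled so that the
truth voxel (2/S mm) is at least as fine as the smallest pixel
(FOV 125 / 512 ≈ 0.24 mm → S ≥ 9).

Key defaults, units and rationale:

| parameter | default | why |
|---|---|---|
| `background_hu` / `insert_hu` | 40 / −40 HU | soft-tissue range, −80 HU targeted contrast |
| `lattice_period` | 2 mm | texture scale between pixel sizes of the two FOVs |
| `noise_sigma_ref` | 12 (A), 18 (B) HU at 100 mA | plausible abdominal CT noise; makes the scanners differ |
| `hu_offset` | 0 (A), +4 (B) HU | reported inter-scanner HU variation |
| `filter_range_sigma` | 20 HU per level | spans no-op to edge-blurring across levels 1–6 |
| `roi radius` | 16 mm | fits the 50 mm regions with margin; ≥32 voxels at all settings |
| `n_bins` | 20 | matrix tractability, ROI-adaptive |
| `tally_cutoff` / `reliable_band` / `clip_max` | 0.15 / 0.05 / 0.20 | reporting thresholds of the framework |

## Known limitations

* The noise model is stationary Gaussian; real CT noise is correlated and
  object-dependent, which typically *worsens* second-order metric
  stability — simulated tallies are optimistic in absolute terms.
* The kVp contrast factor is a single global scalar; real energy
  dependence is material-specific.
* Phase-derived FFT metrics depend on the mask-bounding-box embedding
  convention; other centering conventions shift phase statistics.
* PAD is scale-free but explodes for metrics whose baseline is near zero;
  such comparisons surface as large finite or flagged infinite PADs and
  dominate mean-PAD summaries (median summaries are reported where this
  matters).
* The per-ROI, non-pooled accounting means tallies are not directly
  comparable to analyses that pool inserts.
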