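# cttaphantom

Reliability assessment of CT texture-analysis (CTTA) metrics on a
simulated texture phantom.

Radiomic texture metrics promise quantitative tumor characterization from
routine CT, but their values shift with the scanner and with acquisition
settings (slice thickness, field of view, reconstruction filtering, tube
voltage, tube current). Before a metric is used in a multicenter model it
should be shown to be *reliable*: stable under test-retest, robust to
protocol changes, and consistent across scanners. `cttaphantom` implements
that assessment end to end as a fully simulated, seeded pipeline, for
researchers who want to study metric stability — or stress-test their own
feature definitions — without scanner time:

1. **Digital texture phantom** — a 15 cm soft-tissue cylinder
   (background 40 HU) containing three 5 × 5 cm regions filled with a
   deterministic periodic binary lattice of darker insert material
   (−40 HU) at 10%, 20% and 40% volume fill, spanning the texture range of
   tumors on CT.
2. **Two virtual scanners** — partial-volume averaging onto the
   reconstruction grid, kVp-dependent contrast scaling, Gaussian quantum
   noise with σ ∝ 1/√mA (12 HU reference on scanner A, 18 HU on scanner
   B), slice-wise edge-preserving (bilateral) filtering with 6 exposed
   strengths on A and 2 on B, and a per-scanner HU calibration offset.
   A one-factor-at-a-time acquisition matrix gives 21 settings on A and
   16 on B, each acquired twice with independent noise (test-retest).
3. **235-metric texture panel** per spherical ROI, computed on 20-bin
   gray-level quantization: 13 first-order histogram metrics, 80 2-D and
   80 3-D co-occurrence/difference (GLCM/GLDM) metrics, 33 2-D and 11 3-D
   run-length (GLRLM) metrics, and 18 band-limited Fourier (FFT magnitude
   and phase) metrics, in a fixed canonical order with the FFT block at
   indices 218–235.
4. **Reliability framework** based on the percent absolute difference

   PAD = |x_test − x_baseline| / |x_baseline|

   * *repeatability*: PAD between the two scans of each setting;
   * *robustness*: PAD between each varied setting and the baseline scan,
     grouped by parameter family, tallied at the 0.15 cutoff;
   * *reproducibility / reliability*: a metric is **reliable** when every
     one of its repeatability and robustness PADs is ≤ 5% on **both**
     scanners.

## Worked example

The numbered scripts under `analysis/` run the full study; the same can be
done in one call:

```r
library(cttaphantom)
cfg <- small_config(matrix_size = 64)   # full acquisition matrix, 64x64 grid
res <- run_study(cfg, seed = 1)         # simulate + extract + assess

res$repeatability$tally
#>         A         B
#> 0.5583924 0.5531028

res$report
#> <reliability_report> 5/235 features reliable at band 0.05
res$report$reliable
#> [1] "fft_mag_entropy"     "fft_phase_entropy"   "fft_phase_max"
#> [4] "fft_phase_rcentroid" "fft_phase_rspread"
```

Reading: at this noise level roughly 56% of the 4935 (21 × 235) and 3760
(16 × 235) test-retest comparisons per ROI fall within the 0.15 cutoff on
scanners A and B, and only five metrics — all from the FFT block, led by
the entropy of the spectrum magnitude and phase — stay within 5% across
every setting, repeat and scanner. Second-order (GLCM/GLDM/GLRLM) metrics
are far less stable: under tube-current and filter variation their median
worst-case PAD is about 0.63 versus 0.08 for the FFT block. Stage scripts
(`analysis/01_simulate.R` … `04_properties.R`) write the volumes,
feature table, comparison records, per-family tallies and the 0–20%
blue-to-red PAD heatmaps under `results/`.

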