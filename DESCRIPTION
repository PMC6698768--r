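Package: cttaphantom
Title: Digital Texture-Phantom Simulation and Reliability Assessment of CT
    Texture Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates CT acquisitions of a digital texture phantom (three
    geometric texture patterns at 10/20/40 percent material fill in a
    homogeneous cylinder) on two configurable virtual scanners under a
    one-factor-at-a-time acquisition matrix (slice thickness, field of view,
    edge-preserving reconstruction filtering, tube voltage, tube current),
    including test-retest pairs. Computes a fixed 235-metric texture panel
    (first-order histogram, 2D/3D gray-level co-occurrence and difference,
    2D/3D gray-level run-length, and band-limited 2D Fourier spectral
    features) on spherical regions of interest with 20-bin gray-level
    quantization, and assesses metric reliability through percent absolute
    differences: repeatability (test-retest), robustness (parameter change
    versus baseline), and cross-scanner reproducibility, with cutoff tallies,
    reliable-metric identification, and heatmap export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
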