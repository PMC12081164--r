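# nirsdot

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through the scalp: near-infrared light at two or more
wavelengths is injected by sources and collected by detectors a few
centimetres away, and changes in detected intensity reflect changes in
oxy- and deoxy-hemoglobin concentration in the tissue between them.
`nirsdot` is an R package for the whole analysis chain of continuous-wave
fNIRS, from raw files to statistical maps on the cortical surface. It is
aimed at researchers who want a scriptable, fully reproducible pipeline:

* **I/O** — SNIRF (`.snirf`, HDF5) and Homer (`.nirs`, MAT) readers and
  writers; ASCII OBJ surfaces; NIfTI head segmentations; TSV event tables;
  closed-form rigid fiducial coregistration.
* **Quality** — scalp coupling index (cardiac-band cross-wavelength
  correlation), coefficient of variation, nonpositive-sample detection,
  and channel pruning.
* **Preprocessing** — optical density conversion
  ΔOD = −log₁₀(I/I₀); spline-interpolation and temporal derivative
  distribution repair (TDDR) motion correction; zero-phase FIR/IIR
  filtering; discrete-cosine detrending; short-separation channel
  regression; the modified Beer–Lambert law
  (ΔHbO, ΔHbR)ᵀ = E⁻¹ (ΔOD_λ / d_eff,λ) with d_eff = d·DPF/PVF; epoch
  averaging.
* **GLM** — Y = Xβ + ε with a canonical double-gamma HRF (peak 5 s,
  undershoot 15 s), drift and superficial confounds, precoloring or
  per-channel AR(1) prewhitening, contrasts with Student's t, and
  Bonferroni/FDR correction; summary-statistics group inference.
* **Forward model** — analytic per-tissue fluence fields on a labeled
  head volume, adjoint (Rytov) channel sensitivities, Voronoi
  volume-to-surface projection, montage sensitivity maps in log10
  decades, and channel-overlap metrics.
* **Tomography** — depth-weighted minimum-norm estimation
  j = Σ_s Aᵀ(AΣ_sAᵀ + κΣ_d)⁻¹m with diag(Σ_s) = diag(AᵀΣ_dA)^(−ω) and
  L-curve selection of κ; and maximum-entropy-on-the-mean (cMEM)
  reconstruction with a parcel-wise Bernoulli–Gaussian prior solved
  through its concave dual in channel space.
* **Optimal montage** — exact branch-and-bound solution of the optode
  placement program (equipment, distance, spacing and per-source
  adjacency constraints; maximal ROI sensitivity).
* **Simulation** — a layered-sphere head phantom with an interleaved
  two-ring probe and short channels, task-evoked responses with
  structured physiological noise at controlled SNR, and validation
  metrics (spatial dispersion, ROC-AUC) against the ground truth.

## A worked example

Simulate a finger-tapping-style session on the phantom, preprocess it,
fit the GLM at the channel level, and reconstruct the response on the
cortical surface with both solvers:

```r
library(nirsdot)

phantom <- makePhantom()
fwd     <- buildForwardModel(phantom$volume, phantom$surface, phantom$probe)
sim     <- simulateRecording(phantom, fwd, defaultSimulation(), seed = 1)
rec     <- sim$recording
rec
#> OpticalRecording: 36 channels x 11599 samples at 10 Hz, 20 events

rep <- channelQualityReport(rec)
sum(rep$good)
#> [1] 36

od <- toOpticalDensity(rec, baselineWindow = c(0, 20))
od <- bandpassFilter(od, 0, 0.5)           # lowpass below 0.5 Hz
od <- shortChannelRegress(od)              # regress superficial signal
hb <- mbll(od)
hb
#> HemoglobinSeries: 18 pairs x 11599 samples (uM)

des <- buildDesign(events(od), od@times, confounds = c("constant", "linear"))
fit <- fitGlm(hb, des, serial = "prewhiten")
res <- testContrast(fit, c(1, 0, 0), correction = "fdr")
head(res[order(res$p), ], 4)
#>    channel effect     se    t        p pCorrected significant
#> 1        1   6.92 0.0973 71.1 0.00e+00   0.00e+00        TRUE
#> 2        2   3.95 0.0924 42.8 0.00e+00   0.00e+00        TRUE
#> 4        4   4.42 0.1007 43.9 0.00e+00   0.00e+00        TRUE
#> 18      18   1.24 0.0917 13.5 1.79e-41   8.07e-41        TRUE
```

The task effect (the first regressor's weight, in µM of ΔHbO) is largest
on the pairs over the active patch and survives FDR correction. The
end-to-end benchmark reconstructs the averaged response with both
inverse solvers and scores them against the simulated ground truth:

```r
endToEndBenchmark(seed = 42, snr = 5, phantom = phantom, forward = fwd)
#>   method spatialDispersion rocAuc peakLatency amplitudeRatio
#> 1    mne              7.05  0.997        10.5          0.318
#> 2   cmem              5.57  0.988        10.5          0.439
```

Spatial dispersion is the energy-weighted geodesic spread (mm) of the
reconstructed map around the true patch; ROC-AUC scores the map as a
classifier of patch membership. The entropy-based solver localizes the
patch more compactly (smaller dispersion) and recovers a larger fraction
of the true amplitude, while both identify the patch nearly perfectly at
this SNR.

A thin command-line wrapper with the same stages (simulate, quality, od,
motion, filter, ssc, mbll, epoch, glm, validate, pipeline) is installed
as `exec/nirsdot`.

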