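---
title: "nirsdot: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nirsdot: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nirsdot` implements the complete analysis chain for continuous-wave
functional near-infrared spectroscopy (fNIRS): file input/output, channel
quality control, motion correction, filtering, conversion to hemoglobin
concentration changes, general-linear-model (GLM) activation analysis,
analytic forward modelling of light sensitivity on a cortical surface,
two tomographic inverse solvers (depth-weighted minimum-norm and
maximum-entropy-on-the-mean), optimal optode placement, and a
layered-sphere phantom harness that exercises all of it end to end.

This vignette documents the models, the tunable parameters and their
defaults, the numerical decisions, and the known limitations. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

# Channel-space model

## Optical density and the modified Beer-Lambert law

Raw intensities $I_\lambda(t)$ become optical density changes
$\Delta OD_\lambda(t) = -\log_{10} I_\lambda(t)/I_{0,\lambda}$, with
$I_{0,\lambda}$ the mean (default) or median over a user baseline window
(`toOpticalDensity`). Channels containing any sample $\le 0$ are
rejected upstream because the logarithm is undefined there; the quality
module flags them rather than repairing them.

Hemoglobin changes per source-detector pair come from inverting the
2x2 extinction system
$$\begin{pmatrix}\Delta HbO\\ \Delta HbR\end{pmatrix} =
  E^{-1}\begin{pmatrix}\Delta OD_{\lambda_1}/d_{eff,\lambda_1}\\
                       \Delta OD_{\lambda_2}/d_{eff,\lambda_2}\end{pmatrix},
  \qquad d_{eff,\lambda} = d \cdot DPF_\lambda / PVF,$$
with $d$ the source-detector distance in cm, the differential pathlength
factor from either the general age/wavelength formula (Scholkmann-type,
default) or the four-wavelength adult-head fits (Duncan-type), and the
partial volume factor defaulting to 50. For a 3 cm channel with
$DPF = 5$ this gives $d_{eff} = 0.3$ cm. Extinction coefficients are a
compact bundled tabulation of the standard compiled oxy/deoxy-hemoglobin
spectra (650-900 nm), linearly interpolated; users can supply their own
2x2 matrix. Total hemoglobin is stored as the exact sum
$\Delta HbT \equiv \Delta HbO + \Delta HbR$.

## Channel quality

The scalp coupling index (SCI) is the Pearson correlation of the two
wavelengths of a pair after zero-phase third-order Butterworth filtering
in the cardiac band (default 0.5-2.5 Hz); it is computed on optical
density so it is invariant to per-wavelength gain. The coefficient of
variation (CV) is $100\,\sigma/\mu$ of the raw intensity. Default
thresholds: SCI < 0.8 or CV > 30% (or any nonpositive sample) marks a
channel bad. Pruning only updates flags; the data are untouched, so it
is idempotent. SCI is undefined (reported missing, channel flagged) when
a filtered signal has zero variance, which includes pairs with a
log-undefined mate.

## Motion correction

Two methods operate on optical density:

* **Spline interpolation** over user-marked windows: a discrete cubic
  smoothing spline (Whittaker form of the csaps penalty) is fitted to
  each window and subtracted, and the corrected segment is re-leveled
  with a linear offset so both edges join the neighboring untouched
  samples; outside the windows the series is bit-identical. The
  smoothing parameter `p = 0.99` follows the common reference
  implementations and is applied in sample-index units — with
  time-unit scaling the fit would be far too loose to cancel a
  transient. Note that a *persistent* baseline step cannot be flattened
  under the bit-identical-outside contract; the method targets transient
  artifacts contained in the marked window. Overlapping windows are
  merged with a warning.
* **Temporal derivative distribution repair (TDDR)**: the derivative of
  the sub-0.5 Hz component is robustly re-centered and re-weighted with
  an iterative Tukey-biweight location estimate (tuning constant 4.685),
  re-integrated, and the high-frequency component and the signal mean
  are restored. Two properties worth knowing: the biweight softly
  shrinks even inlier derivatives (the expected weighted energy ratio is
  about 0.76 for Gaussian derivatives), and the removal of the robust
  mean slope detrends the series; TDDR is therefore not an exact no-op
  on artifact-free data, and the tests check it against an independent
  re-implementation of the published iteration rather than against an
  identity claim.

## Filtering, detrending, superficial regression

`bandpassFilter` offers zero-phase IIR (Butterworth, default order 3,
forward-backward) and linear-phase FIR (default order 128, also applied
forward-backward) designs; the series is demeaned first (the constant
belongs to the stopband of any highpass edge) and the mean is restored
only for pure lowpass. `dctDetrend` projects out, by ordinary least
squares, the discrete cosine basis functions with period longer than the
cutoff (default 200 s, i.e. below 0.005 Hz) plus the constant. Both are
strictly linear operators.

Short-separation regression (`shortChannelRegress`) regresses the mean
of all short channels (source-detector distance at or below 10 mm by
default) out of every long channel by OLS with an intercept, separately
per wavelength or per chromophore — the superficial HbO signal is used
only for long-channel HbO, and likewise for HbR. Short channels pass
through unchanged; a zero-variance regressor skips the step with a
warning.

# GLM activation analysis

The canonical hemodynamic response function is a difference of two
peak-normalized gamma kernels. Rather than fixing textbook shape
parameters, the two time-to-peak parameters are tuned by a small Newton
solve at construction so that the sampled kernel attains its positive
peak at exactly 5 s and its undershoot minimum at exactly 15 s on any
grid containing those points; the undershoot amplitude ratio defaults to
1/6 and the kernel is zero at the origin.

`buildDesign` assembles task regressors (boxcar event trains convolved
with this kernel) followed by the requested confounds: constant, linear
trend, DCT drift set, and the mean short-channel signal. Both a linear
trend and the DCT set are available because block designs benefit from
either; rank deficiency is reported with the offending columns named.

`fitGlm` fits each channel by OLS after one of three serial-correlation
treatments: none; *precoloring*, which smooths data and design with the
(unit-sum) canonical kernel; or *prewhitening*, which estimates a
per-channel AR(1) coefficient from the OLS residual lag-1
autocorrelation, applies the exact AR(1) whitening operator (first
sample scaled by $\sqrt{1-\rho^2}$), and refits once. The single-pass
estimate keeps the procedure deterministic; coefficients with
$|\rho| \ge 1$ are clipped to $\pm 0.99$ with a warning. Degrees of
freedom are $n - \mathrm{rank}(X)$ without an effective-dof correction
for precoloring (a deliberate simplification; prewhitening is the
calibrated default, and the test suite verifies its type-I error rate
near the nominal 5% under an AR(1) null).

Contrasts are tested with Student's t; multiple-testing correction is
Bonferroni or Benjamini-Hochberg FDR across channels. Group-level
inference is the summary-statistics reduction of the mixed model: a
one-sample t test across subject-level contrast estimates, with the
degenerate zero-variance case guarded to a large finite statistic.

# Forward model

Monte-Carlo photon transport is out of scope; the package ships a
deterministic analytic fluence model intended for montage review,
solver validation and simulation. The fluence of an optode at a point
is $\exp(-\int \mu_{eff}\,ds)$ along the straight optode-to-point
segment, with per-tissue attenuation coefficients (mm$^{-1}$; defaults
of realistic magnitude for scalp/skull/CSF/gray/white at near-infrared
wavelengths) integrated by midpoint sampling (48 samples). Because the
midpoint set is symmetric in the endpoints, the adjoint (Rytov) channel
sensitivity — the voxelwise product of source and detector fluences
normalized by the source fluence at the detector — is bit-exactly
reciprocal under source/detector exchange.

Volume-to-surface projection uses a Voronoi scheme: each gray-matter
voxel is assigned to its nearest surface vertex (Euclidean, 6 mm cap;
capped voxels are recorded as unassigned) and a vertex's sensitivity is
the mean over its cell. The field of view is the set of vertices within
30 mm (Euclidean) of any optode; geodesic alternatives were left out for
determinism and cost.

Montage review maps use a log10-decade scale: 0 for the most sensitive
vertex, -1 for ten times less sensitive. This follows the convention of
the montage-review literature rather than the conventional
$10\log_{10}$ decibel; outputs label the unit as log10 decades. Two
overlap metrics are provided: the minimum sensitivity achieved by the
$n$ most sensitive channels per vertex, and the number of channels above
a threshold (default -1 decade) per vertex, each channel's map being
normalized to its own maximum so the threshold is channel-relative.

# Inverse solvers

Both solvers act per wavelength on $m(t) = A\,j(t) + e$, with $A$ the
channel-by-vertex sensitivity restricted to the field of view and a
diagonal channel noise covariance $\Sigma_d$ estimated from a baseline
period of the data being reconstructed.

## Depth-weighted minimum-norm estimate

The closed form
$j(t) = \Sigma_s A^T (A \Sigma_s A^T + \kappa\,\Sigma_d)^{-1} m(t)$
with $\mathrm{diag}(\Sigma_s) = \mathrm{diag}(A^T\Sigma_d A)^{-\omega}$.
The depth exponent $\omega$ defaults to 0.3 (the low end of the range
reported as optimal for fNIRS reconstructions); zero-sensitivity columns
get weight zero and are excluded with a warning. One Cholesky
factorization is reused across all time samples. The regularization
$\kappa$ can be fixed or selected by an L-curve: 30 log-spaced values
spanning $10^{-6}$ to $10^{2}$ times
$\mathrm{tr}(A\Sigma_sA^T)/\mathrm{tr}(\Sigma_d)$, evaluated on the
whole window, choosing the point of extreme discrete curvature of the
log-residual/log-norm curve (traversed with increasing $\kappa$ the
corner turns clockwise, so the most negative signed curvature is the
corner); a flat curve falls back to the smallest grid value with a
warning.

## Maximum entropy on the mean (cMEM)

The prior organizes the field of view into $K$ non-overlapping,
edge-connected parcels. Per parcel $k$ the source vector follows a
spike-and-slab (Bernoulli-Gaussian) reference distribution
$(1-\alpha_k)\,\delta_0 + \alpha_k\,N(0, \Sigma_k(t))$.

*Prelocalization scores.* Each unit-normalized forward column is scored
by the squared norm of its projection onto the principal subspace of the
noise-whitened data window; scores live in $[0,1]$ and are invariant to
global data scaling. The subspace dimension is chosen by a 95% energy
rule applied to the *above-noise-floor* part of the singular spectrum
(floor = median squared singular value). The plain energy rule was
rejected during design: with realistic noise it absorbs noise
dimensions, every normalized column then scores about
$\dim/\,N_c$, junk parcels receive mid-range activation probabilities,
and the parcel switch-off that gives the method its focality is lost.
The floor rule reduces to the plain rule in the noise-free limit.

*Parcellation.* Greedy region growing: the highest unassigned score
seeds a parcel, which absorbs still-unassigned vertices within a
geodesic radius (breadth-first through unassigned vertices, so parcels
stay connected; ties go to the earlier seed). The radius is tuned by
bisection so that $K$ is as close as possible to the channel count.
A disconnected field of view is parcellated per component with a
warning.

*Initialization.* $\alpha_k$ is the median score in the parcel, with
values reaching 0.8 promoted to exactly 1. The parcel covariance is
$\Sigma_k(t) = W^T \Lambda W\, \eta_k(t)$: $W$ is a row-normalized
one-step mesh-diffusion smoother with weight $\sigma = 0.6$ (an isolated
vertex keeps weight 1 on itself), $\Lambda =
\mathrm{diag}(A_k^TA_k)^{-\omega}$ the within-parcel depth weighting,
and $\eta_k(t)$ is 5% of the parcel mean of the squared minimum-norm
solution computed with identity noise covariance and max-normalized per
time sample.

*Units.* Because $\eta_k$ is defined on the max-normalized minimum-norm
solution, the dual problem is solved in the units in which that
normalized solution lives: each sample is scaled by
$s(t) = \max_i |j^{MNE}_i(t)|$ (data by $1/s$, noise covariance by
$1/s^2$) and the source estimate scaled back. Without this the prior's
absolute scale is arbitrary relative to the data and the solver over- or
under-fits noise depending on signal amplitude. The per-sample scale is
exposed on the returned object.

*Optimization.* Per time sample the concave dual
$D(\lambda) = \lambda^T m - \sum_k F_k(A_k^T\lambda)
 - \tfrac12 \lambda^T \Sigma_d \lambda$, with free energy
$F(s) = \log((1-\alpha) + \alpha e^{s^T\Sigma s/2})$, is maximized by a
damped Newton ascent from $\lambda = 0$ with backtracking line search —
the Hessian is available in closed form, so convergence to the unique
maximizer takes a handful of iterations. Convergence is declared when
$\|\nabla D\|_\infty \le 10^{-7}(1 + \|m\|_\infty)$; overflow in the
free energy and its derivative is guarded with log-sum-exp forms, and
activation probabilities are clipped away from 0/1 inside logarithms.
The posterior activation is the tilted posterior
$\alpha^*_k = \alpha_k / (\alpha_k + (1-\alpha_k)e^{-q_k})$ with
$q_k = \tfrac12 \lambda^{*T} A_k \Sigma_k A_k^T \lambda^*$ — note the
negative exponent, which is the direction in which evidence *increases*
activation and the only sign consistent with the derivative of the free
energy and with the stationarity identity
$A j^* + \Sigma_d\lambda^* = m$. The source estimate is
$j_k^* = \alpha_k^* \Sigma_k A_k^T \lambda^*$; with every $\alpha_k$
forced to 1 the whole pipeline reduces exactly to the minimum-norm
closed form with $\Sigma_s = \mathrm{blockdiag}(\Sigma_k)$ and
$\kappa = 1$ in the scaled units, which the tests verify.

Hemoglobin maps on the surface come from the per-vertex 2x2 extinction
inversion of the two wavelength reconstructions; no pathlength division
is involved because the reconstruction is already local.

# Optimal optode placement

The placement problem is the 0-1 program: binaries for "source at p",
"detector at q" and "channel p-q active", maximizing summed ROI
sensitivity of active channels, under equipment counts, at most one
optode per position, a channel distance window, a minimum distance
between any two chosen optodes, and a per-source adjacency (minimum
channel count) constraint. Channel activation is linked to the position
binaries by the standard linearization; since the sensitivities are
nonnegative, every admissible channel is active at the optimum and the
objective is determined by the chosen position sets. The solver is an
exact depth-first branch-and-bound over source and detector subsets with
an admissible top-k bound on the remaining detector gains; ties are
broken toward the lexicographically smallest sorted index vector so
results are reproducible. A soft time limit returns the incumbent with
status `feasible`; infeasibility is reported as such. On every small
instance the tests compare the result against exhaustive enumeration.

# The phantom and what it does (not) show

`makePhantom` builds nested spheres (default outer radii 92/85/81/78/65
mm for skin/skull/CSF/gray/white, 2 mm voxels), an icosphere cortical
mesh at the mid-gray radius (subdivision 4, 2562 vertices), and a
two-ring probe: 8 sources at 15 degrees polar angle, 8 detectors at 30
degrees, azimuthally interleaved so each source forms two 27 mm
channels, plus two 8 mm short-separation detectors. These sizes keep a
full build-simulate-reconstruct cycle within minutes on one CPU while
leaving a few hundred field-of-view vertices.

`simulateRecording` runs the generative model forward: a boxcar train
(default twenty 10 s blocks with rest jittered uniformly over 30-60 s, a
standard block design; the jitter also prevents oscillatory noise from
phase-locking to the epoch grid) convolved with the canonical HRF drives
+10/-3 uM HbO/HbR in a 12 mm geodesic patch; surface Beer-Lambert gives
per-wavelength cortical optical density; the forward matrix projects to
channels; structured noise is added — cardiac (1.1 Hz), respiratory
(0.25 Hz) and Mayer (0.1 Hz) sinusoids with random phases shared between
the two wavelengths of a pair (both sample the same tissue, which is
what makes the simulated scalp coupling index high), AR(1) drift,
a random-walk superficial component shared across channels (what the
short channels see), and exponentially decaying motion spikes — scaled
so that the peak evoked optical density over the per-channel noise
standard deviation equals the requested SNR (default 5). Intensities
are synthesized as $I_0 10^{-\Delta OD}$.

What the phantom does *not* emulate: realistic sulco-gyral anatomy and
the resulting depth heterogeneity, Monte-Carlo photon statistics,
wavelength-dependent tissue attenuation, optode coupling variation, and
spatially correlated physiological noise beyond the single shared
superficial component. Passing the end-to-end checks therefore
demonstrates internal consistency of the pipeline and the qualitative
behavior of the solvers (the entropic solver reconstructing the active
patch at least as compactly as the minimum-norm solution at matched
data), not performance on real recordings.

Validation metrics: spatial dispersion
$\sqrt{\sum_i d_i^2 j_i^2 / \sum_i j_i^2}$ with $d_i$ zero inside the
ground-truth set and otherwise the geodesic distance to its nearest
member, and the rank-based (Mann-Whitney) ROC area of the absolute map
against truth membership. Both are checked against brute-force oracles.

# Degenerate inputs and tie-breaking, in one place

* Zero-variance cardiac-filtered signals: SCI missing, channel flagged.
* Nonpositive intensity anywhere: channel flagged; OD conversion refuses.
* Zero-variance superficial regressor: regression skipped with warning.
* Rank-deficient designs: warning naming the dropped columns;
  coefficients from the pivoted fit with absent columns zeroed.
* All-zero sensitivity columns: excluded from depth weights with warning.
* Flat L-curve: smallest grid kappa with warning.
* Zero data window: uniform prelocalization scores 0.5 with warning.
* Region-growing ties: earlier (higher-score, then lower-index) seed wins.
* Placement ties: lexicographically smallest sorted position indices.
* Zero between-subject variance: group t guarded to a large finite value.

# Problem sizes used by the shipped checks

The test-suite fixtures are sized to run the whole chain comfortably on
a single CPU: the full phantom forward model (18 pairs x ~360
field-of-view vertices) is built once and shared; inverse-solver unit
checks run on an 8-channel icosphere cap; the GLM calibration uses 1000
null simulations of 600 samples; placement checks enumerate instances
with up to 10 candidate positions.

# Known limitations

* Prewhitening is AR(1), single pass; higher-order or iterated noise
  models are out of scope, as are robust (IRLS) GLM variants.
* The HRF has a fixed canonical shape; basis sets and deconvolution are
  not provided.
* The analytic fluence model is a geometric stand-in; absolute
  sensitivity units are not physically calibrated.
* Euclidean (not geodesic) distances define the field of view and the
  Voronoi cells.
* The placement solver is exact but exponential in the worst case; it is
  intended for the moderate search spaces of targeted-ROI montages, with
  a time-limited incumbent fallback.
* Wavelet-domain variants of the entropic solver, volumetric
  reconstruction, and joint two-wavelength priors are not implemented.
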