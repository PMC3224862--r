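---
title: "Measuring source-space MEG functional connectivity with megfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring source-space MEG functional connectivity with megfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Functional connectivity (FC) between brain regions is usually summarized
as correlation or coherence between signals from spatially separate
locations. MEG measures magnetic fields at sensors above the scalp, so
connectivity must be computed after projecting sensor data into source
space. The projection is the crux: because the inverse problem is
ill-posed, reconstructed timecourses at different voxels are not
independent. Cross-talk ("signal leakage") between voxels manufactures
spurious connectivity, and any credible FC measurement must quantify and
discount it. `megfc` implements a complete, testable version of this
methodology on synthetic data: forward model, scalar beamformer,
envelope- and coherence-based FC metrics, leakage diagnostics, and a
simulation-based null framework for significance.

## Forward model

Sources are current dipoles inside a spherically symmetric conductor;
sensors are point magnetometers. The field of a dipole in a sphere has
the well-known closed form in which radial dipoles and a dipole at the
center are exactly silent, and the external field is independent of the
sphere radius (only the center matters). The multi-sphere variant reuses
the same closed form with per-channel sphere centers. A source is
parametrized as `theta = [r, delta]`: a location plus an orientation
angle `delta` within the local tangential plane, measured from the
azimuthal direction. The azimuthal direction is fixed deterministically
as `normalize(z x radial)` (falling back to `x x radial` on the polar
axis), so results are reproducible run to run.

The test suite validates the closed form against an independent
numerical oracle: the primary-current Biot-Savart field plus the
volume-current contribution computed as a surface integral of the
conductor-surface potential, where the potential itself is obtained
numerically (infinite-medium dipole potential plus a harmonic Neumann
correction projected degree-by-degree with the Legendre addition
theorem on a Fibonacci surface grid). The two routes agree to better
than 0.1%.

## Beamformer

The scalar linearly-constrained minimum-variance (LCMV) beamformer
estimates the source amplitude at `theta` as `Q(t) = W' m(t)` with

```
W = (C + mu*sigma*I)^-1 L / (L' (C + mu*sigma*I)^-1 L)
```

where `C` is the sensor covariance of mean-corrected, band-filtered
data, `L` the lead field, `sigma` the uncorrelated-noise power estimated
as the minimum singular value of `C`, and `mu` the regularization
parameter (default 4). Weights are computed per frequency band because
the covariance is band-specific; `sigma` is likewise recomputed per band
(the package documents the alternative of estimating it once broadband).

**Orientation.** At each voxel `delta` maximizes the projected variance
`W(delta)' C W(delta)` under the unit-gain constraint. With
`L(delta) = cos(delta) L1 + sin(delta) L2`, this variance is the ratio
`N(phi)/D(phi)^2` of two first-order trigonometric polynomials in
`phi = 2*delta`. A popular shortcut treats the problem as a 2x2
generalized eigenproblem, but that is exact only for `mu = 0`; with
regularization it maximizes a surrogate. `megfc` instead solves the true
stationarity condition `N'D - 2ND' = 0` exactly: after the Weierstrass
substitution it is a quartic in `tan(phi/2)`, solved with `polyroot`,
with `phi = pi` checked as the remaining candidate. The solution is
validated against a 0.1-degree grid search. When `C` is proportional to
the identity the "maximal variance" orientation degenerates to the
minimum-lead-field-norm direction, a known artifact; it is returned with
a warning.

**Localization maps.** Raw projected variance has the textbook depth
bias (unit-gain weights amplify noise where sensitivity is low), so
`scan_grid` also returns the noise-normalized variance
`W'CW / (sigma W'W)` (pseudo-Z), and task contrasts use the pseudo-T
form `(P_active - P_control) / (sigma W'W)`, which is invariant to a
global gain on the data. Only peak locations of these maps are part of
the tested surface, not their magnitudes.

**Leakage diagnostics.** The absolute Pearson correlation between the
seed voxel's weight vector and every other voxel's weights maps where
leakage can masquerade as connectivity; the analogous lead-field
correlation map shows what a non-adaptive method would suffer. In
matched simulations the weights-correlation volume above 0.25 is
smaller than the lead-field-correlation volume — the adaptive filter
decorrelates overlapping field patterns when distinct signals are
present — and the volume shrinks further when the covariance window
includes a task phase that modulates power.

## Spectral processing

Band filtering uses windowed-sinc (Hamming) FIR kernels with cutoffs
half a transition band outside the band edges; the transition width is
`min(f_lo/2, bandwidth/2, headroom to Nyquist)`. Zero phase is obtained
by applying the kernel forward and backward, realized as one centered
convolution with the kernel's autocorrelation (mathematically
identical); passband gain is within 1% and stopband rejection exceeds
40 dB one octave below the lower edge. The seven analysis bands are
delta (1-4), theta (4-8), alpha (8-13), low beta (13-20), high beta
(20-30), low gamma (30-40) and high gamma (40-70 Hz), with an optional
40-50/50-70 Hz split of high gamma.

The Hilbert envelope is the modulus of the FFT analytic signal. One
second per end is trimmed (configurable) before metrics are computed, to
discard transform edge artifacts; the published description is silent on
trimming, so it is exposed as configuration rather than hard-coded.
Segmentation divides a timecourse into `n = floor(duration/Delta)`
contiguous windows, discarding the remainder.

## FC metrics

Four metrics are computed between a seed and a test timecourse, all on
resting-phase data only:

* **AEC** — Pearson correlation of the two Hilbert envelopes within each
  segment, averaged across segments. Segments where either envelope is
  constant are dropped (with a count).
* **CAE** — each envelope collapsed to one mean per segment; one Pearson
  correlation between the two n-point averaged envelopes. Collapsing is
  effectively a low-pass filter on the envelope, so CAE emphasizes slow
  co-modulation and is typically larger than AEC on the same data.
* **Coh / ICoh** — band coherence from the segment DFTs. A single bin's
  normalized cross-spectrum is always unit modulus, so the auto- and
  cross-spectra are pooled over in-band bins *within* each segment
  before normalization, then averaged across segments. ICoh takes the
  absolute imaginary part per segment (sign removed because burst phase
  may flip between windows; a signed variant is available). The
  imaginary part excludes zero-lag correlation and is therefore
  insensitive to leakage.

No taper is applied by default (matching the bare formula); a Hann
option exists. Per-segment timecourses of AEC/Coh/ICoh provide dynamic
FC; CAE has no per-segment values by construction.

## Significance: the simulated-dipole null

Real and simulated data are processed identically. Each null dataset
contains two dipoles — seed fixed, test at the probed location — with
independent band-limited Gaussian timecourses (variance matched to the
values estimated from the data), multiplied by their lead fields and
added to sensor noise. Any FC measured on such data is spurious by
construction. For images, one dataset is simulated per test voxel; the
sensor-noise record is shared across voxels, like a fixed empty-room
recording.

Single-subject thresholding: (1) voxels are binned by weights
correlation (width 0.05) and the mean null FC per bin computed; (2) the
bin means are subtracted from real and null maps alike (empty bins fall
back to the nearest populated bin); (3) real voxels above the upper
fifth percentile of the corrected null distribution are declared
significant. Quantiles use linear interpolation between order statistics
(`type = 7`), stated explicitly because "upper fifth percentile" is
convention-dependent. The correction is a constant shift within each
bin, so it never reorders voxels within a bin.

Pair-level group analysis: per subject, the mean of the null ensemble is
subtracted from the real value; the mean-corrected null ensembles are
concatenated across subjects (6 subjects x 100 iterations = 600 points)
and the 95% (or 90%) quantile is the confidence limit for the
across-subject mean. Voxel-level group analysis uses an exact two-sided
Wilcoxon signed-rank test on the paired real-minus-null values. With
n = 6 the asymptotic approximation is wrong, so the null distribution is
enumerated exactly (by convolution over the tied-rank generating
function, equivalent to enumerating all 2^n sign assignments); the
attainable floor at n = 6 is p = 2/64 = 0.03125, and under a global null
only the all-same-sign outcomes pass p < 0.05, giving a 3.125% voxelwise
rate. No multiple-comparison correction is applied by default, with an
optional Bonferroni flag.

Envelope-spectrum-matched surrogates address a subtler confound: white
simulated timecourses have flat envelope spectra, so a real-vs-null
difference could reflect univariate envelope statistics rather than
coupling. `spectrum_matched_envelope_source` builds a carrier modulated
by an envelope with a prescribed power spectrum and randomized phases;
matching the spectrum leaves null-level FC unchanged, which is tested as
a property.

## The synthetic world

Every input is generated by code from (parameters, seed):

* **Helmet** — deterministic Fibonacci points on a spherical cap
  (default 64 channels at 0.12 m, 60% coverage), radially oriented.
  Gradiometer hardware is not modeled; noise enters at the sensors.
* **Sensor noise** — rank-8 spatially correlated Gaussian noise plus a
  white floor (30% of variance), 5e-14 T per channel. The amplitude is
  an instrument figure: ~5 fT/sqrt(Hz) over a ~100 Hz band. It also
  keeps `mu = 4` regularization in the regime real pipelines operate in;
  with a starved noise floor the adaptive filter over-sharpens and
  suppresses sources that sit between grid points, which no real MEG
  system exhibits.
* **Coupled pair** — each source is a band-limited Gaussian carrier
  multiplied by a positive slow modulator (rectified, smoothed Gaussian
  noise, bandwidth 0.5 Hz, consistent with envelope power concentrated
  below ~1 Hz). The modulators share a component with weight `alpha`;
  the carriers are always independent. At `alpha = 1` envelope metrics
  see strong coupling while phase metrics see none — the dissociation
  between envelope correlation and coherence. Because the carrier
  contributes fast envelope jitter, the measurable AEC at `alpha = 1`
  is well below 1; `calibrate_coupling` maps `alpha` to the expected
  AEC by Monte-Carlo. (An earlier design used constant-modulus carriers;
  their spectral tails put ~30% of source power outside the analysis
  band and were abandoned.)
* **Background activity** — resting cortex is active in every band. The
  default experiment adds 8 uncoupled broadband (1 to ~70 Hz) dipoles at
  random locations (1e-8 A m each) and, critically, an uncoupled
  broadband component co-located with each source of interest (equal in
  amplitude to the coupled component). Without the local component, an
  analysis band away from the coupled band would contain nothing at the
  seed but the coupled source's filter skirt, and envelope metrics —
  being amplitude-insensitive — would report the coupled envelope in
  every band. The calibration curve accepts a `local_background` ratio
  so expectation and generation stay consistent.
* **Localizer** — task blocks multiply the coupled sources' amplitude by
  0.4 ("movement" suppresses beta power), so pseudo-T contrasts localize
  the sources as a power decrease.
* **Hemodynamic volume** — two Gaussian blobs at the source locations
  whose slow timecourses share a component scaled by the coupling, plus
  spatially smoothed noise; a stand-in for seed-based resting fcMRI.
  Default source coordinates lie on round 10/20 mm lattice positions.

The desk-scale recipe (64 channels, 100 s, 300 Hz, 10 mm grid) keeps
full pipelines tractable; `paper_scale_recipe()` (275 channels, 300 s,
600 Hz, 5 mm) is the full-scale variant.

## What a green test does and does not establish

The generator emulates: dipolar band-limited sources with controllable
envelope coupling, task power modulation, spatially correlated sensor
noise, broadband background activity, and co-registered hemodynamic
blobs. It does not emulate: realistic head geometry (BEM/FEM),
gradiometer pickup, cardiac/respiratory waveforms (covered only by the
low-rank noise generator), 1/f spectral shape within bands, nonstationary
source statistics, or real anatomical variability. Green acceptance
tests therefore establish internal correctness and calibration of the
*methodology*, not fidelity to any particular recording.

In the acceptance suite, simulation sizes are scaled down (channel
counts, durations, grid spacings, iteration counts) to fit a single-CPU
budget; each test states its scaling. Quantities the criteria fix as
part of the stated world — 10 seeds, `alpha = 0.8`, n = 6 subjects, the
SNR >= 5 bound — are kept. The cross-modal band-specificity check uses
the seed-exclusion variant of spatial correlation (30 mm): at desk
scale the whole-brain comparison is dominated by the seed's leakage
point-spread, which is shared across bands and reflects image
smoothness, not connectivity; excluding the seed neighborhood compares
the distal structure the criterion is actually about. (Whether the
published comparison excluded the seed neighborhood is not stated; both
variants are available, whole-brain being the default.)

## Numerical choices

* Quantiles: linear interpolation (`type = 7`) everywhere.
* Map peak ties: smallest linear voxel index, with a message.
* Zero-variance weight/lead-field vectors in correlation maps: value 0
  with a warning; zero-variance AEC segments: dropped with a count.
* Empty weights-correlation bins: nearest populated bin.
* The voxel grid excludes the lattice point at the sphere center (its
  lead field is identically zero).
* Covariance uses `n - 1`; windows shorter than the channel count warn.
* All randomness flows through explicit integer seeds; generators do
  not disturb the caller's RNG stream.

## Limitations

Single-sphere (or per-channel-sphere) conductors only; no vector
beamformer; no eigenspace or nulling variants; no resolution-kernel
analysis; no multi-taper spectra (segmented DFTs are known to be biased
at small `Delta`, which is why real and null data must always be
processed identically); phase-randomization surrogates are not
implemented. NIfTI-1 I/O is a minimal single-file float32 writer/reader
with a diagonal affine; run archives use RDS.
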