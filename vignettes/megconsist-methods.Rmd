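---
title: "Source-space consistency of MEG spectra and connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space consistency of MEG spectra and connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megconsist)
```

## The question the pipeline answers

When a laboratory replaces its MEG system, longitudinal studies suddenly mix
recordings from different hardware: different channel counts and sensor
types, different sampling rates, different vendor beamformers. The working
hypothesis of this package is that projecting all sessions into a common
*source space* — one reconstructed time series per anatomical region —
makes spectral and connectivity measures comparable across systems, so that
a subject measured years apart on different machines still looks like
*themselves*: within-subject consistency should exceed between-subject
consistency.

Because raw clinical MEG recordings are not redistributable, the package is
built around a fully synthetic but physically grounded cohort: each subject
receives a generative *fingerprint*, sessions are forward-modelled onto two
simulated sensor systems, and the complete analysis chain — beamformer
reconstruction, normalized spectra, leakage-corrected amplitude envelope
correlation (AEC-c), and the within/between statistical framework — is then
asked to recover the fingerprint structure. Everything downstream of the
simulator is exactly the analysis a user would run on real data.

## The simulated cohort

The default cohort (`cohort_spec()`) is 8 subjects, each with three
sessions: two on a 151-channel axial-gradiometer helmet (312.5 and 625 Hz
native rates) and one on a 306-channel helmet carrying 102 magnetometers and
204 planar gradiometers (1250 Hz), five minutes of eyes-closed rest per
session.

A subject's fingerprint consists of:

* an **alpha peak frequency**, uniform on 8–12 Hz — the population range of
  the dominant posterior rhythm;
* a **1/f background exponent**, uniform on 0.8–1.4;
* relative **band amplitudes** (delta, theta, alpha, beta, gamma) with
  log-normal subject jitter around typical resting-state ratios
  (alpha-dominant, weak gamma);
* one **envelope-coupling target matrix** per band (alpha, beta): a random
  modular partition of the 90 regions into 6 communities, within-community
  coupling drawn uniformly from 0.35–0.7, projected to the nearest valid
  correlation matrix (unit diagonal, entries in [0, 0.8], positive
  semi-definite within 1e-8);
* per-region **dipole moments** around 30 nAm with log-normal jitter.

Per region the signal is

$$x(t) \;=\; b(t) \;+\; a_\alpha\, c_\alpha(t)\, e_\alpha(t)
          \;+\; a_\beta\, c_\beta(t)\, e_\beta(t),$$

where $b$ is 1/f-shaped background noise over 0.5–48 Hz (the delta, theta
and gamma band amplitudes weight its spectrum in their ranges), the carriers
$c$ are independent band-limited noise per region — the alpha carrier has a
Gaussian spectral profile (SD 0.4 Hz) centered on the subject's alpha peak,
the beta carrier is flat over 13–30 Hz — and the envelopes $e$ are slow
(~1 Hz low-pass) Gaussian processes, coupled across regions through the
matrix square root of the band's coupling target and rectified by absolute
value. Coupling is imposed on *envelopes*, not raw signals, so that the
leakage-corrected envelope metric can in principle detect it; because
rectification and carrier modulation attenuate the realized correlation,
only monotonicity in the target — never equality — is asserted anywhere.

Carriers and envelopes are synthesized in the frequency domain at a 312.5 Hz
base rate and, for higher native rates, upsampled by exact spectral zero
padding (all content lies far below the base Nyquist). Sensor noise is white
Gaussian per channel with per-kind standard deviations (5 fT for
gradiometer and magnetometer field channels, 0.3 pT/m for planar
gradiometers, T/m units); it is drawn from a dedicated counter-seeded
generator so that sessions are bit-reproducible. All randomness derives from
one master seed through a fixed label hash (`seed`, subject, timepoint,
purpose), so any session can be regenerated in isolation.

What the generator deliberately does **not** emulate: cortical anatomy and
realistic (BEM/FEM) volume conduction, ocular/cardiac/muscle artifacts, head
movement, and any true change over time. Consequently a passing recovery
experiment shows that the pipeline preserves subject-specific structure
across sensor systems under ideal physics — not that it would survive
artifact regimes or co-registration error on real data.

## Forward model and geometry

Fields are computed with the closed-form solution for a current dipole in a
homogeneous conducting sphere (head radius 0.09 m). Two exact properties of
that model — a radially oriented dipole and a dipole at the sphere's center
produce no external field — fall out of the implementation algebraically
(the cross product $m \times r_0$ vanishes) and are asserted as exact zeros
in the tests. Helmet geometry is not published for either system, so both
arrays are quasi-uniform Fibonacci layouts on a spherical cap (helmet radius
0.105 m): 151 axial gradiometers (5 cm baseline along the radial normal) or
102 sites each holding a radial magnetometer and two orthogonal planar
gradiometers (1.68 cm baseline perpendicular to the normal). True atlas
centroid coordinates are likewise not published; the default layout is a
synthetic stand-in — 78 "cortical" points at radii 6–7.5 cm plus 12
"subcortical" points at 2–4.5 cm — and any user-supplied 90-row coordinate
table can replace it. A multi-sphere variant (per-channel sphere centers) is
supported as the minimal faithful generalization of vendor practice.

## Reconstruction

Each session is reduced to one broadband (0.5–48 Hz) time series per region
with a scalar LCMV beamformer: sample covariance of the band-passed good
channels over all retained samples, diagonally loaded with 5% of the mean
eigenvalue (the loading fraction is not specified by vendor
implementations; it is configurable and logged, and the unit tests document
why values below ~1% are numerically unsafe with brickwall-filtered noise);
per centroid, the source orientation maximizing output SNR via the
generalized eigenproblem $(L^\top C^{-1}L)\nu = \lambda(L^\top
C^{-2}L)\nu$, restricted to the two leading right singular vectors of the
lead-field block because the sphere model's radial direction is silent; then
unit-gain minimum-variance weights, normalized to unit Euclidean norm.
Weight normalization rescales amplitude only — the tests assert AEC
matrices are identical with and without it. The sign of the orientation
(and hence of each source series) is arbitrary; it is fixed
deterministically and envelopes are sign-invariant anyway. One beamformer
serves both simulated systems: the difference between vendor
implementations is represented by the different arrays, rates and noise,
which is the robustness claim under study.

The three sessions follow different paths to a common 312.5 Hz epoch
structure, as the mixed-rate design requires: the 312.5 Hz session is
beamformed directly; the 625 Hz session is decimated 2x at the sensor level
first; the 1250 Hz session is beamformed at its native rate and the source
series decimated 4x. Decimation is an anti-alias brickwall low-pass at 0.8x
the new Nyquist followed by keeping every k-th sample — implemented as
exact spectrum truncation (zero-phase by construction; a forward-backward
IIR filter would achieve zero phase only approximately and distort band
edges). Epochs are 4096 samples (13.11 s), trailing remainders discarded.

Channel and epoch screening, done visually in practice, are automated
deterministic stand-ins: a channel is flagged when the robust z-score of its
log-variance within its own channel kind exceeds 4; an epoch is dropped when
any channel's peak amplitude exceeds 6 robust z-units of the per-channel
epoch-peak distribution, computed on the log scale with a pooled MAD because
per-channel scale estimates from a handful of epochs are unstable and peak
distributions are right-skewed. Both thresholds are configurable and all
decisions land in the run report.

## Spectra and connectivity

Spectral analysis averages single-taper periodograms over the 4096-sample
epochs and all 90 regions (Bartlett's method; the frequency resolution of
0.076 Hz is fixed by the epoching, and averaging 15–22 epochs controls
variance, so no taper is applied by default — a Hann option exists). The
average is restricted to 0.5–30 Hz (the band on which the two systems'
spectra are comparable; broadband gamma differs between systems for
artifact-handling reasons outside this model) and normalized by its own
area, making it a unit-mass density invariant to global amplitude. The peak
frequency is the argmax bin within 4–13 Hz, ties toward the lower
frequency, no interpolation — consistent with bin-level precision.
Normalization happens per subject and session *before* any group averaging,
matching its use in the per-subject distance statistics.

Connectivity per band (alpha 8–13 Hz, beta 13–30 Hz) and per epoch:
brickwall band-pass (DFT coefficients outside the band set exactly to
zero), pairwise orthogonalization in both directions — time-domain
regression of one band-limited signal on the other, removing zero-lag
leakage — Hilbert envelopes, Pearson correlation of the envelopes with the
first and last 5% of samples discarded (edge guard against Hilbert edge
artifacts on 13.11 s epochs; the guard is not part of the original recipe
but is necessary at this epoch length), the two directional correlations
averaged and rescaled by $(r+1)/2$ into $[0,1]$. Averaging before the
rescale versus after is affine-equivalent; this package averages first.
Envelopes are not low-pass filtered or downsampled before correlation. The
4005 unordered pairs per epoch are averaged element-wise over epochs into
one 90 x 90 matrix per band and session; a pair whose residual is exactly
zero (one signal proportional to the other) is undefined in that epoch and
excluded from its average. Because the Hilbert transform is linear, the
analytic signal of the residual $y - \beta x$ is $A_y - \beta A_x$; the
compiled kernel exploits this to serve all pairs from one analytic matrix
per epoch, and is cross-checked against a direct pairwise reference
implementation in the tests.

## The statistical layer

Consistency of spectra is measured by the two-sample Kolmogorov–Smirnov
statistic applied to the binned normalized spectra treated as probability
masses — $D$ is the primary quantity; the attached asymptotic p-value
(effective n = bins/2) is labelled approximate because spectral bins are
not independent samples. Consistency of connectivity is the Spearman
correlation of the vectorized upper triangle (diagonal excluded; average
ranks for ties; the upper triangle avoids duplicating every tied pair that
full off-diagonal vectorization would create).

Within-subject values compare a subject's own sessions (three ordered
pairs); between-subject values average one subject's cross-sectional
consistency with all others at a fixed timepoint. With 8 subjects and 3
timepoints this yields 24 within and 24 between values per metric, and the
within-versus-between comparison is a two-tailed pooled-variance t-test
with df = 46 — the reading of "average within-subject correlations" that
the published df forces, rather than 8 per-subject means. Time effects are
tested with the textbook one-way repeated-measures ANOVA, $F =
MS_{cond}/MS_{cond\times subj}$ with df $(k-1, (k-1)(n-1))$ — i.e. (2, 14)
for 8 subjects — and partial eta squared $SS_{cond}/(SS_{cond}+SS_{err})$.
Published tables in this literature sometimes print F(2, 7)/F(2, 21) for
this design; those dfs are not reproducible from the standard decomposition
and the implementation does not contort itself to match them. No sphericity
correction is applied. Degenerate inputs are handled deterministically: a
zero condition effect reports F = 0, p = 1; a zero error sum of squares
with a nonzero effect reports F = Inf, p = 0; a paired test on constant
differences is flagged degenerate.

## The two recovery experiments

`replication_experiment()` is the study design in silico: independent
cohorts of 8 subjects x 3 sessions (two axial-gradiometer, one
magnetometer/planar system), full forward and inverse modelling, and the
complete statistical layer; a cohort counts as a success when within-subject
consistency beats between-subject consistency on all three metrics (lower
KS-D, higher alpha and beta Spearman) with unpaired p < 0.05. The
acceptance suite requires at least 9 of 10 cohorts to succeed. Sessions run
at 60 s rather than 5 min — four epochs per session — which is the
smallest length at which the envelope statistics are stable enough to be
interesting while keeping ten full cohorts inside a practical compute
budget; the per-cohort effect sizes at 60 s are already extreme (p around
1e-12 or smaller), so the shortening does not carry the result.

`anova_null_calibration()` checks that the repeated-measures ANOVA holds
its nominal level on this pipeline's own consistency values when no time
effect exists: 100 independent cohorts, three exchangeable same-rate
sessions per subject, within-subject KS-D tables at source level, expecting
a ~5% rejection rate. Source-level spectra (no sensor projection or
beamforming) are used here deliberately: the null being calibrated is the
exchangeability of timepoints, which the — much more expensive — inverse
modelling stage cannot break, and session length is two epochs (26.21 s),
the minimum the epoch structure admits. The measured rate in the acceptance
run is reported by `scripts/acceptance.R`.

## Numerical choices and edge cases

* Band-edge convention: closed intervals on DFT bin centers, everywhere.
* Orientation tie-break: if the two generalized eigenvalues agree within
  1e-9 relative, the lexicographically smallest sign-fixed candidate is
  returned with a warning (exercised by the C = I case).
* The covariance, weight projection, decimation and upsampling all operate
  on masked DFT coefficients with conjugate-pair packing of real channels;
  each fast path is tested for exact (1e-12) agreement with its brute-force
  time-domain counterpart.
* `aec_corrected_pair()` returns NA (never a number) for exactly
  proportional inputs; `aec_matrix()` errors only if a pair is degenerate in
  every epoch.
* All text artifacts are written with 17 significant digits, so re-running a
  seeded pipeline reproduces byte-identical files and checksums.

## Known limitations

The realized AEC-c values compress toward 0.5 after beamformer leakage and
orthogonalization, so within-subject Spearman values of the synthetic
cohorts (~0.1–0.25) sit below those reported for real long-term retest
data; the discriminative property, not the absolute level, is the tested
claim. The spherical conductor model underestimates the spatial complexity
of real head geometry, and the automated artifact screens are far simpler
than human inspection. Single-epoch AEC-c estimates have a sampling SD of
about 0.05 in the alpha band at 4096 samples; properties about the 0.5
independence baseline therefore hold for means over epochs or pairs, not
per realization.
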