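# megconsist

Longitudinal MEG studies routinely span a change of recording system:
different sensor counts and types (axial gradiometers versus magnetometers
plus planar gradiometers), different sampling rates, different vendor
beamformers. **megconsist** implements, as a reproducible in-silico
pipeline, the test of whether *source-space* analysis makes such mixed-system
data comparable: it simulates a cohort of subjects each recorded on two
different whole-head systems, reconstructs one time series per brain region
with a scalar minimum-variance beamformer, computes area-normalized power
spectra and leakage-corrected amplitude envelope correlation (AEC-c)
connectivity, and asks whether each subject's sessions resemble *each other*
more than they resemble other subjects.

It is aimed at MEG methodologists who want a tested, fully seeded reference
implementation of this analysis chain — from forward model to statistics —
and a synthetic test bed for it.

## The model and statistics in brief

* **Forward model.** Equivalent current dipoles at 90 region centroids in a
  homogeneous conducting sphere (Sarvas closed form); 151 axial gradiometers
  or 102 magnetometers + 204 planar gradiometers on a spherical helmet cap.
  Radial and central dipoles are exactly silent — both silences are asserted
  as exact zeros in the tests.
* **Synthetic cohort.** Per subject: alpha peak in 8–12 Hz, 1/f background
  exponent, band amplitudes, ~30 nAm dipole moments, and per-band (alpha,
  beta) 90 x 90 envelope-coupling correlation matrices with modular
  structure. Sessions of one subject are different stochastic realizations
  of the same "fingerprint".
* **Reconstruction.** Scalar LCMV beamformer on broadband (0.5–48 Hz)
  sensor covariance with 5% diagonal loading; optimal orientation per
  centroid from the generalized eigenproblem
  `(L' C⁻¹ L) v = λ (L' C⁻² L) v` on the tangential subspace; unit-gain
  weights `w = C⁻¹ l / (l' C⁻¹ l)`, normalized. Sessions at 625 Hz are
  decimated at the sensor level, sessions at 1250 Hz are beamformed at
  native rate and decimated at the source level; epochs are 4096 samples
  (13.11 s) at 312.5 Hz.
* **Measures.** Area-normalized ROI-averaged power spectra on 0.5–30 Hz and
  their alpha peak (argmax in 4–13 Hz); per-epoch brickwall band-pass
  (alpha 8–13, beta 13–30 Hz), bidirectional pairwise orthogonalization,
  Hilbert envelopes, Pearson correlation rescaled by `(r+1)/2` — averaged
  over epochs into one 90 x 90 matrix per band.
* **Statistics.** Spectral consistency = two-sample Kolmogorov–Smirnov `D`
  on binned spectra; connectivity consistency = Spearman rho of the
  vectorized upper triangle. Within-subject (3 session pairs) versus
  between-subject (per timepoint, averaged over the other subjects) values
  are compared with pooled two-sample t-tests (df = 46 for 8 subjects) and
  repeated-measures ANOVAs with partial eta squared.

## Worked example

A small cohort end to end (4 subjects, 60 s sessions — the defaults are 8
subjects and 300 s):

```r
library(megconsist)
sp  <- cohort_spec(n_subjects = 4, duration_s = 60, seed = 7)
res <- run_pipeline(run_config(sp))
summary(res)
```

```
Consistency values, mean (SD):
  ks_d
    between  BL       0.232 (0.051)
    within   BL-FU1   0.011 (0.005)
    within   BL-FU2   0.017 (0.002)
    ...
  spearman_beta
    between  BL       0.039 (0.016)
    within   BL-FU1   0.192 (0.032)
    ...
Statistics:
within vs between (ks_d): t(22) = -16.11, p = 1.165e-13
within vs between (spearman_alpha): t(22) = 9.149, p = 5.934e-09
within vs between (spearman_beta): t(22) = 7.944, p = 6.626e-08
peak frequency over timepoints: F(2, 6) = 0.6923, p = 0.5364, partial eta^2 = 0.187
```

Reading this: a subject's spectra stay close to themselves across sessions
and systems (within-subject KS-D ≈ 0.01–0.02) while different subjects'
spectra differ by an order of magnitude more (≈ 0.23); connectivity
matrices likewise rank-correlate far better within than between subjects in
both bands, with strongly significant unpaired t-tests; and the alpha peak
frequency shows no time/system effect, as it should when nothing true
changes over time. `plot(res, "spearman_alpha")` draws the within/between
distributions; `consistency_roi_map(res, "alpha")` gives the per-region
consistency map.

Individual stages are exported and usable on their own data structures:
`build_sensor_array()`, `lead_field()`, `simulate_source_activity()`,
`project_to_sensors()`, `decimate()`, `split_epochs()`,
`reconstruct_roi_series()`, `average_normalized_spectrum()`,
`aec_matrix()`, `build_consistency_table()`, `rm_anova()`, and friends. A
thin command-line wrapper with `simulate` / `reconstruct` / `analyze` /
`all` / `report` verbs lives in `inst/scripts/megconsist.R`.

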