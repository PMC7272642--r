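---
title: "Source-level MEG spectral biomarkers: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-level MEG spectral biomarkers: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Resting-state MEG band power, estimated at the cortical source level,
carries information about early-stage Alzheimer's disease (AD): regional
power in the theta–alpha range, its normalization against the whole
cerebrum, and its reactivity to eye opening all differ between AD patients
and cognitively normal controls (NC). `megspect` implements the complete
analysis chain for this class of study — band-limited regional source
power under eyes-closed (EC) and eyes-open (EO) conditions, whole-cerebral
normalization, EC−EO reactivity, Bonferroni-corrected mass-univariate
group comparison, and polynomial-kernel SVM discrimination — together
with a synthetic cohort generator, so that every stage can be validated by
parameter recovery on data whose ground truth is known. No subject-level
MEG from the motivating study design is publicly deposited, so the
package's empirical claims are about the method, demonstrated on synthetic
cohorts, not about any clinical dataset.

# Signal model

## Forward model

The head is a homogeneous conducting sphere (radius 9 cm). A current
dipole $\mathbf{q}$ at position $\mathbf{r}_0$ inside the sphere produces
the closed-form external magnetic field of the spherically symmetric
conductor (the standard volume-conductor solution), and the lead-field
column of a cortical vertex is the projection of that field onto each
sensor's sensing direction for a unit dipole along the vertex's source
orientation. Two exact properties of this geometry are used as physics
tests: a dipole at the sphere center and any radially oriented dipole
produce no external field.

Sensors are point magnetometers on a spherical cap (radius 11 cm, sensing
radially), a simplification of a whole-head gradiometer helmet that keeps
the inverse problem structure intact. Cortical vertices lie quasi-uniformly
(Fibonacci lattice) on an inner shell (radius 7 cm) restricted to the
upper cap of the sphere (`vertex_z_min = -0.25`): the cerebral mantle
occupies the cranial vault, and confining the shell to the helmet's
coverage ensures every parcel is magnetically visible. Source
orientations are seeded pseudo-random unit vectors *tangential* to the
shell. The spherical conductor is blind to radial dipole components, so
the tangential part is exactly what the array can see; random tangential
orientations stand in for the mixed gyral/sulcal orientations of real
cortex without leaving individual parcels silent.

The parcellation partitions vertices into 68 contiguous nearest-seed
patches labelled with the Desikan–Killiany atlas names (34 per
hemisphere, left first — the canonical region order of every table in the
package). Seeds are chosen per hemisphere by farthest-point sampling
among the vertices themselves, so every region owns at least its seed
vertex and `n_regions = n_vertices` degenerates to singleton regions.

## Inverse model

Source estimation is a depth-weighted, Tikhonov-regularized minimum-norm
estimate with fixed orientations:

$$ K = W L^\top (L W L^\top + \lambda^2 I)^{-1}, \qquad
   \lambda^2 = \frac{\operatorname{trace}(L W L^\top)}{n_{\text{chan}}\,\mathrm{snr}^2}, $$

with diagonal depth weights $W_{vv} = \lVert L_{\cdot v}\rVert^{-2p}$.
Defaults: $\mathrm{snr} = 3$ and $p = 0.5$, the conventions of
minimum-norm source-imaging software; $p = 0$ disables weighting.
Numerically silent columns get zero weight and zero estimates rather than
amplified noise. No noise-covariance whitening is applied: the synthetic
sensor noise is white by construction, so the identity covariance is
exact rather than a compromise.

## Regional "absolute power"

For each band, the source estimate of every retained 2-s epoch is
rectified and averaged over all time points per vertex, then averaged
(unweighted scout mean) over each region's vertices. The result is a mean
absolute current amplitude in A·m — an amplitude-domain quantity, not a
squared spectral density; the package follows the field's usage in
calling it absolute power. Implementation note: because both the inverse
operator and the zero-phase filter are linear, the pipeline applies the
inverse once to broadband epochs and band-filters the source time series;
a unit test asserts bit-level equality with the definitional order
(filter sensors per band, then invert).

# Preprocessing

* **Artifact rejection.** Contiguous 2-s blocks (aligned to the epoch
  grid) in which any channel exceeds 10 pT in absolute value are excised.
  Block-wise excision makes rejection idempotent and commuting with
  epoching. A trailing partial block is kept; epoching discards it anyway.
* **Epoching.** `floor(duration / 2 s)` consecutive non-overlapping
  epochs; the remainder is dropped.
* **Band-pass filtering.** The five analysis bands are theta1 4–6,
  theta2 6–8, alpha1 8–10, alpha2 10–13 and beta 13–20 Hz (delta is
  artifact-prone, gamma uninformative for this contrast; the theta and
  alpha splits sharpen discrimination). Filtering applies the *exact
  analog 4th-order Butterworth band-pass magnitude-squared response* in
  the frequency domain with 1-s reflection padding per epoch. This is the
  response of a forward–backward (zero-phase) Butterworth pass, without
  the coefficient-conditioning problems of bilinear-transform filters at
  small normalized frequencies, and it vectorizes over channels and
  epochs. A test verifies agreement with `signal::filtfilt` (correlation
  > 0.999 away from edges) and zero group delay.

# Feature construction

Per subject, six value types per (band, region): absolute power under EC
and EO; their whole-cerebral-normalized (WCN) z-scores
$(x_a - \bar{x}) / \mathrm{sd}(x)$ across the 68 regions; the EC−EO
difference; and the WCN of that difference. The WCN divisor is the
population SD (N), so WCN vectors have exactly zero mean and unit SD;
sample SD is available as an option. The canonical feature order is
value-type-major, then band, then region, giving the
$6 \times 5 \times 68 = 2040$-element vector with names like
`wcnEC.alpha1.rh_supramarginal`. WCN of a single-region grid is
undefined (zero dispersion), so reduced test grids need at least two
regions.

# Statistics

Each of the 2,040 cells is compared between groups with a two-tailed
Welch unequal-variance t-test (Student and Mann–Whitney variants are
config options). The significance threshold is
$0.05 / 68\ \text{regions} / 5\ \text{bands} = 0.000147$; the divisor
counts regions and bands only, so the threshold is applied within each
value-type family of 340 cells. Cells with zero variance in both groups
and equal means report $p = 1$ by convention.

# Classification

A soft-margin SVM with a second-order polynomial kernel
$(\gamma\,u^\top v + c_0)^2$, $c_0 = 1$, $C = 1$ (libsvm, solver
tolerance $10^{-8}$ for reproducibility). The kernel scale defaults to
$\gamma = 1/p$ for $p$ features — the SVM library's own convention, and
the analog of an automatic kernel scale. This choice matters: with
$p = 2040$ standardized features and $\gamma = 1$, kernel values are
$O(p^2)$ and the $C = 1$ soft margin degenerates toward the majority
class; $\gamma = 1/p$ keeps kernel values $O(1)$ at any dimension. All
kernel parameters are exposed in the configuration. Features are z-scored
with training-fold statistics only (population SD, so the fit is
invariant under duplicating the training set). Evaluation is stratified
subject-level 6-fold cross-validation: every subject is predicted exactly
once by a model that never saw it; pooled out-of-fold decision scores
(oriented AD-positive) define the ROC, and AUC is the trapezoidal
integral. AD is the positive class for sensitivity/specificity. A
published description of this design splits observations 1700/340, which
sums to the feature count rather than the subject count; subject-level
CV is the only internally consistent reading and is what the package
implements.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Cohort**: 20 AD + 27 NC subjects, EC and EO recordings each.
* **Source activity**: per region and band, a white-noise process
  band-pass filtered with the analysis filters (synthesis and analysis
  band edges agree exactly), scaled so its RMS equals the subject's drawn
  amplitude, shared by all vertices of the region (region coherence —
  locally synchronous cortical patches), plus a region-level $1/f$
  broadband floor (RMS $10^{-9}$ A·m).
* **Amplitudes**: the group × condition × band × region mean table
  assigns every region the same per-band baseline with EC > EO in every
  band — strongly in alpha (8 vs 4 nA·m in alpha1; alpha blocking) and
  mildly elsewhere. Between-subject variation is one log-normal factor
  per (band, region) with unit mean and CV 0.2, drawn once per subject
  and shared across conditions, so reactivity is subject-consistent and
  amplitudes stay positive. The AD group's mean in the designated effect
  cell (alpha1, right supramarginal by default) is raised by 2
  between-subject SDs (factor 1.4) in both conditions.
* **Sensing**: recording = lead field × sources, plus white sensor noise
  (SD 50 fT) and Poisson boxcar artifacts (2/min, 12 pT, 100 ms, one
  random channel each) that the 10 pT rejection stage must catch.
* **Determinism**: everything is a pure function of the spec seed;
  per-subject sub-seeds are derived once, and the template geometry has
  its own seed (the array and head model are fixed study apparatus while
  subjects vary — one template head stands in for per-subject MRI
  models).

What the generator does *not* emulate: spatially structured alpha
topography (no occipital dominance), 1/f slope differences between
groups, cardiac/ocular components (only threshold-detectable amplitude
spikes), gradiometer pickup geometry, head-position variation, and
inter-regional functional coupling. Passing recovery tests therefore
shows the *pipeline* is correct and sensitive under the stated
conditions, not that the pipeline would reproduce any particular clinical
result.

# Problem sizes

Three scales are used, chosen as the package's own trade-off between
fidelity and wall-clock cost:

* **Desk scale** (generator default): 64 channels, 500 vertices, 250 Hz,
  30 s — used for single-source localization checks (20 random vertices,
  ≥ 90% correct region).
* **Cohort-analysis scale** (replicate suites, analysis scripts):
  96 channels, 136 vertices (2 per region), 50 Hz, 30 s. Region-level
  amplitude unmixing requires more sensors than regions — with 64
  channels the rank-64 measurement cannot separate 68 simultaneously
  active parcels, and a 2-SD single-region effect drowns in leakage; 96
  channels resolve it. 50 Hz sampling keeps all band edges below 0.8 of
  the Nyquist frequency while making a full 47-subject × 2-condition
  cohort run in about 20 s.
* **Acquisition scale** (160 channels, 15,000 vertices, 1000 Hz, 120 s)
  is available behind `cohort_spec(acquisition_scale = TRUE)` for users with
  the patience; nothing in the code depends on the scale.

The replicate recovery suite runs 20 cohorts with the designated 2-SD
alpha1 effect and requires the (alpha1, right supramarginal) absolute-power
EC cell to clear the corrected threshold in at least 80% of them. The
false-positive suite runs 200 global-null cohorts at the ground-truth
amplitude level (the sensing chain adds nothing to a null) and bounds the
family-wise error of the absolute-power EC family, whose 340 cells are
independent by construction, at $0.05 + 2$ Monte-Carlo SE.

# Numerical choices and degenerate inputs

* Frequency-domain zero-phase filtering with reflection padding; the
  response at 0 Hz is exactly 0.
* Silent lead-field columns (norm < $10^{-12}$ of the maximum) get zero
  depth weight and zero estimates.
* WCN of an all-equal vector raises a degenerate-dispersion error rather
  than returning silent zeros.
* Welch cells with zero variance in both groups: $p = 1$ if means agree,
  $p = 0$ otherwise.
* Ties in ROC scores are collapsed to single thresholds; the curve always
  contains (0,0) and (1,1).
* Artifact rejection that leaves less than one epoch raises a
  "no usable data" error naming the subject and condition.

# Known limitations

* The spherical single-shell conductor and point magnetometers are the
  simplest physically valid acquisition model; absolute amplitudes are
  not calibrated against any real device.
* Minimum-norm scout estimates mix neighboring parcels. The package's
  recovery guarantees are stated for the cohort-analysis scale
  (96 channels); with substantially fewer sensors than parcels,
  single-region effects of this size are not recoverable by any linear
  distributed inverse of this family.
* The 2-s epoch length with 1-s reflection padding limits attenuation
  accuracy near band edges for the lowest band (4–6 Hz).
* Group comparison treats cells marginally; no spatial or spectral
  smoothing, and no FDR alternative (the corrected threshold is the
  study's design).
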