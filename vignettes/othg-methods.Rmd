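---
title: "Quantifying label-free THG imaging of cerebral organoids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying label-free THG imaging of cerebral organoids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(othg)
```

## Scope

Third-harmonic generation (THG) is a label-free nonlinear signal emitted
at one third of the excitation wavelength wherever refractive-index
interfaces (membranes, organelles) sit in the focal volume. In intact
cerebral organoids it resolves the dark, nucleus-dense ventricular zone
(VZ) wrapped around each ventricle-like cavity, the brighter cortical
plate (CP), and bright neuronal somata. `othg` implements the
quantitative analyses this kind of experiment needs — extinction-length
estimation, 3D VZ morphometry, soma tracking with migration statistics,
two-channel colocalization, and small-cohort group statistics — plus a
synthetic organoid phantom generator with exact ground truth, so every
stage of the pipeline can be validated end to end without raw image
data.

## Attenuation model

Detected n-photon signal excited at surface power $P(z)$ and focused to
depth $z$ follows

$$S(z) \propto P(z)^{\,n}\, e^{-n z / \ell},$$

with $n = 3$ for THG and $\ell$ the effective extinction length
(combined scattering and absorption of the excitation light). The fit is
ordinary least squares of $\ln\!\left(S / P^n\right)$ on $z$, and
$\ell = -n/\text{slope}$. Choices worth knowing:

* **Per-slice summary.** How a 2D slice becomes one signal number is not
  standardized; the default is the mean of the top 1% brightest in-mask
  voxels, which is robust for the mostly dark field of view typical of
  THG. Plain mean and median are selectable and the choice is recorded
  in the profile and the fit object.
* **Non-positive slices** (after optional constant background
  subtraction) are dropped, not clamped, and their count is reported;
  log of a clamped zero would otherwise dominate the fit.
* **Non-decaying profiles** (slope $\ge 0$) return a fit flagged
  non-physical with $\ell = \infty$, never a negative length.
* **Depth window.** Published depth profiles often contain a bright
  surface-interface peak; no window is excluded by default, but
  `z_window` restricts the fitted range explicitly.
* **Depth axis.** $z = 0$ is the first acquired slice (the organoid
  surface against the coverslip); depth is slice index times the z step.

Invariance properties (tested): multiplying all signal by a constant
changes only the intercept; multiplying all powers by a constant leaves
$\ell$ unchanged.

## Morphometry

Per VZ region: volume $V$ = voxel count × voxel volume (exact);
surface area $A$ = area of the triangulated isosurface of the binary
region at level 0.5; thickness = $V/A$. For a sphere $V/A = r/3$, which
is what makes the ratio a useful relative wall-thickness measure.

* **Isosurface by marching tetrahedra.** Each cell of eight voxel
  centres is split into six tetrahedra around its main diagonal; the
  crossing surface in each tetrahedron is a triangle or quad. This is
  table-free and handles anisotropic voxels exactly (all geometry in
  micrometres). On raw binary data any midpoint isosurface
  overestimates curved surfaces (stair-step facets), so the mask is
  first smoothed with a Gaussian of one minimal-voxel-edge sigma and the
  0.5 level set of the smoothed field is measured; on a digital ball of
  radius 20 µm at 1 µm voxels this lands within ~0.5% of $4\pi r^2$
  (raw: +27%; plain voxel-face counting: +50% worst case). Face
  counting survives only as a test oracle with a 2/3 smooth-surface
  correction.
* **Shells have two surfaces.** The isosurface of a shell mask includes
  the cavity-facing surface, intentionally: $A$ of an ideal shell is
  $4\pi(r_{out}^2 + r_{in}^2)$.
* **Organoid thickness convention.** Published organoid-level
  "thickness" does not state whether regions are averaged before or
  after the ratio; the printed totals of a representative dataset are
  inconsistent with the pooled ratio, so the per-region mean of $V/A$
  is the headline value and the pooled total-$V$/total-$A$ is always
  co-reported.
* **Semi-automatic segmentation** (the manual workflow imports drawn
  masks instead): Gaussian smoothing → Otsu threshold separating
  background/cavity from tissue → second Otsu within tissue separating
  the low-THG VZ band from CP → removal of the band adjacent to the
  exterior background (the smoothed CP-to-background transition at the
  organoid surface otherwise mimics VZ) → 3D closing → 6-connected
  labeling → minimum-size filter (default $10^4$ µm³, a ~13 µm cube,
  suppressing speckle). Thresholds are volume-global by default: a
  per-slice variant exists (`per_slice = TRUE`, clamped to 0.5–1.5× the
  global estimate) and helps under residual depth attenuation, but on
  slices dominated by one tissue class per-slice Otsu splits that class
  arbitrarily, so it is off by default. On noiseless phantoms the
  default recovers regions at voxelwise Jaccard ≈ 0.87.
* The minimum region size counted as a "ventricle" is a free parameter
  (`min_volume_um3`), logged with every run.

## Tracking

Somata are detected per frame by multiscale Laplacian-of-Gaussian blob
detection: scale-normalized $-\sigma^2 \nabla^2 (G_\sigma * I)$ with the
Laplacian computed in physical micrometres (anisotropy-correct), local
maxima over the 26-neighborhood of the across-scale maximum response,
thresholded **relative to the frame's maximum response** so global
intensity scaling does not change detections, then refined to subvoxel
centroids by intensity weighting.

Frame-to-frame linking is a globally optimal one-to-one assignment
minimizing summed squared displacement (Hungarian algorithm), gated at
`max_step` (default 20 µm per 20-min frame, i.e. 60 µm/hr — more than
twice the fastest mean speeds seen in these experiments); unmatched
spots open or close tracks, and a track end may be joined to a later
track start across up to `max_gap_frames` skipped frames. Tracks
shorter than 4 observed frames are excluded from group statistics by
default (short fragments bias straightness upward); the count of
discarded fragments is reported.

Per-track metrics follow the field's conventions: displacement is the
straight start-to-end distance; path length the sum of step lengths;
straightness their ratio (undefined for a stationary track — reported
missing, not 0 or 1); **mean speed is path length over duration**, the
track-speed convention of common tracking software and the only
definition consistent with tortuous cells being slow in displacement
but not in motion; instantaneous speed is per-step distance over the
frame interval, assigned to the step's end.

## Colocalization

"Percentage of overlap" is mask-based (Manders-style count overlap),
not intensity correlation: each channel is thresholded (Otsu by
default — the automatic threshold of the commercial tool this mirrors
is undocumented — with fixed and percentile alternatives, all recorded
in the result) and $100\,|A\wedge B|/|A|$ is reported in both
directions. The per-cell variant asks, for each cell centroid of
channel A, whether the mean channel-B intensity within a soma radius
(default 5 µm) exceeds the B threshold; whether a published overlap
percentage is voxelwise or cellwise is often ambiguous, so both are
available and can be reported together.

## Group statistics

Cohorts in this literature are small (6–10 organoids) and two error-bar
conventions coexist, sometimes in the same study: SEM and 90%
confidence half-width ($t_{0.95,\,n-1} \times$ SEM — t quantiles, not
normal, given the small n). `summary_from_errorbar()` makes the reading
explicit, and group tests can be computed directly from published
(mean, error, n) triples. The default two-sample test is the classical
pooled-variance Student t (typical of the era's graphing software),
with Welch always co-reported; p is two-sided. Per-cell tests (n ≈ 200
cells from 6 organoids) are reproduced as published, without an
organoid-level clustering correction — deliberately, since the goal is
to reproduce the published analysis, not to repair it.

## The phantom generator: what it emulates, and what it does not

The generator states a world with the features the analysis relies on:

* **Geometry.** A spherical organoid of CP-like tissue (default radius
  150 µm) containing `n_ventricles` cavities (radius 20–35 µm) each
  wrapped in a VZ shell (default 20 µm thick, matching wild-type-like
  wall thickness), with at least `min_separation_um` (10 µm) of CP
  between shells and between any shell and the organoid surface:
  distinct ventricles are the stated world; shells closer than the
  smoothing scale are not resolvable by any thresholding segmentation.
  Intensities order cavity < VZ < CP < soma (defaults 2, 30, 60, 400)
  per the observed contrast; bright somata are Poisson-placed in CP at
  `cp_soma_density` (default $10^4$/mm³). Fixing `ventricle_centers`
  makes geometry deterministic so seeds vary only soma placement.
* **Optics.** Depth attenuation $(P(z)/P(0))^n e^{-nz/\ell}$ with
  $n = 3$, then optional Poisson shot noise on expected photon counts
  and Gaussian read noise. The formula is the standard effective-
  attenuation convention that the fitting stage inverts; $n$ is a
  parameter so two-photon phantoms use the same code.
* **Motion.** A persistent random walk: step directions drawn von
  Mises–Fisher around the previous direction with concentration
  $\kappa$, blended with the outward radial unit vector by weight
  `radial_bias`; step length $\max(0, \mathcal N(\bar v \Delta t,
  \sigma_v \Delta t))$ with $\Delta t = 20$ min, the volumetric
  acquisition interval used in practice. The observable literature
  reports straightness, not $\kappa$, so `calibrate_straightness()` /
  `kappa_for_straightness()` map one to the other by simulation; at
  $\kappa \to \infty$, `radial_bias = 1` the model degenerates to
  straight radial lines (straightness exactly 1). Cells leaving the
  rendered volume are truncated and flagged, never dropped silently.
* In end-to-end experiments the surface power log rises as
  $e^{z/\ell}$, holding delivered excitation constant with depth —
  mirroring the experimental practice of increasing power with depth
  and keeping the detector operating point uniform across the volume.

What it does **not** emulate: real THG speckle and membrane texture,
phase-matching physics of the $\chi^{(3)}$ response, GFP expression
kinetics, mitosis or track splitting, drift, or anisotropic PSF blur. A
green end-to-end test therefore establishes that the *pipeline* is
correct and unbiased under the stated noise and density regime — not
that it would segment any real organoid without parameter adjustment.

## Numerical and scale-down choices

* End-to-end cohort validation uses 9 rendered fields of 25 cells
  (≥ 200 tracks per genotype after filtering) at (5, 4, 4) µm voxels in
  ~390 µm fields, 19 frames — coarser rasters than a real 512×512
  acquisition but the same physical cell density and step lengths; this
  keeps the full loop within a CI budget (~10 min, one CPU).
* Extinction recovery is validated over $\ell \in \{100, 150, 200\}$ µm
  with shot noise at 100 expected photons/voxel in the brightest slice;
  noiseless recovery is exact to rounding, noisy median relative error
  is well under the 10% criterion.
* The Monte-Carlo oracle for t-test p-values uses $2\times10^5$ draws
  from the exact t distribution (agreement required within 3 Monte-
  Carlo SDs), a size chosen to keep the suite fast; the comparison is
  insensitive to this choice because the draws are from the exact null.
* All randomness flows through explicit integer seeds (`with_seed()`
  restores the caller's RNG state); identical seeds reproduce volumes,
  tracks and reports bit-for-bit.
* TIFF I/O is a self-contained baseline codec (uncompressed grayscale
  strips, 8/16-bit unsigned and 32-bit float, both byte orders read,
  ImageJ-style voxel metadata) because the target R environment has no
  TIFF bindings; it is validated against an external reference reader
  in the test suite. Missing voxel-size metadata is an error unless an
  override is given — never a silent 1 µm assumption.

## Known limitations

* The semi-automatic segmentation assumes the VZ band is darker than CP
  after smoothing; inverted or low-contrast stains need the manual
  import path.
* Linking has no motion model (no Kalman prediction) and no splitting;
  at densities far above ~40 cells per 320 µm field the ambiguity
  fraction it reports should be inspected.
* The straightness calibration is specific to the track length and
  frame interval used; curves must be recalibrated when either changes.
* Surface areas of regions only a few voxels thick are dominated by
  discretization; the monotonicity of $V/A$ in true thickness is
  preserved, but absolute values below ~3 voxels of thickness should
  not be over-interpreted.
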