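---
title: "Simulating the precision of quantitative PET phantom metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the precision of quantitative PET phantom metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Longitudinal PET studies interpret a change in a lesion's standardized
uptake value (SUV) as a biological change. That interpretation is only as
good as the *precision* of the metric: how much SUVmax, SUVpeak or SUVmean
would vary if the same object were scanned again, possibly lying a little
differently in the scanner. `petprecision` rebuilds that test–retest
experiment in silico. Digital analogs of the NEMA NU-2 image-quality (IQ)
phantom and of a gray/white brain phantom are imaged repeatedly — in a
fixed position or randomly repositioned within clinically realistic bounds
— at matched count statistics, quantified exactly as a harmonization
analysis would, and the precision of the two series is compared with
variance F-tests, sphere by sphere, metric by metric, reconstruction by
reconstruction.

Because everything is simulated, the "true" activity concentrations are
known exactly, every repositioning transform is known exactly, and each
mechanism (voxel sampling, resolution, noise) can be switched on and off
independently — which is precisely what a physical phantom experiment
cannot do.

## Phantom scenes

Scenes are continuous-domain objects: ordered lists of geometric
primitives (spheres, ellipsoids, boxes, elliptical cylinders), each with a
true activity concentration in kBq/mL, composited in painter's order so
that nested compartments are expressed naturally.

* `build_iq_scene(sphere, background)` — six spheres of inner diameters
  10, 13, 17, 22, 28 and 37 mm, coplanar on the standard 57.2 mm ring,
  inside a 9400 mL background vessel modelled as an elliptical cylinder.
  The cylinder is a deliberate simplification of the body-profile vessel:
  only the background level and texture near the spheres enter the
  analysis, not the vessel silhouette. Filling at 20 and 2 kBq/mL gives
  the nominal 10:1 contrast of EANM/EARL-style fills (measured fills in
  practice range roughly 1.75–3.08 kBq/mL background against
  17.78–28.63 kBq/mL spheres; both concentrations are free parameters).
* `build_brain_scene(solution, ratio)` — a procedural stand-in for a
  gray/white brain phantom: an ellipsoidal cortical shell (7 mm ribbon)
  around interior white matter, plus caudate- and putamen-like deep gray
  nuclei, gray at the fill-solution concentration and white at
  `solution / ratio`. The gray:white ratio defaults to 4:1, the nominal
  design contrast of such phantoms; it is exposed as a parameter because
  measured contrasts vary. The function also returns a VOI template: ten
  gray and ten white regions (five per hemisphere per tissue) spanning
  large cortical patches down to ~200-voxel deep structures, disjoint
  within each tissue and guaranteed to lie inside their tissue's labels.

`voxelize_scene()` rasterizes a scene with fractional voxel coverage:
voxels provably interior or exterior to a compartment (conservative
bounds, exact for spheres) are filled analytically, and only
boundary-straddling voxels are sampled at `supersampling^3` subvoxel
points (default 4 per axis, i.e. 64 samples). This realizes the tissue
fraction effect — boundary voxels holding a mixture of compartments — with
a volume error bounded in practice well below `1/supersampling` relative.

Coordinates are world millimetres; voxel `(i, j, k)` (1-based) has its
centre at `origin + (index − 0.5) * voxel_size`, with half-open voxel
extents. Scenes serialize to JSON; images read and write NIfTI-1 with the
voxel sizes in the header (`RNifti`).

## Image formation

`simulate_replicate()` composes the acquisition chain, in this order:

1. **Rigid repositioning.** `sample_transform(max_rot, max_disp)` draws
   per-axis rotations uniform on ±`max_rot` (default 5°) and a translation
   uniform in the ball of radius `max_disp` (default 20 mm), the bounds of
   a deliberately sloppy clinical repositioning. The transform is applied
   to the *scene* (centres and orientations move; concentrations do not),
   so repositioning never interpolates an image. The rotation bound is
   interpreted per axis; it is a parameter, so a total-rotation convention
   is one line away.
2. **Voxelization on a fine internal grid.** Each reconstruction profile
   refines its output grid by an integer factor chosen so the internal
   grid sits near 1 mm (e.g. 4 for 4 mm voxels). Blurring on the fine grid
   and block-averaging down *afterwards* separates the resolution of the
   imaging system from the sampling of the output grid — the two effects
   whose interaction the repositioning analysis probes. Block averaging of
   concentrations conserves total activity exactly.
3. **Resolution blur.** Isotropic Gaussian of configurable FWHM
   (σ = FWHM/2.3548), separable, truncated at 4σ and renormalized, with
   replicate (nearest-edge) padding. Replicate padding keeps uniform
   surroundings exactly uniform, which is what makes windowed simulation
   (below) unbiased. The centre value of a blurred sphere has a closed
   form, used throughout the tests as an independent oracle.
4. **Resolution modelling ("PSF") emulation.** Two styles, mirroring how
   vendors differ: a post-reconstruction style — Richardson–Lucy
   deconvolution (default 10 iterations, kernel equal to the blur FWHM),
   non-negative by construction and renormalized to the input total — and
   an in-reconstruction style emulated as a sharper direct blur (5 mm).
   Richardson–Lucy overshoot at sharp edges is the analog of the
   Gibbs-type artifacts resolution modelling is known for, and is left in
   deliberately. The FWHMs are emulation parameters, not vendor
   measurements; profiles are labelled analogs ("TOF", "TOF+PSF"), and the
   four body-mode voxel-size settings (4×4×4, 2×2×2, 3.1819×3.1819×2,
   2.0364×2.0364×2 mm³) are provided by `iq_recon_profiles()`.
5. **Count-statistics noise.** A voxel-level Poisson surrogate: expected
   voxel counts are `concentration × voxel volume (mL) × frame duration
   (min) × counts_per_mL_per_min × decay factor at the frame midpoint`;
   sampled counts are rescaled back to concentration units. The default
   scale, 600 counts per kBq-minute (~1% counting sensitivity), puts
   background coefficients of variation at a moderate few percent for
   5-minute frames and 4 mm voxels. Relative noise falls as the square
   root of collected counts, which is the only property the precision
   analysis needs from the noise model. `quantile_coupled = TRUE` draws
   counts by quantile inversion so that runs with equal seeds but
   different count scales are comonotone — common random numbers, the
   standard coupling for paired comparisons across noise levels; marginal
   distributions are unchanged.

`equal_counts_schedule(first, n, half_life)` builds the decay-compensated
framing: contiguous frames whose integrals of `exp(−λt)` are exactly
equal, so every frame collects the same expected counts
(λ = ln 2 / 109.77 min for ¹⁸F; a 5-minute first frame is followed by a
5.163-minute second frame, and `half_life = Inf` collapses to equal
durations). Stationary series are successive frames of one acquisition;
repositioned series are independent acquisitions at first-frame
statistics. For long synthetic series where an n-frame schedule would
outrun the decay budget, every stationary replicate uses first-frame
statistics, which the equal-count construction makes exchangeable.

Seeds: one master seed; per-replicate, per-frame seeds derive from it by
a documented splitting hash (`derive_seed`), keeping whole experiments
bit-reproducible.

## Quantification

* `suv_max()` — maximum voxel in a search region, ties broken at the
  lowest linear index.
* `suv_peak()` — highest kernel-weighted average over an exhaustive
  search of voxel-centre candidate positions. The kernel
  (`make_peak_kernel()`) is a 1 mL sphere (radius 6.2035 mm) with
  *fractional* voxel weights from subvoxel counting, so its represented
  volume is 1 mL to well within 0.5% on every grid used, including 4 mm
  voxels. Candidate centres are restricted to voxel centres — standard
  practice and bounded compute; a continuum search would differ at the
  sub-voxel level.
* `segment_a50()` — background-corrected 50% isocontour: threshold
  `T = B + 0.5 (SUVmax_local − B)`, where the local maximum is found near
  a supplied seed point, then the 26-connected component of voxels ≥ T
  containing that maximum. The background estimate `B` is the image mean
  over a region of the phantom background with a clearance around every
  sphere (`background_region_mask()`); for real NIfTI input the caller
  supplies `B` or a background mask. A local (not global) maximum is
  used, so neighbouring spheres cannot capture the threshold.
* `recovery_coefficient()` — observed over true concentration.
* `measure_iq_replicate()` — all six spheres of a replicate: segmentation
  seeded at the *transform-propagated* true centre (simulation provenance
  replaces image registration, matching analyses performed on original,
  unregistered images), then SUVmax/peak/mean in a generous search region
  and their RCs. Failures yield flagged rows, never silent drops.
* `region_means()` — brain template VOIs realigned rigidly onto the
  image (template voxel centres transformed, image sampled
  nearest-neighbour), per-VOI means and `RC_mean = mean / solution`.
  Passing the ground-truth transform emulates perfect realignment; a
  perturbed transform emulates registration error.

## Precision statistics

`replicate_summary()` gives mean, sample SD (n−1), CV, median and range —
the box-plot convention (box = SD, whiskers = range, line = median).
`variance_f_test(a, b)` is the two-sample variance F-test,
`F = s²_a/s²_b` on `(n_a−1, n_b−1)` degrees of freedom with a *two-sided*
p-value (the comparison is symmetric "difference in precision"; sidedness
is not dictated by the design, and two-sided is the conservative choice).
No multiple-comparison correction is applied by default, matching how
such tables are conventionally reported; a Holm column is available.
Degenerate cases follow stated conventions (both series constant → p = 1;
one constant → p = 0, flagged). Normality of RC replicates across
repositionings is assumed, as it implicitly is whenever an F-test is used
on such data; this is a documented limitation, and the test's null
calibration is itself verified by simulation in the test suite.
`precision_table()` arranges p-values as one row per target and one
column per reconstruction × metric, printing non-significant cells as
"–". `variance_inflation()` is the headline effect size:
`s²_repositioned / s²_stationary`.

## Study sizes, windowed simulation, and what the tests show

The full configured experiment (`run_experiment()`) simulates complete
phantom volumes. For replicate *studies* of a single sphere the package
uses windowed simulation (`simulate_sphere_series()`): each replicate is
reconstructed on a sub-grid of the profile's own lattice around the known
transformed sphere centre. The window corner snaps to the global lattice,
so the sphere's sub-voxel position relative to the voxel grid — the
carrier of the tissue fraction effect — is exactly what it would be in the
full volume, while computation stays local; replicate padding over the
uniform background makes the crop unbiased. The shipped studies use
windows of the sphere radius plus ~21 mm, replicate counts of 12 (the
physical experiment's size) up to 100 for precision-of-precision checks,
and 20 meta-repetitions when a claim is about how often an effect
appears.

What the synthetic generator emulates: true fill concentrations,
phantom geometry, repositioning bounds, resolution and voxel-size
interactions, and count-statistics scaling with frame duration. What it
does not: attenuation, scatter and randoms, sinogram-domain and
time-of-flight reconstruction physics, and — most consequentially —
the *spatial correlation* of reconstruction noise. Noise here is white
across voxels. VOI averages of white noise are smoother relative to
single voxels than VOI averages of real, resolution-correlated PET noise,
so comparisons that *ratio* a repositioning variance against a
noise-floor variance systematically flatter VOI-average metrics. Absolute
repositioning-induced spreads are unaffected by this caveat, and their
ordering (SUVpeak most stable, SUVmax least) is asserted in the test
suite. Passing tests therefore validate mechanisms and their directions,
not scanner-specific magnitudes.

## Numerical choices

* Blur kernels truncated at 4σ, renormalized; axes with σ below 0.05
  voxel are skipped (identity at that scale).
* Richardson–Lucy ratios guarded by a 10⁻¹² relative floor; output
  renormalized to the non-negative input total.
* Voxel classification margins use the voxel half-diagonal (exact for
  spheres, conservative for ellipsoids/cylinders/boxes), so supersampling
  is only ever spent on genuinely ambiguous voxels.
* Ties in `suv_max` break at the lowest linear index; segmentation uses
  ≥-threshold inclusion and 26-connectivity.
* `segment_a50` on an object whose local maximum does not exceed the
  background errors out rather than returning an empty mask.
* Seeds derived by a modular linear hash stay below 2³¹.

## Known limitations

Beyond the noise-texture caveat above: the peak search does not consider
sub-voxel centre offsets; the background estimator is simulation-aware
(real-data use must supply a background region); the brain scene is a
geometric stand-in, not an anatomical phantom, so regional values should
be read as tissue-class behaviour rather than structure-specific truth;
and the A50 mean over a 50% isocontour is intrinsically biased low by the
partial-coverage voxels the contour admits — in the no-blur, no-noise
limit the mask mean recovers only ~90–97% of the fill value depending on
sphere size, which is a property of the estimator itself, not of the
implementation.
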