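# petprecision

Test–retest precision of quantitative PET metrics, rebuilt as an
in-silico experiment.

In longitudinal oncology and brain PET, a change in a lesion's
standardized uptake value is only interpretable if the metric's
*precision* is known: how much SUVmax, SUVpeak or SUVmean would vary on a
rescan, especially when the patient lies slightly differently in the
scanner. `petprecision` reproduces the phantom experiment that measures
this, entirely in software, for people who work on PET quantification and
harmonization (EARL-style recovery-coefficient analyses) and want a
controllable, ground-truth version of it:

* **Digital phantoms** — the NEMA NU-2 image-quality phantom (six spheres,
  10–37 mm, on the standard 57.2 mm ring in a 9400 mL background, ~10:1
  fill contrast) and a procedural gray/white brain phantom with a
  ten-gray/ten-white VOI template.
* **Replicated acquisitions** — rigid repositioning (rotations < 5° per
  axis, displacements ≤ 20 mm) or a fixed position; Gaussian resolution
  blur on a fine internal grid; Richardson–Lucy resolution-modelling
  emulation; the four body-mode voxel-size profiles; Poisson
  count-statistics noise under decay-compensated equal-count frame
  schedules (¹⁸F, frames of exactly equal expected counts).
* **Quantification** — SUVmax; SUVpeak as the highest average of a 1 mL
  spherical VOI with fractional voxel weights, searched exhaustively;
  SUVmean over a background-corrected 50% isocontour
  (threshold `T = B + 0.5·(SUVmax − B)`, 26-connected); recovery
  coefficients `RC = SUV / A_true`; brain template means after rigid
  template realignment. The same functions run on real PET volumes in
  NIfTI-1 format.
* **Precision statistics** — per-series SD/CV summaries, variance
  inflation `s²_repositioned / s²_stationary`, and two-sided variance
  F-tests (`F = s²_a/s²_b`, df `(n_a−1, n_b−1)`) arranged in
  sphere-by-reconstruction tables with non-significant cells printed
  as "–".

## Worked example

Twelve stationary versus twelve repositioned replicates of the 10 mm
sphere, 4 mm voxels, 7 mm resolution, 5-minute frames:

```r
library(petprecision)

profile <- iq_recon_profiles()[["TOF-4mm"]]
stationary   <- simulate_sphere_series(10, profile, "stationary",   n = 12, master_seed = 1)
repositioned <- simulate_sphere_series(10, profile, "repositioned", n = 12, master_seed = 1, stream = 100)

round(replicate_summary(stationary$rc_max)$sd, 4)
#> [1] 0.0087
round(replicate_summary(repositioned$rc_max)$sd, 4)
#> [1] 0.0284
variance_inflation(repositioned$rc_max, stationary$rc_max)
#> [1] 10.69688
variance_f_test(repositioned$rc_max, stationary$rc_max)
#> <ftest_result> F(11, 11) = 10.7, two-sided p = 0.0004593
```

Read: with the phantom fixed, RC_max of the 10 mm sphere fluctuates by
±0.009 (noise only); letting the phantom be repositioned within clinical
bounds triples that spread, a ~11-fold variance inflation that the F-test
flags decisively — the small-sphere repositioning effect at coarse voxels.
`run_experiment()` scales the same machinery to the full design (all
spheres, both conditions, several reconstructions and frame durations)
from a single YAML/JSON config, and `build_brain_scene()` +
`region_means()` do the regional brain analysis.

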