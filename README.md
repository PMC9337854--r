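# othg — quantitative analysis of label-free THG imaging of cerebral organoids

Third-harmonic generation (THG) microscopy images intact cerebral
organoids without any label: refractive-index interfaces (membranes,
organelles) emit at one third of the excitation wavelength, resolving
the dark nucleus-dense **ventricular zone (VZ)** around each
ventricle-like cavity, the brighter **cortical plate (CP)**, and bright
neuronal somata — deep into uncleared tissue. `othg` is an R toolkit
for the analyses such experiments need, for example when comparing
wild-type and disease-model (e.g. MECP2-mutant) organoid cohorts:

* **Attenuation** — depth-resolved signal profiles and effective
  extinction length ℓ from the semi-log fit
  `ln(S/P³) = a + slope·z`, ℓ = −3/slope (the photon order is a
  parameter, so 2-photon data fit too).
* **Morphometry** — 3D VZ segmentation (semi-automatic, or import of
  manually drawn masks), per-region volume `V`, triangulated-isosurface
  area `A`, thickness `V/A`, and ventricle counts per organoid.
* **Tracking** — Laplacian-of-Gaussian soma detection in 4D stacks,
  globally optimal frame-to-frame linking, and migration metrics:
  displacement, mean speed (path/duration), straightness
  (displacement/path).
* **Colocalization** — Manders-style voxel overlap percentages and
  per-cell "k of n cells carry channel-B signal" counts.
* **Group statistics** — SEM and 90% CI (t-quantile) summaries and
  two-sample t-tests (pooled + Welch), from raw values or from
  published (mean, error bar, n) triples.
* **Synthetic organoids** — a phantom generator with exact ground truth
  (geometry labels, attenuation length, cell tracks) emulating
  three-photon depth attenuation, shot/read noise, and persistent
  random-walk radial migration at a 20-minute volumetric interval, so
  the entire pipeline is validated closed-loop.

I/O covers multi-page/hyperstack TIFF with voxel metadata (built-in
baseline codec, no external imaging libraries needed), CSV power logs /
spots / tracks / metrics, YAML configurations, and stage-coordinate
mosaic assembly for serial multi-site acquisitions.

## Worked example

Simulate an organoid, image it through the attenuation model, and
recover what went in:

```r
library(othg)

spec   <- phantom_spec(organoid_radius = 110, n_ventricles = 3,
                       ventricle_radius_range = c(16, 24),
                       vz_shell_thickness = 16, voxel_size = c(2, 2, 2))
optics <- optics_spec(extinction_length = 150, surface_power_by_depth = 1.5)

ph  <- generate_phantom(spec, seed = 42)
att <- apply_attenuation(ph$image, optics)

# robust per-slice summary (mean of top 1% voxels), fitted inside the
# tissue (the dark margin above/below the organoid carries no signal)
prof <- extract_depth_profile(att, 1.5)
fit_extinction(prof, photon_order = 3, z_window = c(20, 200))
#> extinction fit (n=3): l = 146.9 um, slope = -0.02043 /um, R^2 = 0.956

seg <- segment_vz(ph$image)
measure_organoid(seg)
#> organoid: 3 ventricle(s), V = 4.919e+05 um^3, A = 7.767e+04 um^2,
#>   V/A = 6.33 um (per-region mean), 6.33 um (pooled)
```

The fitted extinction length recovers the 150 µm that generated the
stack to within 2% despite the anatomy-driven variation of the
per-slice signal; the segmentation finds the three ground-truth
ventricles (voxelwise Jaccard ≈ 0.87), and `V/A` is the wall-thickness
measure used to compare genotypes.

Testing published group summaries directly:

```r
wt <- summary_from_errorbar(152.1, 3.5, 6, "sem", "WT")  # extinction, um
mt <- summary_from_errorbar(125.9, 4.9, 6, "sem", "MT")
t_test_from_summary(wt, mt, "pooled")
#> two-sample t (pooled): t = 4.351, df = 10, p = 0.001441
```

Time-lapse tracking closed loop (calibrated motion → render → detect →
link → metrics) is wrapped in one call:

```r
wt <- migration_cohort_experiment(mean_speed = 23.4,
                                  target_straightness = 0.881,
                                  n_movies = 9, n_cells = 25, seed = 11)
str(wt$recovered)
#> $ mean_speed  : num 23.4
#> $ straightness: num 0.878
#> $ displacement: num 116
wt$link_accuracy
#> [1] 0.98
```

## Command line

```
othg simulate    --config cfg.yaml --out dir --seed 1 [--timelapse]
othg attenuation --stack s.tif --power p.csv --order 3 --out fit.json
othg morphometry --stack s.tif --auto --out metrics.csv
othg track       --stack movie.tif --dt 20 --max-step 20 --out tracks.csv
othg coloc       --a gfp.tif --b thg.tif --out coloc.json
othg stats       --summaries groups.csv --method both --out tests.csv
```

Every subcommand writes a JSON run manifest (config, seed, versions,
input hashes) beside its outputs.

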