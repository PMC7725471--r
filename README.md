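# vesiclehood

Quantitative morphometry of insulin secretory vesicles (dense-core
granules) in cryo-electron tomograms of pancreatic β cells, with a
synthetic tomogram generator so the whole measurement chain can be
validated against known ground truth.

Cryo-ET of cryo-FIB-milled lamellae images β-cell vesicles in a
near-native state, but the limited ±60° tilt range leaves a *missing
wedge* in Fourier space that erases the membrane at each vesicle's
poles, and the ~200 nm lamella physically cuts vesicles of comparable
size. Direct 3D integration of a segmented vesicle therefore
underestimates its volume. Both artifacts spare the equatorial cross
section, so the package measures each (near-spherical) vesicle from
the area *A* of its central cross section:

    d = 2 * sqrt(A / pi)        (diameter)
    V = pi * d^3 / 6            (volume)

Around this estimator it provides:

* `generator_config()` / `sample_vesicle_field()` / `render_field()` /
  `apply_missing_wedge()` / `add_noise()` — synthetic lamella-slab
  tomograms: non-overlapping vesicles with membranes, lumens, dense
  cores, granular metal clusters; wedge corruption; seeded noise.
* `segment_vesicles()` / `match_to_truth()` — threshold segmentation
  (smoothing, closing, per-slice + 3D hole filling, 26-connected
  components) standing in for manual annotation, plus IoU matching
  against ground truth.
* `measure_vesicles()` — per-vesicle cross-section area, diameter,
  volume, and slab-clipped volume, with boundary-truncation handling.
* `classify_vesicles()` / `core_contrast()` — mature/immature calls
  from a robust, matched-filtered interior-contrast statistic
  (presence of a dense core); `detect_clusters()` for 30–90 nm metal
  deposits.
* `assign_region()` / `summarize_region()` / `compare_regions()` —
  the three-region scheme (3–8 µm from the nuclear membrane, 3–6 µm
  and ≤2 µm from the plasma membrane), per-region mature fraction,
  diameter statistics, count density, volume fraction, and Welch +
  Mann–Whitney comparisons flagged at p < 1e-4.
* `run_pipeline()` — the whole chain over per-region presets, with one
  seed, a serialized manifest, and resumable summaries
  (`summarize_run()`). `inst/cli/vesiclehood` wraps the same functions
  as a command-line tool (`generate | segment | measure | classify |
  summarize | run`).
* `read_volume()` / `write_volume()` — MRC-2014 I/O (voxel size in the
  header, Å ↔ nm); `read_table()` / `write_table()` — fixed-schema CSV.

## Worked example

Generate a peripheral-region tomogram (scaled grid), corrupt it with
the missing wedge and noise, and run the measurement chain:

```r
library(vesiclehood)

preset <- load_region_preset("region3",
                             overrides = list(grid_shape = c(320, 320, 110)))
cfg <- preset$generator
cfg$seed <- 11L
tomo <- generate_tomogram(cfg)            # field + volume + truth labels

labs <- segment_vesicles(tomo$volume)
recs <- measure_vesicles(labs)
recs <- classify_vesicles(recs, tomo$volume, labs)
recs <- detect_clusters(recs, tomo$volume, labs)

match_to_truth(labs, tomo$labels)$recall
#> [1] 1
summarize_region(recs, slab_volume_um3(cfg), "region3")[,
  c("n_vesicles", "mature_fraction", "mean_diameter_nm",
    "count_density_per_um3", "volume_fraction")]
#>   n_vesicles mature_fraction mean_diameter_nm count_density_per_um3
#> 1          3       0.3333333         250.6098               33.2919
#>   volume_fraction
#> 1        0.279466
```

Three vesicles were planted in this 0.09 µm³ slab and all three
recovered (recall 1); exactly the one that carries a dense core is
called mature (fraction 1/3); the mean measured diameter (250.6 nm,
outer = lumen + two 7 nm membranes) sits where the region-3
calibration (lumen 266 ± 52 nm) puts it; 33 vesicles/µm³ and 28 %
occupied volume reflect the dense peripheral packing up to the
sampler's jamming limit. A full multi-region run is one call:

```r
res <- run_pipeline(run_config(seed = 1,
                               overrides = list(grid_shape = c(320, 320, 110))),
                    outdir = "run1")
res$summaries
res$comparisons[["region1 vs region3"]]
```

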