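# tomogold

Quantitative analysis of nanogold labeling in cryo-electron tomograms.

Monodisperse gold nanoparticles (1.4 nm or 5 nm) conjugated to a
HaloTag ligand are delivered into live cells, where they covalently label a
Halo-tagged protein — e.g. ribosomal protein L29 — and are then imaged in
situ by cryo-electron tomography.  Gold's high atomic number makes it far
denser than any biological material, which creates both an opportunity and
two problems this package addresses:

* **Detection.** Gold can be found directly in a whole tomogram by intensity
  thresholding: slab-average along z, normalize to [0, 1], keep voxels above
  `mean + 3.3·SD`, group them into connected components, drop single-voxel
  background, and gate components by voxel count around the theoretical
  sphere volume (53 voxels for a 7 Å sphere on a 3 Å grid) — anything much
  larger is gallium, ice or membrane.
* **Randomization.** In subtomogram averaging the gold dominates alignment.
  Hiding it — replacing every voxel above `μ + 3.3σ` with a draw within one
  SD of the mean, per particle — lets alignment recover the macromolecule.
* **Geometry and efficiency.** With particle orientations refined, the
  particle coordinate is re-centered on the tag site (`r̂_R`, e.g. the L29
  C terminus 12.9 nm from the ribosome center) via the ZYZ rotation of each
  particle, and the minimum Euclidean distance from each tag site to any
  gold center (`r̂_G`) is computed.  Sites within the maximum tether
  distance (10 nm: worm-like-chain reach of the disordered residues plus
  dextran and ligand) count as labeled, giving the labeling efficiency

  ```
  efficiency = N_labeled / (N_labeled + N_unlabeled)
  ```

* **Quantification.** Fluorescence-calibration regression (molecules from
  Avogadro arithmetic, OLS line, background-subtracted inversion to
  molecules/cell), subvolume→cell copy-number extrapolation, and gold
  size-distribution separability for multiplexing.

Because real in-situ validation data is enormous, the package ships a
synthetic tomogram generator with exact ground truth (particle centers and
orientations, tag sites, tethered and unbound gold, additive noise) used by
the test suite to validate every stage end to end.

## Worked example

Simulate a small labeled world, detect the gold, and estimate the labeling
efficiency (shrunk geometry so it runs in seconds; `labeled_fraction = 0.8`
is the ground truth the pipeline should recover):

```r
library(tomogold)

cfg <- simulation_config(
  dims = c(112, 112, 112), voxel_size = 3,          # 336 Å cube, 3 Å/voxel
  n_particles = 5, particle_radius = 25, particle_amplitude = 1,
  tag_offset = c(0, 0, 30),                         # tag site on the surface
  labeled_fraction = 0.8,                           # 4 of 5 carry gold
  tether_mean = 20, tether_sd = 5, tether_max = 40, # tag-to-gold, Å
  gold_radius = 7, gold_coat_thickness = 5, gold_amplitude = 10,
  n_unbound_gold = 1, noise_sd = 0.5, min_separation = 60, seed = 5)

sim <- simulate_tomogram(cfg)
sim$volume
#> <volume_grid> 112 x 112 x 112 voxels @ 3 Å/voxel, density_bright
#>   intensity range [-2.40726, 11.4684], origin (0, 0, 0) Å

det <- detect_gold(sim$volume, detection_params(
  slab_width = 3, min_voxels = 27, max_voxels = 159))
as.data.frame(det)
#>   component_id      x     y     z voxel_count peak_intensity
#> 1            1  78.98 114.3 125.1          87         0.9804
#> 2            2 238.25 127.1 132.5          96         1.0000
#> 3            3 118.29 222.0 140.0          85         0.9946
#> 4            4 165.65 153.4 203.6          85         0.9790
#> 5            5  87.00 195.7 211.5          90         0.9830

sites <- recenter_to_tag_site(sim$truth$particles, c(0, 0, 30))
res <- efficiency_pipeline(sites, det, cutoff_nm = 4)
res$efficiency
#> labeling efficiency 4/5 = 0.800
res$summary
#> min-distance distribution: mean 2.23 nm, sd 0.57 nm, n = 4
res$unbound_gold_fraction
#> [1] 0.2
```

All five golds (four tethered, one free) are detected; the efficiency
estimate recovers the simulated 0.8 exactly and the free gold shows up as a
20 % unbound fraction.  The desk-scale statistics reproduce the field's
reference numbers: `labeling_efficiency(9567, 4181)` gives 0.69588… (printed
as 0.695), `theoretical_voxel_count(7, 3)` gives 53, and
`pixel_span(14, 1.068)` gives 13.

## Command line

A CLI covering all stages is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tomogold.R", package = "tomogold"))')
Rscript $CLI simulate  --config cfg.json --seed 5 \
                       --out-volume vol.mrc --out-truth truth.csv
Rscript $CLI detect    --volume vol.mrc --contrast density_bright \
                       --params det.json --out detections.csv
Rscript $CLI randomize --stack-dir boxes/ --out-dir randomized/ --k-sd 3.3
Rscript $CLI distances --sites sites.csv --golds detections.csv \
                       --cutoff-nm 10 --out summary.json
Rscript $CLI quantify  extrapolate --count 50000 --subvolume 10.1 \
                       --cell-volume 5282.5
```

Config files are JSON mirrors of `simulation_config()` /
`detection_params()`.  `detect` inverts conventional dark-density input
explicitly; pass `--contrast density_bright` for already-inverted volumes.

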