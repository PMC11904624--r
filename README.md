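# fibrosynth

Adaptive exemplar-based synthesis and pore-network analysis of fibrous
porous microstructures in R.

Soft fibrous tissues such as the knee meniscus owe their mechanical and
hydraulic behaviour to a highly organized collagen-fibre microstructure,
but real micro-CT samples of such tissue are scarce: acquisition is
destructive, donors are few, and regression studies of structure–property
relationships need hundreds of geometries. `fibrosynth` addresses that gap
for image analysts and tissue biomechanics researchers by generating new,
statistically matched (or deliberately biased) 3D realizations from a
single binary exemplar volume, and by measuring the morphology and Darcy
permeability of any binary volume with a pore-network model.

## The method in brief

1. **Double distance map.** A binary volume `I0` (solid = 1) becomes the
   grayscale field `I = d̂(I0) − d̂(1 − I0) + 1` on a 0–2 scale, where `d̂`
   is a max-normalized Euclidean distance transform; the solid–pore
   interface sits at `I = 1`. This makes the microstructure
   interpolatable, so patches can be rotated, averaged and blended.
2. **Diversified patch dataset.** Seven transformations (±8° rotations
   about each axis paired with grayscale opening / closing / erosion /
   dilation, sphere of diameter 3), plus per-volume random intensity
   shifts (±0.1) and scales (±10%), yield `7N` cubic patches. Each patch
   is scored by porosity, specific surface area and maximum pore size,
   min–max normalized into the unit feature cube `(α, β, γ)`.
3. **Adaptive filtering.** The eighth of the dataset closest to a feature
   target is retained: `(0.5, 0.5, 0.5)` gives unbiased realizations;
   `α = 0` gives the least porous realization the dataset supports, and
   so on.
4. **Quilting reconstruction.** Patches are placed on a randomized grid
   with overlap margin `m` (default 6 voxels); each placement picks the
   candidate minimizing the mean absolute mismatch on already-placed
   voxels (exhaustive scan), then blends it in with distance-based weights
   confined to the overlap band. Gaussian smoothing (σ = 0.5) and
   thresholding at 1 return a binary volume.
5. **Pore-network analysis.** Marker-based watershed of the pore-phase
   distance map (h-maxima markers) gives pores and throats;
   Hagen–Poiseuille network flow with virtual face reservoirs gives
   directional permeability in Darcy,
   `K = Q μ L / (A ΔP)`.
6. **Closed-form correlations.** Built-in porosity correlations for
   meniscal tissue: `KL = exp(4.719·ln φ + φ + 5.097)`,
   `KT = exp(5.567·ln φ + φ + 4.239)` (Darcy) and the normalized modulus
   `En = 1 − 1.1456 φ² + 0.0853 φ`, plus CT-number → porosity → property
   maps for whole-section images.

A built-in phantom generator (jittered, finite cylindrical fibre segments,
porosity set by bisection) stands in for micro-CT exemplars, so the entire
pipeline is testable without data.

## Worked example

```r
library(fibrosynth)

exemplar <- generate_fibrous_volume(phantom_spec(shape = c(64, 64, 64),
                                                 target_porosity = 0.61,
                                                 seed = 1))
exemplar
#> <binary_volume> 64 x 64 x 64 voxels @ 6.25 um, porosity 0.610

map     <- double_distance_map(exemplar)
dataset <- sample_patches(map, n_per_transform = 60, patch_shape = 16, seed = 2)
dataset
#> <patch_dataset> 420 patches of 16x16x16 voxels @ 6.25 um

cfg   <- reconstruction_config(c(64, 64, 64), patch_shape = 16, margin = 4,
                               seed = 7, feature_target = c(0.5, 0.5, 0.5))
recon <- reconstruct_volume(dataset, cfg)
recon
#> <fibro_recon> 64 x 64 x 64 voxels, porosity 0.664, 343 placements, 100% matched below 0.2

dplyr::bind_rows(exemplar       = morphology_summary(exemplar),
                 reconstruction = morphology_summary(recon$volume),
                 .id = "volume")
#>           volume porosity specific_surface_mm mean_pore_radius_um
#> 1       exemplar    0.610                54.7                34.8
#> 2 reconstruction    0.664                53.3                36.4
#>   mean_throat_radius_um mean_connectivity  K_x  K_y  K_z K_mean
#> 1                  12.6              5.26 2.25 1.92 10.9   5.03
#> 2                  12.9              4.19 1.72 2.43 12.6   5.58
```

The panel reads as follows: the unbiased reconstruction reproduces the
exemplar's porosity (0.66 vs 0.61 at this small demonstration size — the
agreement tightens with more patches and seed averaging), surface area
(53 vs 55 /mm), pore and throat radii (µm), mean coordination number, and
directional permeabilities in Darcy, with the longitudinal (`K_z`)
direction conducting several times better than the transverse ones, as in
aligned fibrous tissue. The fraction of placements with matching error
below 0.2 (here 100%) is the standard quilting quality diagnostic.

Porosity-only characterization via the built-in correlations:

```r
predict_KL(0.61)   # 29.20721  Darcy, longitudinal
predict_KT(0.61)   # 8.143763  Darcy, transverse
predict_En(0.61)   # 0.6257552 normalized Young's modulus
```

`tidy()` / `glance()` methods expose pore and throat tables and one-row
summaries; `autoplot()` methods show volume slices, maps and the patch
feature cube. `run_pipeline()` chains all stages and writes a hashed
artifact manifest; `inst/cli/fibrosynth` wraps the same functions as a
command-line tool (`phantom`, `ddmap`, `dataset`, `reconstruct`,
`analyze`, `predict`, `ctmap`, `pipeline` subcommands).

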