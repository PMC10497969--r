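# chondrosim

Image-based electro-quasistatic modelling of cartilage-like tissue.

Fine-grained numerical models of the interaction between electric fields
and cartilage need tissue-specific geometry: where the chondrocytes are,
how big they are, and how their insulating membranes polarise. `chondrosim`
is an R package that runs this pipeline end to end at desk scale, for
researchers working on bioimpedance sensing and electrical stimulation of
cartilage:

1. **Synthetic tissue** — seeded generation of ellipsoidal chondrocyte
   populations (volumes 2157 ± 957 µm³ by default) rendered into noisy
   confocal-style 16-bit TIFF stacks with exact ground-truth labels.
2. **Segmentation** — the classical chain: isotropic resampling,
   denoise/flatten/stretch, automatic (Otsu) thresholding, physical-unit
   artifact filters (slice area > 300 µm² removed, volume < 200 µm³
   removed), distance-transform watershed, and moment-based 3D ellipsoid
   fitting.
3. **Evaluation** — IoU-thresholded instance matching by optimal
   assignment, with `accuracy = TP/(TP+FN+FP)`, precision, recall, F1.
4. **Geometry** — pairwise intersection graphs with cycle detection and
   void filling, watertight iso-surface meshes, Taubin smoothing, quadric
   edge-collapse decimation, STL export, and voxelisation into a two-phase
   (buffer/cytoplasm) material grid with explicit membrane faces.
5. **Solver** — the electro-quasistatic equation
   `div((sigma + j omega eps) grad phi) = 0` on a voxel admittance network
   with a 7 nm thin-layer membrane (sigma_m = 8.7e-6 S/m, eps_rm = 5.8;
   cytoplasm 0.48 S/m / 60; buffer 1 S/m / 80), COCG iteration, impedance
   spectra over 1 kHz–1 THz (10 points/decade), and transmembrane
   potential maps.
6. **Dielectric** — effective `sigma_eff(omega)`, `eps_r_eff(omega)` from
   the parallel-plate cell constant, plus the analytic single-shell
   Maxwell–Wagner suspension model (the β-dispersion oracle).
7. **UQ** — polynomial-chaos expansion by point collocation (order 4:
   254 model runs for 5 parameters, 662 for 7), first-order Sobol indices,
   and 90% prediction intervals from 10⁴ surrogate samples.

## Worked example

Generate a clean synthetic stack, segment it back, and compute the
dielectric spectrum of the recovered geometry:

```r
library(chondrosim)

cells <- sample_population(5, box = c(64, 64, 64),
                           allow_touching = FALSE, min_gap = 2, seed = 11)
rs <- render_stack(cells, voxel_size = 0.8,
                   noise = noise_preset("clean", seed = 12),
                   box = c(64, 64, 64))

seg <- segment_stack(rs$stack)
m <- match_instances(seg$labels, rs$labels, tau = 0.5)
nrow(seg$cells)        # 5  -- all generated cells detected
accuracy(m)            # 1  -- every instance matched at IoU >= 0.5

population_summary(seg$cells, box = c(64, 64, 64))
# mean volume 1723 +/- 1055 um^3, volume ratio 3.29 %

geom <- voxelize_geometry(cells = seg$cells, box = rep(64, 3),
                          voxel_size = 1, electrode_axis = "x")
sp <- frequency_sweep(geom, material_props(),
                      frequencies = c(1e4, 1e6, 1e8))
extract_dielectric(sp)
#   frequency sigma_eff eps_r_eff
# 1     1e+04    0.9476    562.11
# 2     1e+06    0.9606    317.05
# 3     1e+08    0.9777     79.46
```

The numbers show the physics the package is built around: the cells lower
the bulk conductivity slightly below the 1 S/m buffer, the charged
membranes raise the low-frequency permittivity far above the buffer's 80,
and the β-dispersion step around 1 MHz collapses that excess at high
frequency, where the cells become electrically invisible.

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages with
file interchange (TIFF/CSV/JSON) and writes a run manifest with content
hashes; `inst/cli/chondrosim.R` exposes the same stages as shell
subcommands (`synth`, `segment`, `evaluate`, `mesh`, `voxelize`, `solve`,
`dielectric`, `uq`, `pipeline`).

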