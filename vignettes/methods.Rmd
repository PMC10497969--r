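---
title: "From cell images to tissue impedance: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cell images to tissue impedance: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrosim)
```

# Overview

`chondrosim` implements a complete desk-scale pipeline for estimating the
impedance and effective dielectric properties of cartilage-like tissue from
3D cell images: a synthetic confocal-stack generator with exact ground
truth, a classical instance-segmentation chain, geometry assembly (meshes
and voxel material grids), an electro-quasistatic solver with a thin-layer
membrane, dielectric extraction with an analytic single-shell oracle, and
polynomial-chaos uncertainty quantification. This vignette documents the
models, the tunable parameters, and the numerical decisions, in the order
the pipeline runs.

# The synthetic tissue generator

Chondrocytes in healthy articular cartilage are blob-shaped and well
approximated by ellipsoids. The generator draws cell volumes from a
truncated normal distribution with mean 2157 µm³ and standard deviation
957 µm³ — the population statistics of healthy bovine chondrocytes that
this simulator emulates — with semi-axis ratios $a:c$ uniform in $[1, 2]$
(the shape statistics are not published, so a mildly prolate blob family is
a declared choice, not an inference) and uniform Euler-angle orientations.
Rendering uses the default confocal voxel geometry of
$0.1099 \times 0.1099 \times 1$ µm (z, y, x order throughout; voxel centres
at $(i + 0.5)\,h$ with 0-based indices).

The intensity model is additive: constant background, bright cells with
per-cell intensity jitter (uniform $\pm 20\%$), a multiplicative linear
illumination gradient per axis, optional Poisson shot noise, additive
Gaussian read noise, and a Poisson-distributed number of small bright
artifacts (0.4–1.5 µm spheres, deliberately below the 200 µm³ volume
filter). What the generator does **not** emulate: the microscope's
point-spread function, z-attenuation, multi-channel dyes, pericellular
matrix, or partially stained cells. Segmentation results on these synthetic
stacks therefore demonstrate the correctness of the chain's geometry
recovery, not its robustness to every optical artifact of real confocal
data.

Ground-truth labels come from the analytic ellipsoid membership test at
voxel centres; overlapping cells are resolved to the cell whose normalised
ellipsoid coordinate is smallest (the "deepest" interior). Every stochastic
element is driven by an explicit seed through a private RNG stream, so a
`(parameters, seed)` pair reproduces a stack bit for bit.

# The segmentation chain

The chain mirrors the classical automated route: resample to isotropic
voxels → denoise/flatten/stretch → automatic global threshold → physical
artifact filters → distance-transform watershed → moment-based ellipsoid
fitting.

* **Resampling** interpolates every axis (linearly by default) to the
  smallest voxel dimension. Confocal stacks are ~9× coarser in z; adjacent
  cells separate much better on an isotropic grid.
* **Pre-processing**: Gaussian denoising (default $\sigma$ = 0.5 µm),
  background flattening by subtraction of a large-kernel Gaussian estimate
  (default $\sigma$ = 10 µm — large against a 16 µm cell, small against
  the field of view), then a percentile contrast stretch (1st–99.9th).
  Each stage can be toggled off.
* **Thresholding** defaults to Otsu's between-class-variance criterion on a
  256-bin histogram. When the histogram has an empty inter-mode gap any
  threshold inside the gap is an Otsu optimum; the package deterministically
  takes the lowest such bin. The resulting mask is the invariant.
* **Artifact filters** operate in physical units so they behave identically
  at any resolution: per-slice 2D components above 300 µm² are removed
  (gigantic imaging artifacts; a per-slice rule because parts of genuine
  cells can be small in individual slices), then 3D components below
  200 µm³ (tiny noise). 2D components use 8-connectivity, 3D components
  26-connectivity (both configurable).
* **Watershed**: holes are filled, the Euclidean distance transform is
  computed with physical spacing, internal maxima are extracted with
  h-maxima suppression (default dynamic $h$ = 2 µm of distance height —
  below half a typical cell radius, above the staircase ripple of the
  distance map), and the inverted distance map is flooded from those seeds
  within the mask. Ties in the flood order are broken by insertion order,
  making the result deterministic.
* **Ellipsoid fitting**: for each label, the centre is the voxel centroid
  and the axes come from the eigen-decomposition of the voxel covariance
  (including the $h^2/12$ within-voxel term). For a uniform solid
  ellipsoid the semi-axes are $\sqrt{5\lambda_i}$; a final isotropic
  rescaling enforces the exact identity (fitted volume) = (labelled voxel
  volume), so summed fitted volumes always equal summed voxel volumes.
  Labels with fewer than 4 voxels or coplanar support are skipped with a
  warning.

Instance matching for evaluation computes the IoU over all overlapping
pairs and selects the one-to-one assignment maximising total IoU
(maximum-weight bipartite matching), then applies the IoU threshold
$\tau$ (default 0.5). Optimal assignment removes any dependence on label
order; an exhaustive-search oracle verifies it in the tests. Zero-overlap
pairs are never matched, and `accuracy = TP/(TP+FP+FN)` is defined as 1
when both images are empty.

# Geometry assembly

**Intersection graph.** All $n(n-1)/2$ cell pairs are tested (a
bounding-sphere prefilter short-circuits distant pairs without changing the
logical count). The pair test samples 1000 deterministic Fibonacci-lattice
surface points per ellipsoid and checks containment in the other ellipsoid
with a 0.01 µm tolerance, plus a centre-containment check so fully nested
cells register.

**Void repair.** Cycles (from a fundamental cycle basis of each graph
component — sufficient to locate cavities without enumerating all simple
cycles) are voxelised locally; the pairwise common volumes are fused. Two
signals indicate a void: the fused region fragments into multiple pieces,
or the cell union encloses a background cavity (flood fill from the domain
boundary). An enclosed cavity is filled directly; for a fragmented fusion
without a closed cavity (the typical three-cell ring, whose central gap is
an open channel in 3D), the void is taken as the uncovered voxels within
the bounding sphere of the fused pieces. The filler sphere sits at the void
centroid with radius 1.1× the void bounding radius (the margin is exposed;
no published value exists). Cavities above half the union volume are
flagged for review instead of auto-filled.

**Surface meshes.** Iso-surfaces are extracted by marching the Freudenthal
(Kuhn) 6-tetrahedra decomposition of each grid cube. This
tessellation-consistent variant of marching cubes was chosen over the
classic 256-case table because it has no ambiguous configurations and is
watertight by construction; accuracy is equivalent (the fidelity tests
measure < 0.5% volume and area error on an ellipsoid at 0.25 µm voxels,
within the 1% bound the pipeline requires of its geometric input).
Binary labels are pre-smoothed with a 1-voxel Gaussian before extraction so
the surface interpolates sub-voxel positions instead of the raw staircase;
`smooth_sigma = 0` gives the raw voxel surface whose enclosed volume
matches the voxel count. Taubin smoothing (default $\lambda = 0.5$,
$\mu = -0.53$, 10 iterations — the classic pass-band pair; no published
values) relaxes staircase artifacts with far less shrinkage than plain
Laplacian smoothing, and quadric edge-collapse decimation reduces the face
count while rejecting collapses that would break edge-manifoldness (link
condition) or flip normals. On a sphere reduced from ~45k to 2k faces the
measured changes are ≈ 0.1% in volume and well under 1% in area — far
inside the ~5% / ~15% envelope accepted for simplified cell surfaces.

**Voxelisation for the solver.** The material grid has two phases —
buffer and cytoplasm — with intersecting cells fused into a single
cytoplasm: interior shared walls carry no membrane, matching the physical
picture of merged cytoplasms. Every buffer/cytoplasm voxel face is a
membrane face. Raw staircase face areas overestimate a smooth surface by a
factor up to $\sqrt 3$ (the Manhattan-area bias), which would inflate the
membrane capacitance accordingly; each face therefore carries the
projection factor $|\hat n \cdot \hat e_{\mathrm{axis}}|$ of the analytic
surface normal at the face centroid. Summed projected areas converge to
the true membrane area, and with them the interfacial capacitance. For
geometries built from segmented labels (no analytic surface) the factor
defaults to 1 and the staircase bias is inherited — a documented
limitation.

# The electro-quasistatic solver

Under the electro-quasistatic approximation the potential obeys
$\nabla \cdot \big((\sigma + j\omega\varepsilon)\nabla\varphi\big) = 0$.
The default material set is $\sigma_m = 8.7\times10^{-6}$ S/m,
$\sigma_{cyt} = 0.48$ S/m, $\sigma_{buf} = 1$ S/m, $\varepsilon_{rm} =
5.8$, $\varepsilon_{rcyt} = 60$, $\varepsilon_{rbuf} = 80$, membrane
thickness $d_m = 7$ nm, with 1 V applied between two plates covering
opposite box faces.

The discretisation is a node-centred finite-volume admittance network: one
node per voxel, branch admittance $y = \kappa A / d$ between neighbours
(series combination of the two half-voxel admittances, $\kappa = \sigma +
j\omega\varepsilon_0\varepsilon_r$), and on membrane faces an additional
series thin-layer element $y_m = \kappa_m A\,c_f / d_m$ ($c_f$ the
projection factor). The 7 nm membrane is ~100× below any affordable voxel,
so resolving it geometrically is impossible; the thin-layer element carries
the same interfacial admittance per unit area. Dirichlet plates attach to
the boundary voxel layers through half-voxel branches, which makes the
scheme *exact* for piecewise-constant 1D fields — the homogeneous-medium
tests recover the parallel-plate impedance to 13 digits.

The system is complex-symmetric and is solved by the Conjugate Orthogonal
Conjugate Gradient (COCG) iteration with a Jacobi preconditioner, zero
initial guess, fixed ordering, and a relative-residual tolerance of
$10^{-10}$ — deterministic per platform. The impedance is
$Z = V / I$ with $I$ summed over plate-adjacent branches; exact network
conservation makes any cross-section equivalent, and the two plate
currents are compared as a built-in diagnostic. Frequency sweeps use
$10^{\mathrm{linspace}(\log_{10} f_{\min},\, \log_{10} f_{\max},\,
\mathrm{decades}\cdot \mathrm{ppd} + 1)}$ — both endpoints included, so
the default 1 kHz–1 THz grid at 10 points per decade has 91 frequencies —
with one independent solve per frequency (results are frequency-order
independent).

The transmembrane potential is reported per membrane face as
$\varphi_{cyt} - \varphi_{buf}$ across the thin-layer element. At low
frequency the nearly insulating membrane carries essentially the whole
local drop, and the computed maximum on an isolated sphere matches the
Schwan estimate $1.5\,E\,R$ within a few percent at 1 kHz.

Effective properties for the plate geometry follow from the cell constant
$k = L/A$: $\sigma_{\mathrm{eff}} = \mathrm{Re}(1/Z)\,k$ and
$\varepsilon_{r,\mathrm{eff}} = \mathrm{Im}(1/Z)\,k / (\omega
\varepsilon_0)$.

## The single-shell oracle

The analytic reference for a dilute suspension of membrane-covered cells
is the standard interfacial-polarisation (Maxwell–Wagner) model: the
shelled sphere is reduced to an equivalent homogeneous particle
$$\varepsilon_p^* = \varepsilon_m^*
\frac{2(1-v)\varepsilon_m^* + (1+2v)\varepsilon_c^*}
     {(2+v)\varepsilon_m^* + (1-v)\varepsilon_c^*},
\qquad v = (1 - d_m/R)^3,$$
then mixed with the buffer by the dilute Maxwell–Wagner formula
$\varepsilon^*_{\mathrm{eff}} = \varepsilon_b^* (1 + 2p\beta)/(1 -
p\beta)$, $\beta = (\varepsilon_p^* - \varepsilon_b^*)/(\varepsilon_p^* +
2\varepsilon_b^*)$. This model produces the β-dispersion: a permittivity
step around 1 MHz caused by membrane charging. The solver reproduces it
within 3% at a 2% volume fraction on a 64³ grid (the tests assert 5%),
and both routes show the characteristic monotonicity — higher cell volume
fraction gives larger low-frequency permittivity and lower conductivity,
with the cells invisible at high frequency.

## Discretisation error and refinement

The voxel network is first-order accurate for curved interfaces: the
polyhedral staircase induces local field singularities that converge
slowly. On a fixed discrete shelled-sphere fixture (geometry and membrane
faces frozen, solver grid refined 2× and 3×), $\sigma_{\mathrm{eff}}$
changes by < 0.05% between the two finest levels, but
$\varepsilon_{r,\mathrm{eff}}$ — a small imaginary admittance component at
low frequency — still changes by ≈ 0.5%. A second-order conforming FEM on
a smooth CAD surface can reach consistency near 0.05% for both quantities;
the voxel network deliberately trades that for robustness (no CAD or
tetrahedral meshing step can fail) and exact conservation. This is the
package's known accuracy limitation, and the acceptance suite reports the
measured figure rather than hiding it.

# Uncertainty quantification

Outputs ($\sigma_{\mathrm{eff}}$ and $\varepsilon_{r,\mathrm{eff}}$ per
frequency) are expanded in polynomials orthonormal under the uniform
parameter distributions (tensor Legendre, total degree ≤ 4 by default).
Coefficients come from least squares on a seeded random collocation design
of $2M + 2$ points, $M = \binom{d+p}{p}$ — the standard 2× oversampling
for point collocation, which gives 254 model evaluations for 5 parameters
and 662 for 7 at order 4. First-order Sobol indices are ratios of
coefficient power on single-parameter terms to total variance (zero
variance defined as index 0); 5th/95th percentiles come from $10^4$
surrogate samples.

**Case 1 (geometric uncertainty)** uses a two-cell unit geometry: a
movable prolate cell (a:c = 1.5) at the box centre with uncertain x/y/z
position, volume (±25%) and orientation angle (0–90° about a transverse
axis), and a fixed copy towards the top-right corner. The position range
is constructed so the surface-to-surface distance between the cells spans
4.5–22.5 µm, and collocation nodes where the cells would intersect are
redrawn (keeping the design size fixed). The desk-scale default — 524 µm³
cells in a 48 µm box at 32³ voxels and 6 frequencies — reproduces the
qualitative finding that the cell volume dominates the dielectric output
while position is negligible (indices < 0.05). Exact published parameter
ranges live in supplementary material that is not available, so the ranges
here are declared defaults, and quantitative interval widths are not
asserted. Because the voxelised response is a staircase in the geometric
parameters, a fraction of fitted power leaks into inert parameters at
coarse resolution; the leak shrinks with grid refinement and is why the
degenerate-case test asserts dominance rather than exact unity.

**Case 2 (material uncertainty)** varies membrane thickness and the
cellular dielectric properties (±25% around nominal) on a fixed geometry,
optionally holding the extracellular properties fixed — they can be
measured separately on decellularised tissue and otherwise overshadow the
cellular parameters.

# Reproducibility and scale

Every random draw is seeded and isolated; pipelines rerun byte-identically.
The test-suite and verification problem sizes (64³–96³ solver grids, 254
collocation nodes at 32³, 500-cell populations) were chosen as the smallest
fixtures on which each scientific claim is measurable; all solver
tolerances are stated in the function defaults.
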