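---
title: "Methods: 3D traction reconstruction and matrix-remodeling statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D traction reconstruction and matrix-remodeling statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfm3d)
```

## The measurement problem

Multicellular cohorts invading a three-dimensional collagen gel deform the
matrix around them. Tracking fluorescent fiducial beads embedded in the gel
— referenced against a force-free configuration obtained after lysing the
tissue — gives a scattered sample of the matrix displacement field. From it
one wants (i) local strain, (ii) the stress state of the gel and the
traction the tissue exerts across its surface, and (iii) statistics of the
accompanying matrix remodeling and cohort dynamics: collagen fibril
alignment ahead of the invasive front, the temporal correlation between
cohort shape and nearby bead motion, and the directionality of invasion
across replicate tissues.

`tfm3d` implements this pipeline end to end, together with a synthetic-data
layer that generates every input with known ground truth. All lengths are in
micrometres, times in hours, moduli and stresses in pascal, and angles in
degrees; images and masks use matrix `[row, col]` indexing with angles
measured counter-clockwise from +x with y pointing up.

## Displacement, strain

Bead tracks (`bead_id, t, x, y, z`) are converted to displacement samples by
subtracting each bead's reference position (`displacements_from_tracks()`).
The scattered sample is turned into a continuous field with a per-component
radial-basis-function interpolant (`displacement_interpolator()`). The
default is a Gaussian kernel with a small ridge and a length scale of twice
the mean nearest-neighbour bead spacing (estimated from the bounding-box
density of the cloud); at the reference seeding density of
4e-4 beads/μm³ (4×10⁸ beads/ml) the spacing is ≈7.5 μm and the
default length scale ≈15 μm. A compactly supported Wendland C2 kernel
(sparse linear algebra, for very large clouds) and a polyharmonic kernel
with an exact affine tail are alternatives. Queries farther than one length
scale from every sample are flagged as extrapolation.

Strain is obtained by differentiating the interpolant with central
differences (step `h = 1` μm; the gradient of an affine field is recovered
to machine precision regardless of `h`). Both strain measures are reported:

* Green–Lagrange strain `E = (G + Gᵀ + GᵀG)/2`, `G = ∇u`, exactly zero for
  rigid motions and the appropriate finite-strain measure;
* infinitesimal strain `ε = (G + Gᵀ)/2`, the measure entering Hooke's law.

The elastic solve below is *linear*, so it consumes `ε`. Pairing a
finite-strain kinematic readout with a linear-elastic constitutive model is
deliberate and mirrors common practice in this kind of analysis: the goal is
the spatial pattern and directionality of traction rather than an absolute
magnitude, and the inconsistency between the two measures is second order in
`‖∇u‖` (here at most a few percent). Both tensors appear in
`strain_table()` so the size of that gap is always visible.

## The elastic boundary-value problem

The gel is modelled as a homogeneous isotropic linear-elastic solid,

$$T = 2\mu\,\varepsilon + \lambda\,\mathrm{tr}(\varepsilon) I,$$

with Poisson ratio ν = 0.2 by default and Young's modulus `E = 500` Pa. The
modulus of a collagen gel is strongly preparation-dependent and the package
treats it as a configurable scale parameter: tractions are proportional to
`E`, so patterns and ratios are modulus-independent. Real gels are
anisotropic, viscoelastic and strain-stiffening; none of that is modelled,
which is precisely why only spatial patterns should be interpreted.

`solve_displacement_bvp()` solves static equilibrium `∇·T = 0` with
Dirichlet data on both boundaries: interpolated bead displacements on the
tissue–gel interface, and zero displacement on the outer gel boundary (a
cylinder of 2 mm height and diameter by default, matching the physical gel
block; the finite outer boundary perturbs the far field by `(a/R)³ ≈ 10⁻⁴`
for a 50 μm tissue).

The mesh (`build_gel_mesh()`) extrudes the triangulated tissue surface
radially to the outer boundary. Shell radii are log-spaced, which keeps the
element aspect fixed relative to the distance from the interface — the right
grading for fields decaying like `r⁻²`. Prisms between shells are split into
three tetrahedra with globally consistent diagonals (sorting each column
triple by global vertex index), and quadratic ten-node elements are formed
by edge-midpoint insertion. Midside nodes are projected onto the curved
shells and the elements are treated **isoparametrically**: with straight
(affine) elements the faceted sphere lies strictly inside the true
interface, where the exact cavity stress is ~12% larger, and recovered
tractions inherit that bias. Surfaces must be star-shaped about their
center; idealized spheres (`surface_sphere()`) are first-class, and any
watertight star-shaped triangulation is accepted.

Stress is evaluated from Hooke's law at the element nodes and recovered to
mesh nodes by volume-weighted averaging over adjacent elements. Tractions
follow as `t = T·n` with `n` the outward tissue normal (pointing into the
gel). **Sign convention:** the normal component `tₙ = t·n` is positive when
the interface is under tension, i.e. when the tissue pulls the matrix toward
itself — the situation indicated by inward-directed bead displacement. (The
scalar `n·T·n` is invariant under flipping `n`, so this is the only
unambiguous way to label "tensile".)

Verification, all in the test suite and acceptance script:

* patch test — affine Dirichlet data reproduced to ~1e-10 on straight
  (`curved = FALSE`) meshes of either order; on curved isoparametric meshes
  the test passes to quadrature-consistency level (~1e-3 relative even on a
  deliberately coarse, strongly curved mesh), the standard behaviour of
  curved elements under fixed-order quadrature;
* spherical-cavity oracle `u(r) = -p a³/(4 μ r²) r̂` (tensile `p > 0` pulls
  inward, `σ_rr = p a³/r³`): displacement error for `r ≤ 4a` decreases
  monotonically over refinements at 6/12/24 layers and is ≪5% when refined,
  and the surface-median `|t|` lands within a few percent of `p`;
* linearity, zero-data, hydrostatic (`t = -p n`), and net-force balance
  (`∮ t dA ≈ 0` for the cavity load within 5% of `mean|t|·area`).

The problem sizes used throughout (icosphere subdivision 1, 6–24 radial
layers, ≈1.4k–5.8k quadratic tetrahedra) were chosen as the coarsest meshes
whose verification errors sit comfortably inside those bounds.

## Fibril alignment

Orientation is estimated per subregion from the structure tensor — the
subregion sum of outer products of the (optionally pre-smoothed) intensity
gradient. The fiber axis is the gradient's dominant direction rotated by
90°, and the coherence (normalized eigenvalue anisotropy) gates out
featureless subregions (default threshold 0.2; exposed in the config).
Fibers are orientations, not directions, so every statistic uses the
doubled-angle device: alignment index `R` = resultant length of `2θ`,
circular mean = half the mean of `2θ`, Rayleigh test on `2θ`, and the angle
difference to a reference (e.g. the migration direction) folded into
`[0°, 90°]`.

The measurement grid is **spaced**: 8 px windows sampled every 16 px
(30 × 30 = 900 locations on a 480 px image). Contiguous windows are not
statistically independent — a fibril or the optical blur straddles window
borders — and feeding such correlated angles to the Rayleigh test inflates
its effective sample size (measured type-I error ≈11% at nominal 5% with
contiguous windows). With the spaced grid the test is calibrated: 5.5%
rejections at α = 0.05 over 400 isotropic images, with a uniform p-value
distribution (KS p = 0.96). Region contrasts (near-front vs far matrix) use
a label-shuffling permutation test on the difference in `R`, since the
choice of test behind published rose-plot contrasts is typically unstated.

The synthetic fibrillar images draw axial angles from a doubled-angle von
Mises distribution (concentration κ, `κ = 0` isotropic), render anti-aliased
segments (default length 8 px — shorter than a sampling window, so
neighbouring measurements stay decoupled), blur with a 1 px Gaussian PSF and
add Gaussian noise. They emulate the orientation statistics of
reflection-mode images of collagen, not their full optical physics: no
speckle, no depth attenuation, no fibril crosslinks or curvature. Passing
tests therefore demonstrate correctness of the estimators on images with
controlled orientation content, not robustness to every real-world artifact.

## Cohort dynamics and directionality

`cross_covariance()` implements the sample cross-covariance
`c_xy(k) = n⁻¹ Σ (x_t − x̄)(y_{t+k} − ȳ)` and the cross-correlation
coefficient `r_xy(k) = c_xy(k)/(s_x s_y)`. The `1/n` (biased) estimator with
`1/(n−1)` standard deviations is the default convention — the one used by
common statistical software — with a `1/(n−|k|)` variant and `1/n` standard
deviations available as options (with matched conventions `r_xx(0) = 1`
exactly). A brute-force double-loop implementation serves as the test
oracle.

For the near/far analysis, beads are classified by minimum distance to the
cohort over the window (near < 50 μm; exactly 50 μm counts as far — the
classes are strict inequalities, so the boundary must be assigned by fiat).
Bead scalar series default to the signed projection of displacement onto the
bead-to-cohort direction, which carries the "in phase with extension"
information; raw magnitude is an option. Both series are first-differenced
before correlating, so the contrast concerns length *variations* rather
than the shared growth trend, and the per-bead peak correlations of near vs
far beads are compared with Welch's one-sided t-test (robust to the unequal
variances the two classes typically have).

The coupled-series generator produces a cohort length with linear growth
plus a periodic protrusion–retraction cycle, near beads as a lagged, scaled
copy plus tracking noise, and far beads as independent noise of matched
marginal variance. Defaults: 2 h sampling over 40 h, 12 h fluctuation
period, noise σ = 3.5 μm giving a signal-to-noise ratio of ≈5, and 7 beads
per class. The fluctuation period is deliberately not twice the sampling
interval times the default lag: a cycle of 4 samples would make a 2-sample
lag exactly half a period and the correlation peak ±2-ambiguous by symmetry,
a degenerate configuration rather than a fair test.

Invasion directionality uses binarized tissue masks of identical initial
geometry: `frequency_map()` is the exact per-pixel occupancy fraction `k/n`,
and `invasion_angles()` labels connected components outside the base shape
and reports one tip angle per cohort (directional, 0° = east,
counter-clockwise), with the Rayleigh test of directional uniformity.
Cohort length from a mask is the maximal perpendicular distance from the
original tissue edge, or a geodesic (8-connected shortest-path) length for
bent cohorts.

## Numerical and degenerate-input policy

* All generators are bit-reproducible from integer seeds (`withr::with_seed`
  keeps the global RNG untouched); the end-to-end pipeline writes a manifest
  (config echo, seed, artifact checksums) from which a run can be repeated
  exactly.
* The reference timepoint of synthetic tracks is noise-free: it *defines*
  the rest configuration, so a zero-amplitude schedule yields displacement
  vectors that are pure single-measurement noise (RMS σ√3).
* Flat images yield an empty orientation sample with a warning; empty masks
  and absent cohorts yield zero length / empty angle lists with warnings;
  zero-variance series, coplanar interpolation data, non-watertight
  surfaces, surfaces touching the gel boundary, and partitions that fail to
  cover the tractions are errors.
* Ties: bead exactly at the near/far threshold → far; top-decile traction
  nodes are selected by rank with deterministic tie-breaking on node index,
  so a uniform field carries exactly 10% of nodes.
* `ν ≥ 0.5` is rejected (incompressible limit needs a mixed formulation).

## Known limitations

Homogeneous isotropic linear elasticity is the central simplification:
absolute traction magnitudes inherit the uncertainty of the gel modulus and
of matrix nonlinearity, and only spatial/temporal patterns should be
compared across conditions. The mesher requires star-shaped surfaces;
strongly branched real tissues would need a general tetrahedralizer.
Synthetic data emulate the statistical structure of the real measurements
(field decay laws, Poisson bead seeding, orientation concentration, lagged
coupling), not cell biology or full microscope optics — conclusions about
estimator calibration transfer to real data only insofar as those
ingredients dominate.
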