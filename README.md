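# tfm3d

Three-dimensional traction force microscopy and matrix-remodeling analysis
for collective cell migration in collagen gels.

Multicellular cohorts invading a 3D extracellular matrix pull on the
surrounding collagen. `tfm3d` reconstructs that mechanical picture from the
quantities such experiments actually measure — trajectories of fiducial
beads embedded in the gel, referenced to a force-free (post-lysis) state;
reflection-mode images of collagen fibrils; time series of cohort shape;
binarized masks of replicate tissues — and is aimed at quantitative
cell-biology and mechanobiology groups running micropatterned 3D invasion
assays.

The core computation is a direct boundary-value solve. Bead displacements
`u` are interpolated into a continuous field (per-component RBF), strain is
evaluated from the displacement gradient both as Green–Lagrange strain
`E = ½(∇u + ∇uᵀ + ∇uᵀ∇u)` and infinitesimal strain `ε = ½(∇u + ∇uᵀ)`, and
the gel is treated as an isotropic Hookean solid, `T = 2με + λ tr(ε) I`
(ν = 0.2, modulus a configurable scale). Static equilibrium `∇·T = 0` is
solved by quadratic-tetrahedral finite elements on a radially extruded mesh
of the gel, with the interpolated displacements as Dirichlet data on the
tissue surface and zero displacement on the outer gel boundary (a 2 mm
cylinder). Tractions follow as `t_i = T_ij n_j` on the interface, with
`t·n > 0` labelled tensile. Around it sit the remodeling statistics:
structure-tensor fibril orientation with axial circular statistics
(alignment index `R` on doubled angles, Rayleigh test, Δθ to a reference
direction), lagged cross-covariance
`c_xy(k) = n⁻¹ Σ (x_t − x̄)(y_{t+k} − ȳ)` between cohort length and bead
displacement with near (<50 μm) / far (>50 μm) contrasts, and
invasion-frequency maps and rose diagrams over replicate masks. A
synthetic-data layer (closed-form cavity and Kelvin point-force fields,
Poisson bead seeding, fibrillar image rendering, coupled series, mask
stacks) generates every input with known ground truth.

## Worked example

A virtual experiment: a 50 μm spherical tissue pulls on the gel with a
uniform tensile traction of 100 Pa; beads at 4×10⁸ beads/ml are tracked
with 0.1 μm noise; the pipeline reconstructs the traction from the tracks
alone.

```r
library(tfm3d)

material <- elastic_material(E = 500, nu = 0.2)
scene <- synthetic_scene(
  material = material,
  loading = cavity_load(a = 50, p = 100),          # tensile pull, Pa
  domain = gel_box(c(-100, -100, -100), c(100, 100, 100)),
  bead_density = 4e-4,                              # beads / um^3
  noise_sigma = 0.1, seed = 11
)
tracks <- synthesize_bead_tracks(scene, timepoints = c(0, 2),
                                 amplitude_schedule = c(0, 1))
field  <- displacements_from_tracks(tracks, reference_time = 0, time = 2)
interp <- displacement_interpolator(field)

mesh <- build_gel_mesh(surface_sphere(radius = 50, subdivisions = 1),
                       outer = gel_cylinder(radius = 1000, height = 2000),
                       n_layers = 12)
solution  <- solve_displacement_bvp(mesh, material, interp)
tractions <- surface_tractions(solution)
glance(tractions)
#> # A tibble: 1 × 5
#>   n_nodes median_t mean_t max_t tensile_fraction
#>     <int>    <dbl>  <dbl> <dbl>            <dbl>
#> 1     162     96.1   96.6  169.            0.994
```

The surface-median traction magnitude is 96.1 Pa — within 4% of the 100 Pa
ground truth despite the tracking noise — and 99.4% of interface nodes are
under tension (`t·n > 0`), i.e.
the reconstructed tissue pulls the matrix inward everywhere, which is the
mechanical signature of collective invasion this analysis is built to
detect. `autoplot(tractions)` maps `|t|` over the surface;
`strain_table(interp, points)` gives both strain tensors at any location
(for this load, radial contraction with the characteristic −2
hoop-to-radial ratio).

The same vocabulary covers the remodeling statistics:

```r
img <- render_fiber_image(fiber_field_spec(kappa = 5, mean_angle = 40, seed = 1))
alignment_stats(subregion_orientations(img), reference_angle = 40)
#> <alignment_stats> n = 850, mean = 38.6 deg, R = 0.533, Rayleigh p = 2.67e-114
#>   delta-theta vs 40.0 deg: median 18.1 deg

cs <- synthesize_coupled_series(coupled_series_spec(lag = 2, seed = 3))
near_far_correlation_report(cs$cohort, cs$beads)
#> <correlation_report>
#> # A tibble: 2 × 5
#>   class     n mean_peak_r sd_peak_r modal_lag
#>   <chr> <int>       <dbl>     <dbl>     <int>
#> 1 far       7       0.189    0.0923         0
#> 2 near      7       0.532    0.120          2
#> Welch one-sided (far < near) p = 4.04e-05
```

Fibrils concentrated about 40° are detected at their true mean with a
decisive Rayleigh rejection of isotropy; beads near the cohort correlate
with its length variations at the generator's 2-sample lag while far beads
do not, and the class contrast is significant.

`run_e2e(default_config(), seed = 1, out_dir = "out")` executes the whole
pipeline (tracks → strain → traction → fibrils → dynamics → frequency maps)
and writes CSV/TIFF/VTK/JSON artifacts plus a manifest (seed, config echo,
checksums) from which any run reproduces bit-identically. A thin CLI wrapper
lives at `inst/cli/tfm3d.R`.

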