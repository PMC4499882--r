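#' Run the full synthetic end-to-end pipeline
#'
#' Exercises every stage on synthetic data with known ground truth and writes
#' all artifacts plus a JSON run manifest:
#' \enumerate{
#'   \item simulate a cavity-loaded bead scene and write the bead tracks;
#'   \item reconstruct the displacement field, interpolate, and write a
#'     strain table;
#'   \item mesh the gel around the spherical tissue, solve the elastic BVP
#'     with the interpolated interface displacements, and write tractions;
#'   \item render a fibrillar image and write orientation statistics;
#'   \item generate coupled cohort/bead series and write the correlation
#'     report;
#'   \item generate a mask stack and write the frequency map and invasion
#'     angles.
#' }
#' Every random draw derives from `seed`, so a run is reproducible (bit
#' identical artifacts) from its manifest alone.
#'
#' @param config Configuration list from [default_config()] /
#'   [load_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param mesh_layers Radial mesh layers (overrides the config; the default
#'   keeps the solve light).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest_path`.
#' @export
run_e2e <- function(config = default_config(), seed = 1L,
                    out_dir = config$output$dir, mesh_layers = NULL) {
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  material <- elastic_material(config$material$E, config$material$nu)
  hw <- config$scene$box_halfwidth

  # -- simulate ---------------------------------------------------------
  scene <- synthetic_scene(
    material = material,
    loading = cavity_load(a = config$scene$a, p = config$scene$p),
    domain = gel_box(c(-hw, -hw, -hw), c(hw, hw, hw)),
    bead_density = config$scene$bead_density,
    noise_sigma = config$scene$noise_sigma,
    seed = seed
  )
  tracks <- synthesize_bead_tracks(scene, timepoints = c(0, 2),
                                   amplitude_schedule = c(0, 1))
  tracks_path <- file.path(out_dir, "bead_tracks.csv")
  write_bead_tracks(tracks, tracks_path)

  # -- strain -----------------------------------------------------------
  field <- displacements_from_tracks(tracks, reference_time = 0, time = 2)
  interp <- displacement_interpolator(
    field, method = config$interpolation$method,
    length_scale = config$interpolation$length_scale,
    ridge = config$interpolation$ridge
  )
  probe <- as.matrix(expand.grid(x = c(60, 80), y = 0, z = 0))
  strains <- strain_table(interp, probe)
  strain_path <- file.path(out_dir, "strain_table.csv")
  write_field_csv(strains, strain_path)

  # -- traction ---------------------------------------------------------
  n_layers <- if (is.null(mesh_layers)) config$mesh$n_layers else mesh_layers
  surface <- surface_sphere(radius = config$scene$a, subdivisions = 1L)
  mesh <- build_gel_mesh(
    surface,
    outer = gel_cylinder(radius = config$mesh$gel_radius,
                         height = config$mesh$gel_height),
    n_layers = n_layers, order = config$mesh$order
  )
  solution <- solve_displacement_bvp(mesh, material, interp)
  tractions <- surface_tractions(solution)
  traction_path <- file.path(out_dir, "tractions.csv")
  write_field_csv(tractions, traction_path)
  write_vtk_points(tractions[, c("x", "y", "z")],
                   file.path(out_dir, "tractions.vtk"),
                   vectors = list(traction = as.matrix(
                     tractions[, c("tx", "ty", "tz")])),
                   scalars = list(t_mag = tractions$t_mag,
                                  t_n = tractions$t_n))

  # -- fibrils ----------------------------------------------------------
  fib <- render_fiber_image(fiber_field_spec(kappa = 5, mean_angle = 40,
                                             seed = seed + 10L))
  sample <- subregion_orientations(
    fib, subregion_size = config$alignment$subregion_size,
    stride = config$alignment$stride,
    coherence_min = config$alignment$coherence_min)
  astats <- alignment_stats(sample, reference_angle = 40)
  write_image_tiff(pmin(fib$image, 1), file.path(out_dir, "fibrils.tiff"))
  jsonlite::write_json(
    list(n = astats$n, mean_angle = astats$mean_angle, R = astats$R,
         p_rayleigh = astats$p_rayleigh,
         delta_theta_median = astats$delta_theta_median),
    file.path(out_dir, "alignment.json"), auto_unbox = TRUE, digits = NA)

  # -- dynamics ---------------------------------------------------------
  cs <- synthesize_coupled_series(coupled_series_spec(
    duration = config$series$duration, dt = config$series$dt, lag = 2L,
    seed = seed + 20L))
  report <- near_far_correlation_report(cs$cohort, cs$beads,
                                        max_lag = config$ccf$max_lag)
  jsonlite::write_json(
    list(p_value = report$p_value,
         class_summary = report$class_summary,
         near_modal_peak_lag = report$class_summary$modal_lag[
           report$class_summary$class == "near"]),
    file.path(out_dir, "dynamics.json"), auto_unbox = TRUE, digits = NA)

  # -- freqmap ----------------------------------------------------------
  stack <- synthesize_mask_stack(
    n_tissues = config$masks$n_tissues,
    base_shape = disk_mask(config$masks$image_size, config$masks$base_radius),
    seed = seed + 30L)
  fmap <- frequency_map(stack)
  angles <- invasion_angles(stack)
  write_image_tiff(unclass(fmap), file.path(out_dir, "frequency_map.tiff"))
  jsonlite::write_json(
    list(n_cohorts = angles$n, R = angles$R,
         rayleigh_p = angles$rayleigh$p.value),
    file.path(out_dir, "invasion.json"), auto_unbox = TRUE, digits = NA)

  manifest_path <- write_manifest(out_dir, config, seed)
  invisible(list(scene = scene, tracks = tracks, field = field,
                 interp = interp, mesh = mesh, solution = solution,
                 tractions = tractions, alignment = astats, report = report,
                 frequency_map = fmap, invasion = angles,
                 manifest_path = manifest_path))
}

# JSON manifest: config echo, seed, package version, md5 of every artifact.
write_manifest <- function(out_dir, config, seed) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "tfm3d",
    version = as.character(utils::packageVersion("tfm3d")),
    seed = seed,
    config = config,
    artifacts = as.list(setNames(unname(sums), files))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
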