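#' Loading specifications for synthetic scenes
#'
#' `cavity_load()` describes a uniform tensile traction `p` on a spherical
#' tissue of radius `a`; `point_load()` a concentrated (Kelvin) force applied
#' at a point, emulating a localized pull at an invasive front.
#'
#' @param a Cavity radius, um.
#' @param p Interface traction, Pa (positive = tensile, inward matrix pull).
#' @param force Length-3 force vector, Pa um^2.
#' @param location Length-3 application point, um.
#' @return A `scene_loading` object.
#' @export
cavity_load <- function(a = 50, p = 100) {
  if (a <= 0) abort("`a` must be positive")
  structure(list(type = "cavity", a = a, p = p, center = c(0, 0, 0)),
            class = "scene_loading")
}

#' @rdname cavity_load
#' @export
point_load <- function(force, location = c(0, 0, 0)) {
  structure(list(type = "point", force = as.numeric(force),
                 location = as.numeric(location)),
            class = "scene_loading")
}

#' Synthetic bead-tracking scene
#'
#' Describes a virtual traction-force-microscopy experiment: an elastic gel
#' domain seeded with fluorescent fiducial beads around a loaded tissue. Bead
#' density defaults to `4e-4` beads/um^3 (i.e. ~4 x 10^8 beads/ml, the
#' seeding density used for 1-um polystyrene beads in collagen), and tracking
#' noise to an isotropic 0.1 um per coordinate (sub-pixel accuracy for 1-um
#' beads).
#'
#' @param material An [elastic_material()].
#' @param loading A [cavity_load()] or [point_load()].
#' @param domain A [gel_box()] or [gel_cylinder()] containing the loading.
#' @param bead_density Beads per um^3.
#' @param noise_sigma Tracking noise SD per coordinate, um.
#' @param seed Integer RNG seed; every realization is reproducible from it.
#' @return A `synthetic_scene` object.
#' @export
synthetic_scene <- function(material = elastic_material(),
                            loading = cavity_load(),
                            domain = gel_box(c(-100, -100, -100), c(100, 100, 100)),
                            bead_density = 4e-4,
                            noise_sigma = 0.1,
                            seed = 1L) {
  material <- as_material(material)
  if (bead_density <= 0) abort("`bead_density` must be positive")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  loc <- if (loading$type == "cavity") loading$center else loading$location
  if (!domain_contains(domain, matrix(loc, 1))) {
    abort("loading location must lie inside the domain")
  }
  if (loading$type == "cavity") {
    # the cavity must clear the domain boundary
    wall <- min(ray_exit_distance(domain, loc, diag(3)),
                ray_exit_distance(domain, loc, -diag(3)))
    if (loading$a >= wall) abort("cavity radius must be smaller than the distance to the domain boundary")
  }
  structure(
    list(material = material, loading = loading, domain = domain,
         bead_density = bead_density, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

#' Evaluate the scene's ground-truth displacement field
#'
#' @param scene A [synthetic_scene()].
#' @param points Query points (um).
#' @return Tibble `x, y, z, ux, uy, uz`.
#' @export
scene_displacement <- function(scene, points) {
  switch(scene$loading$type,
    cavity = cavity_displacement_field(points, scene$material,
                                       a = scene$loading$a, p = scene$loading$p,
                                       center = scene$loading$center),
    point = kelvin_displacement_field(points, scene$material,
                                      force = scene$loading$force,
                                      location = scene$loading$location)
  )
}

#' Seed fiducial beads as a homogeneous Poisson point process
#'
#' The bead count is Poisson with mean `density * volume(domain)` and the
#' positions are uniform, optionally thinned to exclude a spherical tissue
#' region (beads cannot sit inside the cell cohort).
#'
#' @param domain A `gel_domain`.
#' @param density Beads per um^3 (default 4e-4 = 4 x 10^8 beads/ml).
#' @param seed Integer RNG seed.
#' @param exclude Optional list `list(center =, radius =)`: drop beads inside
#'   this sphere.
#' @return Tibble with `bead_id, x, y, z`.
#' @export
sample_bead_positions <- function(domain, density = 4e-4, seed = 1L,
                                  exclude = NULL) {
  if (density <= 0) abort("`density` must be positive")
  vol <- domain_volume(domain)
  if (vol <= 0) abort("domain has zero volume")
  pts <- withr::with_seed(as.integer(seed), {
    n <- rpois(1L, density * vol)
    sample_points_in_domain(domain, n)
  })
  if (!is.null(exclude)) {
    q <- sweep(pts, 2, exclude$center)
    keep <- sqrt(rowSums(q^2)) > exclude$radius
    pts <- pts[keep, , drop = FALSE]
  }
  tibble(bead_id = sprintf("b%05d", seq_len(nrow(pts))),
         x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Synthesize bead trajectories under a loading amplitude schedule
#'
#' Rest positions are Poisson-seeded in the scene's domain (excluding the
#' tissue for cavity loadings); at each timepoint the ground-truth field is
#' applied scaled by the schedule, plus isotropic Gaussian tracking noise:
#' `position(t) = rest + amplitude(t) * u(rest) + noise`. The first schedule
#' entry must be 0 so that the first timepoint is the force-free reference
#' configuration (the role played experimentally by the post-lysis state).
#'
#' @param scene A [synthetic_scene()].
#' @param timepoints Strictly increasing times, hours.
#' @param amplitude_schedule Numeric vector, one amplitude per timepoint;
#'   `amplitude_schedule[1]` must be 0.
#' @return Tibble in bead-track form: `bead_id, t, x, y, z`, one row per bead
#'   per timepoint. The ground-truth field and rest positions are attached as
#'   attributes `truth` and `scene`.
#' @export
synthesize_bead_tracks <- function(scene, timepoints = c(0, 2),
                                   amplitude_schedule = c(0, 1)) {
  if (length(timepoints) != length(amplitude_schedule)) {
    abort("`timepoints` and `amplitude_schedule` must have equal length")
  }
  if (length(timepoints) < 2L) abort("need at least two timepoints")
  if (any(diff(timepoints) <= 0)) abort("`timepoints` must be strictly increasing")
  if (amplitude_schedule[1] != 0) {
    abort("`amplitude_schedule[1]` must be 0 (force-free reference state)")
  }
  exclude <- if (scene$loading$type == "cavity") {
    list(center = scene$loading$center, radius = scene$loading$a)
  }
  beads <- sample_bead_positions(scene$domain, scene$bead_density,
                                 seed = scene$seed, exclude = exclude)
  rest <- as_point_matrix(beads)
  truth <- scene_displacement(scene, rest)
  uvec <- as.matrix(truth[, c("ux", "uy", "uz")])
  nt <- length(timepoints)
  nb <- nrow(rest)
  noise <- withr::with_seed(scene$seed + 1L, {
    if (scene$noise_sigma > 0) {
      array(rnorm(nb * nt * 3L, sd = scene$noise_sigma), dim = c(nb, 3L, nt))
    } else {
      array(0, dim = c(nb, 3L, nt))
    }
  })
  # the reference timepoint defines the rest configuration and is exact:
  # displacements then carry one noise term per vector (RMS sigma * sqrt(3))
  noise[, , 1L] <- 0
  rows <- purrr::map(seq_len(nt), function(k) {
    pos <- rest + amplitude_schedule[k] * uvec + noise[, , k]
    tibble(bead_id = beads$bead_id, t = timepoints[k],
           x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  out <- bind_rows(rows) %>% arrange(.data$bead_id, .data$t)
  attr(out, "truth") <- truth
  attr(out, "scene") <- scene
  out
}
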