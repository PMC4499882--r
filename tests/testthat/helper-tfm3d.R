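# Shared fixtures. Meshes are cached per session because assembly dominates
# test time; everything is built in code (no stored fixtures).

default_material <- function() elastic_material(E = 500, nu = 0.2)

# analytic cavity displacement valid at any radius (including the faceted
# interface nodes slightly inside the nominal sphere): the Dirichlet oracle
cavity_bc <- function(material, a, p, center = c(0, 0, 0)) {
  force(material); force(a); force(p); force(center)
  function(pts) {
    q <- sweep(pts, 2, center)
    r <- sqrt(rowSums(q^2))
    q * (-p * a^3 / (4 * material$mu * r^2) / r)
  }
}

.mesh_cache <- new.env(parent = emptyenv())
cached_mesh <- function(key, builder) {
  if (is.null(.mesh_cache[[key]])) .mesh_cache[[key]] <- builder()
  .mesh_cache[[key]]
}

sphere_mesh <- function(n_layers, subdiv = 1L, order = 2L, a = 50,
                        curved = TRUE) {
  cached_mesh(sprintf("s%d_L%d_o%d_a%g_c%d", subdiv, n_layers, order, a, curved),
              function() {
    build_gel_mesh(surface_sphere(a, subdivisions = subdiv),
                   gel_cylinder(radius = 1000, height = 2000),
                   n_layers = n_layers, order = order, curved = curved)
  })
}

# brute-force double-loop cross-covariance oracle (independent of the
# implementation)
ccf_bruteforce <- function(x, y, max_lag) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sx <- sd(x); sy <- sd(y)
  lags <- (-max_lag):max_lag
  ccov <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) s <- s + (x[t] - xb) * (y[t + k] - yb)
    }
    ccov[i] <- s / n
  }
  list(lag = lags, ccov = ccov, ccor = ccov / (sx * sy))
}
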