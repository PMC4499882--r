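#' Specification of coupled cohort/bead time series
#'
#' Generator emulating the joint dynamics of a migrating cohort and the
#' surrounding matrix: cohort length grows linearly with a periodic
#' protrusion-retraction fluctuation superimposed; beads near the cohort move
#' as a (possibly lagged) scaled copy of the length series plus tracking
#' noise, while far beads fluctuate independently with matched marginal
#' variance. Sampling interval defaults to 2 h (the live-imaging frame
#' interval) over 40 h.
#'
#' Default `noise_sigma = 3.5` um gives a signal-to-noise ratio (SD of the
#' coupled component over noise SD) of about 5.
#'
#' @param duration,dt Total duration and sampling interval, hours.
#' @param baseline_length Initial cohort length, um.
#' @param growth_rate Linear extension rate, um/h.
#' @param fluctuation_amplitude,fluctuation_period Amplitude (um) and period
#'   (h) of the protrusion-retraction cycle.
#' @param coupling_gain Dimensionless gain from cohort length to near-bead
#'   displacement.
#' @param lag Lag of the near-bead response, integer samples (bead follows
#'   cohort by `lag * dt` hours).
#' @param noise_sigma Bead measurement noise SD, um.
#' @param n_near,n_far Number of near / far beads.
#' @param seed Integer RNG seed.
#' @return A `coupled_series_spec` object.
#' @export
coupled_series_spec <- function(duration = 40, dt = 2, baseline_length = 50,
                                growth_rate = 1.5, fluctuation_amplitude = 5,
                                fluctuation_period = 12, coupling_gain = 1,
                                lag = 0L, noise_sigma = 3.5,
                                n_near = 7L, n_far = 7L, seed = 1L) {
  if (dt <= 0) abort("`dt` must be positive")
  if (duration < 10 * dt) abort("`duration` must be at least 10 * dt")
  if (abs(lag) * dt >= duration / 4) abort("`lag * dt` must be < duration / 4")
  structure(
    list(duration = duration, dt = dt, baseline_length = baseline_length,
         growth_rate = growth_rate,
         fluctuation_amplitude = fluctuation_amplitude,
         fluctuation_period = fluctuation_period,
         coupling_gain = coupling_gain, lag = as.integer(lag),
         noise_sigma = noise_sigma, n_near = as.integer(n_near),
         n_far = as.integer(n_far), seed = as.integer(seed)),
    class = "coupled_series_spec"
  )
}

cohort_length_model <- function(spec, t) {
  spec$baseline_length + spec$growth_rate * t +
    spec$fluctuation_amplitude * sin(2 * pi * t / spec$fluctuation_period)
}

#' Synthesize coupled cohort and bead displacement series
#'
#' @param spec A [coupled_series_spec()].
#' @return List of class `coupled_series` with
#'   `cohort`: tibble `t, length, area` (area grows linearly, um^2);
#'   `beads`: tibble `bead_id, class (near/far), t, displacement` (um);
#'   `spec`.
#' @export
synthesize_coupled_series <- function(spec) {
  stopifnot(inherits(spec, "coupled_series_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  n <- length(t)
  len <- cohort_length_model(spec, t)
  # near beads respond to the cohort length `lag` samples earlier
  len_lagged <- cohort_length_model(spec, t - spec$lag * spec$dt)
  coupled <- spec$coupling_gain * len_lagged
  sd_far <- sqrt(var(coupled) + spec$noise_sigma^2)
  res <- withr::with_seed(spec$seed, {
    area <- 40 * len + rnorm(n, sd = 10)  # nominal 40-um-wide cohort
    near <- purrr::map(seq_len(spec$n_near), function(i) {
      tibble(bead_id = sprintf("near%02d", i), class = "near", t = t,
             displacement = coupled + rnorm(n, sd = spec$noise_sigma))
    })
    far <- purrr::map(seq_len(spec$n_far), function(i) {
      tibble(bead_id = sprintf("far%02d", i), class = "far", t = t,
             displacement = rnorm(n, sd = sd_far))
    })
    list(area = area, beads = bind_rows(bind_rows(near), bind_rows(far)))
  })
  structure(
    list(cohort = tibble(t = t, length = len, area = res$area),
         beads = res$beads, spec = spec),
    class = "coupled_series"
  )
}
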