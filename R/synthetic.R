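# Synthetic fixtures: parametric mixing curves and descriptor design tables
# with planted responses, so every downstream stage can be exercised without
# running DEM.

#' Generate a synthetic segregation-index mixing curve
#'
#' Exponential-in-revolutions decay toward the uniform-mixing asymptote:
#' `psi(t) = 1 + (psi0 - 1) * exp(-rate_k * rpm * t / 60) + N(0, noise_sd)`,
#' clipped to \[0, 2\]. Mixing progress is driven by the impeller revolution
#' count, so doubling the RPM halves every crossing time in seconds. The
#' analytic crossing time of any cutoff is attached as metadata.
#'
#' @param psi0 initial segregation index, in (1, 2]
#' @param rate_k decay constant per impeller revolution (> 0)
#' @param rpm impeller speed (revolutions/minute)
#' @param noise_sd Gaussian noise standard deviation (dimensionless, >= 0)
#' @param n_points number of samples
#' @param duration_s sampled time span (s); default covers 3 decay
#'   time-constants in revolutions
#' @param seed RNG seed for the noise
#' @param cutoff cutoff whose analytic crossing time is attached (default 1.1)
#' @return a `segregation_series` with attributes `analytic_t_end` (s),
#'   `analytic_rev_end` (revolutions) and `spec` (the generating parameters)
#' @export
generate_mixing_curve <- function(psi0 = 1.9, rate_k = 0.5, rpm = 30,
                                  noise_sd = 0, n_points = 200,
                                  duration_s = NULL, seed = 1L, cutoff = 1.1) {
  stopifnot(psi0 > 1, psi0 <= 2, rate_k > 0, noise_sd >= 0, n_points >= 2,
            rpm > 0)
  if (is.null(duration_s)) duration_s <- 3 / rate_k * 60 / rpm
  t <- seq(0, duration_s, length.out = n_points)
  rev <- rpm * t / 60
  psi <- 1 + (psi0 - 1) * exp(-rate_k * rev)
  if (noise_sd > 0)
    psi <- psi + with_local_seed(seed, rnorm(n_points, 0, noise_sd))
  psi <- pmin(pmax(psi, 0), 2)
  out <- data.frame(time = t, revolutions = rev, psi_bulk = psi)
  class(out) <- c("segregation_series", "data.frame")
  # closed-form crossing: rev_end = log((psi0-1)/(cutoff-1)) / rate_k
  rev_end <- if (cutoff >= psi0) 0 else log((psi0 - 1) / (cutoff - 1)) / rate_k
  attr(out, "analytic_rev_end") <- rev_end
  attr(out, "analytic_t_end") <- rev_end * 60 / rpm
  attr(out, "spec") <- list(psi0 = psi0, rate_k = rate_k, rpm = rpm,
                            noise_sd = noise_sd, n_points = n_points,
                            duration_s = duration_s, seed = seed,
                            cutoff = cutoff)
  out
}

#' Default descriptor ranges of the synthetic design space
#'
#' Desk-scale spans for the nine descriptors (SI units), mirroring the spread
#' of a realistic material/process design space: millimetre-scale particles,
#' pharmaceutical powder densities, soft-sphere moduli, hundreds to thousands
#' of particles and tens of RPM.
#'
#' @return named list of `c(min, max)` ranges
#' @export
default_design_ranges <- function() {
  list(particle_radius = c(1.5e-3, 4.5e-3),
       density = c(800, 1500),
       restitution = c(0.4, 0.9),
       cohesion = c(0, 1e5),
       friction = c(0.05, 0.5),
       youngs_modulus = c(5e6, 5e7),
       n_particles = c(500, 5000),
       rpm = c(10, 60),
       cake_height = c(0.02, 0.10))
}

scale01 <- function(x, rng) (x - rng[1]) / (rng[2] - rng[1])

planted_responses <- function() {
  list(
    # additive effects with planted importance ordering h >> RPM >> R;
    # the remaining six descriptors are inert
    ranking = function(Z) 60 + 24 * Z$cake_height + 12 * Z$rpm +
      6 * Z$particle_radius,
    # two-zone h x RPM interaction: deep cakes stirred slowly take a step
    # jump in mixing time (the bottom blade no longer turns the bed over) —
    # an axis-aligned non-additive surface that tree ensembles represent and
    # a linear model cannot
    interaction = function(Z) 30 +
      40 * (Z$cake_height > 0.5) * (Z$rpm < 0.5) + 4 * Z$particle_radius,
    # exactly linear in the h and RPM columns (recoverable by an elastic net)
    linear = function(Z) 10 + 20 * Z$cake_height + 8 * Z$rpm,
    # pure noise null
    noise = function(Z) rep(0, nrow(Z)))
}

#' Generate a synthetic descriptor design table with a planted response
#'
#' Latin-hypercube samples of the nine descriptors over `ranges`, with
#' `t_end_s` generated from a documented planted response plus Gaussian
#' noise. The planted effects are recorded in the `planted` attribute so
#' recovery tests can check against them.
#'
#' @param n_rows number of design rows
#' @param response one of `"ranking"` (additive effects, importance order
#'   cake_height > rpm > particle_radius, six inert descriptors),
#'   `"interaction"` (h x RPM interaction), `"linear"`, `"noise"`; or a
#'   function of the 0-1-scaled descriptor data.frame
#' @param noise_sd response noise standard deviation (s)
#' @param ranges named list of descriptor ranges; see [default_design_ranges()]
#' @param seed RNG seed
#' @return a `feature_table` with attribute `planted` describing the response
#' @export
synthetic_design_table <- function(n_rows = 40, response = "ranking",
                                   noise_sd = 1, ranges = default_design_ranges(),
                                   seed = 1L) {
  stopifnot(n_rows >= 10)
  nms <- descriptor_names()
  stopifnot(setequal(names(ranges), nms))
  with_local_seed(seed, {
    U <- lhs::randomLHS(n_rows, length(nms))
    colnames(U) <- nms
    tab <- as.data.frame(U)
    for (nm in nms) {
      rng <- ranges[[nm]]
      tab[[nm]] <- rng[1] + tab[[nm]] * (rng[2] - rng[1])
    }
    tab$n_particles <- round(tab$n_particles)
    Z <- as.data.frame(lapply(nms, function(nm) scale01(tab[[nm]], ranges[[nm]])))
    names(Z) <- nms
    fn <- if (is.function(response)) response else planted_responses()[[response]]
    if (is.null(fn)) stop("unknown planted response '", response, "'",
                          call. = FALSE)
    tab$t_end_s <- fn(Z) + rnorm(n_rows, 0, noise_sd)
    tab$provenance <- "synthetic"
    attr(tab, "planted") <- list(response = if (is.function(response)) "custom"
                                 else response, noise_sd = noise_sd,
                                 seed = seed)
    class(tab) <- c("feature_table", "data.frame")
    tab
  })
}
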