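#' Material and process parameters for one simulation
#'
#' The nine descriptors that define a single agitated-filter-dryer run: six
#' material properties (particle radius, density, coefficient of restitution,
#' cohesive energy density, tangential friction, Young's modulus) and three
#' process parameters (particle count, impeller speed, cake height). These are
#' also the nine feature columns of the surrogate stage.
#'
#' @param particle_radius particle radius R (m)
#' @param density particle density rho (kg/m^3)
#' @param restitution coefficient of restitution e, in (0, 1]
#' @param cohesion cohesive energy density gamma_cohesion (J/m^3); 0 disables
#'   cohesion
#' @param friction tangential (Coulomb) friction coefficient mu_f, >= 0
#' @param youngs_modulus Young's modulus E (N/m^2)
#' @param n_particles number of particles N_p
#' @param rpm impeller speed (revolutions per minute)
#' @param cake_height fill level h of the particle bed (m)
#' @return an object of class `material_process_params`
#' @export
material_process_params <- function(particle_radius = 3e-3,
                                    density = 1100,
                                    restitution = 0.6,
                                    cohesion = 1e4,
                                    friction = 0.1,
                                    youngs_modulus = 5e6,
                                    n_particles = 2000,
                                    rpm = 60,
                                    cake_height = 0.09) {
  p <- list(particle_radius = particle_radius, density = density,
            restitution = restitution, cohesion = cohesion, friction = friction,
            youngs_modulus = youngs_modulus, n_particles = as.integer(n_particles),
            rpm = rpm, cake_height = cake_height)
  pos <- c("particle_radius", "density", "youngs_modulus", "n_particles",
           "rpm", "cake_height")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
  }
  if (!is.finite(p$restitution) || p$restitution <= 0 || p$restitution > 1)
    stop("'restitution' must lie in (0, 1]", call. = FALSE)
  if (p$cohesion < 0) stop("'cohesion' must be >= 0", call. = FALSE)
  if (p$friction < 0) stop("'friction' must be >= 0", call. = FALSE)
  structure(p, class = "material_process_params")
}

#' Names of the nine material/process descriptors
#' @return character vector of feature-column names
#' @export
descriptor_names <- function() {
  c("particle_radius", "density", "restitution", "cohesion", "friction",
    "youngs_modulus", "n_particles", "rpm", "cake_height")
}

#' Vessel geometry: flat-bottomed cylinder with flat vertical blades
#'
#' A minimal agitated-filter-dryer abstraction: cylindrical vessel with a flat
#' floor and `blade_count` flat vertical blades spanning the radius, rotating
#' about the axis at the impeller speed.
#'
#' @param vessel_radius inner vessel radius (m)
#' @param blade_count number of blades (>= 1 for agitated runs; 0 for unbounded
#'   two-body experiments)
#' @param blade_height blade height above the floor (m)
#' @return an object of class `vessel_geometry`
#' @export
vessel_geometry <- function(vessel_radius = 0.05, blade_count = 2,
                            blade_height = 0.025) {
  if (is.finite(vessel_radius) && vessel_radius <= 0)
    stop("'vessel_radius' must be positive", call. = FALSE)
  if (blade_count < 0) stop("'blade_count' must be >= 0", call. = FALSE)
  structure(list(vessel_radius = vessel_radius,
                 blade_count = as.integer(blade_count),
                 blade_height = blade_height),
            class = "vessel_geometry")
}

#' Rayleigh critical time step
#'
#' Surface (Rayleigh) wave propagation time across a particle,
#' `pi * R * sqrt(rho/G) / (0.1631 nu + 0.8766)` with shear modulus
#' `G = E / (2 (1 + nu))`. Stable explicit DEM integration requires a time
#' step well below this.
#'
#' @param particle_radius particle radius (m)
#' @param density particle density (kg/m^3)
#' @param youngs_modulus Young's modulus (N/m^2)
#' @param poisson_ratio Poisson ratio
#' @return critical time (s)
#' @export
rayleigh_time <- function(particle_radius, density, youngs_modulus,
                          poisson_ratio = 0.3) {
  G <- youngs_modulus / (2 * (1 + poisson_ratio))
  pi * particle_radius * sqrt(density / G) / (0.1631 * poisson_ratio + 0.8766)
}

#' Contact-model parameters and integration settings
#'
#' Derives the numerical settings of the soft-sphere contact model from the
#' material parameters: the damping ratio `beta = ln e / sqrt(ln^2 e + pi^2)`
#' from the restitution coefficient, and a default time step of
#' `dt_safety` times the Rayleigh critical time.
#'
#' @param params a [material_process_params()] object
#' @param poisson_ratio Poisson ratio (dimensionless); walls share the particle
#'   material
#' @param dt integration time step (s); default `dt_safety * rayleigh_time(...)`
#' @param dt_safety safety fraction of the Rayleigh time used when `dt` is NULL
#' @param gravity gravitational acceleration (m/s^2, acting downward)
#' @return an object of class `contact_model_params`
#' @export
contact_model_params <- function(params, poisson_ratio = 0.3, dt = NULL,
                                 dt_safety = 0.2, gravity = 9.81) {
  stopifnot(inherits(params, "material_process_params"))
  t_crit <- rayleigh_time(params$particle_radius, params$density,
                          params$youngs_modulus, poisson_ratio)
  if (is.null(dt)) dt <- dt_safety * t_crit
  if (dt > t_crit)
    stop(sprintf("dt = %g s exceeds the Rayleigh critical time %g s", dt, t_crit),
         call. = FALSE)
  le <- log(params$restitution)
  beta <- if (params$restitution >= 1) 0 else le / sqrt(le^2 + pi^2)
  structure(list(poisson_ratio = poisson_ratio, dt = dt,
                 rayleigh_dt = t_crit, damping_beta = beta, gravity = gravity),
            class = "contact_model_params")
}

#' Particle mass from radius and density
#' @param particle_radius radius (m)
#' @param density density (kg/m^3)
#' @return sphere mass (kg)
#' @export
particle_mass <- function(particle_radius, density) {
  (4 / 3) * pi * particle_radius^3 * density
}

#' @exportS3Method base::print
print.material_process_params <- function(x, ...) {
  cat("Material/process parameters (9 descriptors):\n")
  cat(sprintf("  R = %g m, rho = %g kg/m^3, e = %g, gamma_coh = %g J/m^3\n",
              x$particle_radius, x$density, x$restitution, x$cohesion))
  cat(sprintf("  mu_f = %g, E = %g N/m^2, N_p = %d, RPM = %g, h = %g m\n",
              x$friction, x$youngs_modulus, x$n_particles, x$rpm, x$cake_height))
  invisible(x)
}

# run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
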