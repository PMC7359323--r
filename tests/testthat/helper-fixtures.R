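# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# hand-built snapshot from a position matrix
make_snapshot <- function(pos, labels, radius = 1, time = 0, rpm = 0,
                          vel = NULL, density = 1100) {
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  radius <- rep_len(radius, n)
  granumix:::new_snapshot(time, rpm, data.frame(
    id = seq_len(n), label = as.integer(labels),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
    wx = rep_len(0, n), wy = rep_len(0, n), wz = rep_len(0, n),
    radius = radius, mass = particle_mass(radius, density)))
}

desk_params <- function(n_particles = 400, ...) {
  material_process_params(n_particles = n_particles, ...)
}

# settled cohesionless-ish bed reused across metric tests
settled_bed_400 <- function() {
  fixture("bed400", function()
    initialize_bed(desk_params(400), vessel_geometry(), seed = 7))
}

# larger settled bed with >= 2000 contacts for the random-mixing null
settled_bed_1200 <- function() {
  fixture("bed1200", function()
    initialize_bed(desk_params(1200, cake_height = 0.08), vessel_geometry(),
                   seed = 11))
}

# mean psi over seeded random 50/50 relabelings of a fixed contact graph
psi_random_labeling_mean <- function(snapshot, n_rep = 200, seed = 1,
                                     tolerance = 1e-3) {
  pairs <- contact_pairs(snapshot, tolerance)
  n <- nrow(snapshot$particles)
  half <- rep(1:2, c(floor(n / 2), ceiling(n / 2)))
  granumix:::with_local_seed(seed, {
    mean(vapply(seq_len(n_rep), function(r) {
      lab <- sample(half)
      segregation_index(granumix:::census_from_pairs(lab, pairs))
    }, 0))
  })
}

# seeded ARMA simulation used by the forecast tests
sim_ar <- function(n, ar, seed, mean = 0, sd = 1) {
  granumix:::with_local_seed(seed,
    mean + as.numeric(arima.sim(list(ar = ar), n = n, sd = sd)))
}

# small tuning grids so Monte-Carlo surrogate suites stay fast
small_tune <- function() {
  list(rf = list(mtry = c(3, 9), depth = NA, ntree = 300),
       svr = list(cost = c(1, 10), gamma = c(NA, 0.1)),
       plsr = list(ncomp = 1:3),
       elastic_net = list(alpha = c(0.1, 0.9)))
}
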