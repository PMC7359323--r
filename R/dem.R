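# DEM driver: bed initialization, stepping, full runs, trajectory I/O.

new_snapshot <- function(time, rpm, particles) {
  structure(list(time = time, revolutions = rpm * time / 60,
                 particles = particles),
            class = "trajectory_snapshot")
}

#' @exportS3Method base::print
print.trajectory_snapshot <- function(x, ...) {
  cat(sprintf("DEM snapshot: t = %.4f s (%.2f rev), %d particles\n",
              x$time, x$revolutions, nrow(x$particles)))
  invisible(x)
}

state_matrices <- function(snapshot) {
  p <- snapshot$particles
  list(pos = cbind(p$x, p$y, p$z), vel = cbind(p$vx, p$vy, p$vz),
       omega = cbind(p$wx, p$wy, p$wz), radius = p$radius, mass = p$mass)
}

run_core <- function(snapshot, params, geometry, contact, nsteps, snap_every,
                     rpm = params$rpm) {
  s <- state_matrices(snapshot)
  .dem_run_cpp(s$pos, s$vel, s$omega, s$radius, s$mass,
               params$youngs_modulus, contact$poisson_ratio, params$restitution,
               params$friction, params$cohesion, geometry$vessel_radius,
               geometry$blade_count, geometry$blade_height, rpm, 0,
               contact$gravity, contact$dt, as.integer(nsteps),
               as.integer(snap_every), snapshot$time)
}

core_snapshot <- function(res, k, snapshot0, rpm) {
  st <- res$states[[k]]
  p <- snapshot0$particles
  p$x <- st$pos[, 1]; p$y <- st$pos[, 2]; p$z <- st$pos[, 3]
  p$vx <- st$vel[, 1]; p$vy <- st$vel[, 2]; p$vz <- st$vel[, 3]
  p$wx <- st$omega[, 1]; p$wy <- st$omega[, 2]; p$wz <- st$omega[, 3]
  new_snapshot(res$times[k], rpm, p)
}

#' Initialize a settled two-layer particle bed
#'
#' Places `N_p` particles on a jittered lattice inside the vessel, lets them
#' settle under gravity with the blade stationary, then labels the two vertical
#' half-beds: label 1 on the low-x side of the axis plane, label 2 on the
#' high-x side (the plane through the median x, so the label counts differ by
#' at most one). The returned snapshot is the t = 0 state of an agitation run.
#'
#' @param params a [material_process_params()] object
#' @param geometry a [vessel_geometry()] object
#' @param seed integer seed for the placement jitter
#' @param contact optional [contact_model_params()]; derived from `params` if NULL
#' @param settle_time settling pre-roll duration (s) with the blade stationary
#' @return a `trajectory_snapshot` at t = 0
#' @export
initialize_bed <- function(params, geometry, seed = 1L, contact = NULL,
                           settle_time = 0.4) {
  stopifnot(inherits(params, "material_process_params"),
            inherits(geometry, "vessel_geometry"))
  if (is.null(contact)) contact <- contact_model_params(params)
  R <- params$particle_radius
  Np <- params$n_particles
  if (geometry$vessel_radius <= R)
    stop("vessel_radius must exceed the particle radius", call. = FALSE)

  # lattice sites: square grid, spacing 2R*1.08, layered upward
  sp <- 2 * R * 1.08
  rmax <- geometry$vessel_radius - R * 1.05
  nxy <- floor(2 * rmax / sp)
  g1 <- (seq_len(nxy) - (nxy + 1) / 2) * sp
  xy <- expand.grid(x = g1, y = g1)
  xy <- xy[sqrt(xy$x^2 + xy$y^2) <= rmax, , drop = FALSE]
  n_layers_max <- floor((params$cake_height - R) / sp) + 1
  capacity <- nrow(xy) * max(0, n_layers_max)
  if (capacity < Np)
    stop(sprintf(paste0("infeasible packing: %d particles requested but only %d ",
                        "lattice sites fit below cake height %g m"),
                 Np, capacity, params$cake_height), call. = FALSE)
  n_layers <- ceiling(Np / nrow(xy))
  pos <- do.call(rbind, lapply(seq_len(n_layers), function(k) {
    cbind(xy$x, xy$y, R * 1.02 + (k - 1) * sp)
  }))[seq_len(Np), , drop = FALSE]
  jit <- with_local_seed(seed, matrix(runif(3 * Np, -0.04 * R, 0.04 * R), ncol = 3))
  pos <- pos + jit
  pos[, 3] <- pmax(pos[, 3], R * 1.001)

  m <- particle_mass(R, params$density)
  particles <- data.frame(id = seq_len(Np), label = 1L,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          vx = 0, vy = 0, vz = 0, wx = 0, wy = 0, wz = 0,
                          radius = R, mass = m)
  snap <- new_snapshot(0, params$rpm, particles)

  nsteps <- max(1L, ceiling(settle_time / contact$dt))
  res <- run_core(snap, params, geometry, contact, nsteps, nsteps, rpm = 0)
  if (!is.null(res$error)) stop(res$error, call. = FALSE)
  settled <- core_snapshot(res, length(res$states), snap, params$rpm)
  settled$time <- 0
  settled$revolutions <- 0

  # two vertical half-cylinder layers split at the axis plane (median x)
  ord <- order(settled$particles$x, settled$particles$id)
  lab <- integer(Np)
  lab[ord] <- rep(1:2, c(floor(Np / 2), ceiling(Np / 2)))
  settled$particles$label <- lab
  settled
}

#' Advance a DEM state by a number of time steps
#'
#' Velocity-Verlet integration of the soft-sphere contact model
#' (Hertzian normal force with nonlinear dashpot, Mindlin tangential spring
#' capped by the Coulomb limit, simplified-JKR cohesion) plus gravity and the
#' kinematic vessel/blade boundaries. The blade angle is a function of the
#' snapshot's absolute time, so repeated calls advance it continuously.
#'
#' @inheritParams initialize_bed
#' @param snapshot a `trajectory_snapshot`
#' @param contact a [contact_model_params()] object
#' @param n_steps number of `dt` steps to take
#' @return the advanced `trajectory_snapshot`
#' @export
dem_step <- function(snapshot, params, geometry, contact, n_steps = 1L) {
  res <- run_core(snapshot, params, geometry, contact, n_steps, n_steps)
  if (!is.null(res$error)) stop(res$error, call. = FALSE)
  core_snapshot(res, length(res$states), snapshot, params$rpm)
}

#' Run a DEM agitation simulation
#'
#' Initializes (or reuses) a settled two-layer bed and agitates it for
#' `duration_s` seconds at the impeller speed in `params`, recording snapshots
#' every `snapshot_interval_s`. The time step is rounded so that an integer
#' number of steps fits in each snapshot interval.
#'
#' @inheritParams initialize_bed
#' @param duration_s physical agitation time (s)
#' @param snapshot_interval_s interval between recorded snapshots (s)
#' @param init optional pre-built initial `trajectory_snapshot` (from
#'   [initialize_bed()]); built from `seed` when NULL
#' @param out_file optional CSV path; on an instability error the partial
#'   trajectory is flushed there before aborting
#' @param verbose print step count and wall-clock when TRUE
#' @return a `granumix_trajectory`: list of snapshots with the run parameters,
#'   per-snapshot energy series, step count and wall-clock time as attributes
#' @export
run_simulation <- function(params, geometry = vessel_geometry(), contact = NULL,
                           duration_s = 2, snapshot_interval_s = 0.02,
                           seed = 1L, init = NULL, settle_time = 0.4,
                           out_file = NULL, verbose = FALSE) {
  stopifnot(duration_s > 0, snapshot_interval_s > 0)
  if (is.null(contact)) contact <- contact_model_params(params)
  t_wall <- proc.time()[["elapsed"]]
  if (is.null(init))
    init <- initialize_bed(params, geometry, seed = seed, contact = contact,
                           settle_time = settle_time)
  snap_every <- max(1L, round(snapshot_interval_s / contact$dt))
  dt_adj <- snapshot_interval_s / snap_every
  contact$dt <- dt_adj
  n_int <- max(1L, round(duration_s / snapshot_interval_s))
  nsteps <- n_int * snap_every

  res <- run_core(init, params, geometry, contact, nsteps, snap_every)
  k <- res$n_recorded
  snaps <- lapply(seq_len(k), function(i) core_snapshot(res, i, init, params$rpm))
  energy <- data.frame(time = res$times[seq_len(k)], ke = res$ke[seq_len(k)],
                       pe = res$pe[seq_len(k)])
  traj <- structure(snaps, class = "granumix_trajectory",
                    params = params, geometry = geometry, contact = contact,
                    energy = energy, n_steps = res$n_steps, seed = seed,
                    wall_clock_s = proc.time()[["elapsed"]] - t_wall)
  if (!is.null(res$error)) {
    if (!is.null(out_file)) write_trajectory(traj, out_file)
    stop(res$error, call. = FALSE)
  }
  if (verbose)
    message(sprintf("DEM run: %d particles, %d steps (dt = %.3g s), %.1f s wall clock",
                    params$n_particles, res$n_steps, dt_adj,
                    attr(traj, "wall_clock_s")))
  if (!is.null(out_file)) write_trajectory(traj, out_file)
  traj
}

#' @exportS3Method base::print
print.granumix_trajectory <- function(x, ...) {
  cat(sprintf("DEM trajectory: %d snapshots, t in [%g, %g] s, %d particles\n",
              length(x), x[[1]]$time, x[[length(x)]]$time,
              nrow(x[[1]]$particles)))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per particle per snapshot with columns
#' `t, id, label, x, y, z, vx, vy, vz, radius`.
#'
#' @param traj a `granumix_trajectory` or list of snapshots
#' @param file output CSV path
#' @return `file`, invisibly
#' @export
write_trajectory <- function(traj, file) {
  rows <- do.call(rbind, lapply(traj, function(s) {
    p <- s$particles
    data.frame(t = s$time, id = p$id, label = p$label, x = p$x, y = p$y,
               z = p$z, vx = p$vx, vy = p$vy, vz = p$vz, radius = p$radius)
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param file CSV path
#' @param rpm impeller speed used to attach revolution counts
#' @param density particle density used to reconstruct masses (kg/m^3)
#' @return a `granumix_trajectory`
#' @export
read_trajectory <- function(file, rpm = 0, density = 1100) {
  d <- read.csv(file)
  need <- c("t", "id", "label", "x", "y", "z", "vx", "vy", "vz", "radius")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trajectory CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  snaps <- lapply(split(d, d$t), function(s) {
    s <- s[order(s$id), ]
    new_snapshot(s$t[1], rpm,
                 data.frame(id = s$id, label = s$label, x = s$x, y = s$y,
                            z = s$z, vx = s$vx, vy = s$vy, vz = s$vz,
                            wx = 0, wy = 0, wz = 0, radius = s$radius,
                            mass = particle_mass(s$radius, density)))
  })
  snaps <- snaps[order(as.numeric(names(snaps)))]
  structure(unname(snaps), class = "granumix_trajectory")
}

#' Read a LAMMPS/LIGGGHTS-style text dump
#'
#' Parses `ITEM: TIMESTEP` / `ITEM: ATOMS ...` blocks. Recognized atom columns
#' are `id`, `type` (mapped to label), `x y z`, `vx vy vz` and `radius`;
#' missing velocity or radius columns default to 0 and `default_radius`.
#'
#' @param file dump file path
#' @param dt physical time per dump timestep unit (s)
#' @param rpm impeller speed for revolution counts
#' @param default_radius radius used when the dump has no radius column (m)
#' @return a `granumix_trajectory`
#' @export
read_liggghts_dump <- function(file, dt = 1, rpm = 0, default_radius = 1e-3) {
  lines <- readLines(file)
  its <- grep("^ITEM: TIMESTEP", lines)
  if (!length(its)) stop("not a LAMMPS/LIGGGHTS dump: no ITEM: TIMESTEP found",
                         call. = FALSE)
  bounds <- c(its, length(lines) + 1L)
  snaps <- vector("list", length(its))
  for (k in seq_along(its)) {
    blk <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    step <- as.numeric(blk[2])
    ai <- grep("^ITEM: ATOMS", blk)
    if (!length(ai)) stop("dump block without ITEM: ATOMS header", call. = FALSE)
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", blk[ai]), "\\s+")[[1]]
    dat <- utils::read.table(text = paste(blk[(ai + 1):length(blk)],
                                          collapse = "\n"),
                             col.names = cols)
    get <- function(nm, default) if (nm %in% cols) dat[[nm]] else default
    n <- nrow(dat)
    p <- data.frame(id = get("id", seq_len(n)),
                    label = as.integer(get("type", rep(1L, n))),
                    x = get("x", 0), y = get("y", 0), z = get("z", 0),
                    vx = get("vx", 0), vy = get("vy", 0), vz = get("vz", 0),
                    wx = 0, wy = 0, wz = 0,
                    radius = get("radius", default_radius))
    p$mass <- particle_mass(p$radius, 1100)
    p <- p[order(p$id), ]
    snaps[[k]] <- new_snapshot(step * dt, rpm, p)
  }
  structure(snaps, class = "granumix_trajectory")
}

#' Per-snapshot mechanical energy of a trajectory
#'
#' @param traj a `granumix_trajectory` from [run_simulation()]
#' @return data.frame with columns `time`, `ke` (translational + rotational
#'   kinetic) and `pe` (gravitational potential)
#' @export
trajectory_energy <- function(traj) {
  e <- attr(traj, "energy")
  if (is.null(e)) stop("trajectory carries no energy record", call. = FALSE)
  e
}
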