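# DEM engine: initialization, contact physics oracles, conservation laws.

free_geom <- vessel_geometry(vessel_radius = Inf, blade_count = 0)

test_that("two-layer initialization splits labels evenly at the axis plane", {
  p <- desk_params(4, cake_height = 0.03)
  bed <- initialize_bed(p, vessel_geometry(), seed = 3)
  expect_equal(as.integer(table(bed$particles$label)), c(2L, 2L))
  # label 1 strictly on the low-x side of the split plane
  expect_lt(max(bed$particles$x[bed$particles$label == 1]),
            min(bed$particles$x[bed$particles$label == 2]))

  bed5 <- initialize_bed(desk_params(5, cake_height = 0.03),
                         vessel_geometry(), seed = 3)
  expect_lte(abs(diff(table(bed5$particles$label))), 1)
})

test_that("settled beds have bounded overlap and identical reruns", {
  bed <- settled_bed_400()
  pr <- contact_pairs(bed, 0)
  pos <- cbind(bed$particles$x, bed$particles$y, bed$particles$z)
  d <- sqrt(rowSums((pos[pr[, 1], , drop = FALSE] -
                       pos[pr[, 2], , drop = FALSE])^2))
  overlap <- 2 * bed$particles$radius[1] - d
  expect_lt(max(overlap), 0.01 * bed$particles$radius[1])

  again <- initialize_bed(desk_params(400), vessel_geometry(), seed = 7)
  expect_identical(bed$particles, again$particles)
})

test_that("an isolated particle follows ballistic free fall", {
  p <- desk_params(1)
  ct <- contact_model_params(p)
  s0 <- make_snapshot(matrix(c(0, 0, 1), 1), 1, radius = p$particle_radius)
  s1 <- dem_step(s0, p, free_geom, ct, n_steps = 250)
  expect_equal(s1$particles$vz, -ct$gravity * 250 * ct$dt, tolerance = 1e-12)
  expect_equal(s1$particles$vx, 0)
})

test_that("head-on two-body collision reproduces the restitution coefficient", {
  for (e_target in c(0.4, 0.6, 0.8)) {
    p <- material_process_params(restitution = e_target, cohesion = 0,
                                 friction = 0.2, n_particles = 2)
    ct <- contact_model_params(p, dt = 0.02 * rayleigh_time(
      p$particle_radius, p$density, p$youngs_modulus))
    ct$gravity <- 0
    R <- p$particle_radius
    s0 <- make_snapshot(rbind(c(-1.4 * R, 0, 0), c(1.4 * R, 0, 0)), c(1, 2),
                        radius = R, vel = rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
    s1 <- dem_step(s0, p, free_geom, ct, n_steps = 4000)
    e_meas <- abs(s1$particles$vx[1] - s1$particles$vx[2])  # pre-speed is 1
    expect_lt(abs(e_meas - e_target) / e_target, 0.05)
  }
})

test_that("momentum is conserved in an isolated collision", {
  p <- material_process_params(restitution = 0.6, cohesion = 0, friction = 0.3,
                               n_particles = 2)
  ct <- contact_model_params(p)
  ct$gravity <- 0
  R <- p$particle_radius
  s0 <- make_snapshot(rbind(c(-1.2 * R, 0, 0), c(1.2 * R, 1e-4, 0)), c(1, 2),
                      radius = R, vel = rbind(c(0.4, 0, 0), c(-0.4, 0, 0)))
  m <- s0$particles$mass
  p0 <- colSums(m * cbind(s0$particles$vx, s0$particles$vy, s0$particles$vz))
  s1 <- dem_step(s0, p, free_geom, ct, n_steps = 2000)
  p1 <- colSums(m * cbind(s1$particles$vx, s1$particles$vy, s1$particles$vz))
  expect_lt(max(abs(p1 - p0)) / (sum(m) * 0.4), 1e-10)
})

test_that("a particle resting on the floor sits at the Hertz equilibrium overlap", {
  p <- material_process_params(restitution = 0.5, cohesion = 0, friction = 0.2,
                               n_particles = 1)
  ct <- contact_model_params(p)
  R <- p$particle_radius
  m <- particle_mass(R, p$density)
  s0 <- make_snapshot(matrix(c(0, 0, R * 0.9999), 1), 1, radius = R)
  s1 <- dem_step(s0, p, vessel_geometry(blade_count = 0), ct, n_steps = 20000)
  delta_sim <- R - s1$particles$z
  # independent oracle: scalar root-find on the normal-force law
  Estar <- p$youngs_modulus / (2 * (1 - ct$poisson_ratio^2))
  f <- function(d) (4 / 3) * Estar * sqrt(R) * d^1.5 - m * ct$gravity
  delta_star <- uniroot(f, c(1e-12, R), tol = 1e-15)$root
  expect_lt(abs(delta_sim - delta_star) / delta_star, 0.01)
})

test_that("mechanical energy is dissipated with the blade at rest", {
  bed <- settled_bed_400()
  p <- desk_params(400, rpm = 1e-9)  # blade effectively stationary
  ct <- contact_model_params(p)
  # stir the settled bed, then let it relax with no agitation
  n <- nrow(bed$particles)
  vel <- granumix:::with_local_seed(5, matrix(rnorm(3 * n, 0, 0.3), n, 3))
  bed$particles$vx <- vel[, 1]; bed$particles$vy <- vel[, 2]
  bed$particles$vz <- vel[, 3]
  traj <- run_simulation(p, vessel_geometry(), ct, duration_s = 1.2,
                         snapshot_interval_s = 0.05, init = bed)
  en <- trajectory_energy(traj)
  expect_lt(en$ke[nrow(en)], 1e-6 * en$ke[1])
  total <- en$ke + en$pe
  # net dissipation over the whole relaxation
  expect_lt(total[length(total)], total[1])
  # non-increasing between snapshots once the bed has settled (while motion is
  # violent, KE + gravitational PE does not track the stored elastic energy)
  settled <- which(en$ke < 0.01 * en$ke[1])[1]
  tail_tot <- total[settled:length(total)]
  expect_true(all(diff(tail_tot) < 1e-6 * en$ke[1]))
})

test_that("strong cohesion holds touching particles together against an impulse", {
  p <- material_process_params(restitution = 0.6, cohesion = 1e5,
                               friction = 0.1, n_particles = 2)
  ct <- contact_model_params(p)
  ct$gravity <- 0
  R <- p$particle_radius
  s0 <- make_snapshot(rbind(c(-R * 0.999, 0, 0), c(R * 0.999, 0, 0)), c(1, 2),
                      radius = R, vel = rbind(c(-0.005, 0, 0), c(0.005, 0, 0)))
  s1 <- dem_step(s0, p, free_geom, ct, n_steps = 5000)
  gap <- sqrt(sum((c(s1$particles$x[2], s1$particles$y[2], s1$particles$z[2]) -
                     c(s1$particles$x[1], s1$particles$y[1], s1$particles$z[1]))^2))
  expect_lt(gap, 2 * R)  # still in contact
  # whereas without cohesion the same impulse separates them
  p0 <- material_process_params(restitution = 0.6, cohesion = 0,
                                friction = 0.1, n_particles = 2)
  s2 <- dem_step(s0, p0, free_geom, ct, n_steps = 5000)
  gap0 <- abs(s2$particles$x[2] - s2$particles$x[1])
  expect_gt(gap0, 2 * R)
})

test_that("runs count snapshots, conserve labels and stay inside the vessel", {
  p <- desk_params(60, cake_height = 0.03, rpm = 120)
  geom <- vessel_geometry()
  traj <- run_simulation(p, geom, duration_s = 0.5, snapshot_interval_s = 0.1,
                         seed = 2)
  expect_length(traj, 6)  # t = 0 included
  expect_equal(vapply(traj, function(s) s$time, 0), seq(0, 0.5, by = 0.1),
               tolerance = 1e-12)
  lab0 <- table(traj[[1]]$particles$label)
  for (s in traj) {
    expect_equal(table(s$particles$label), lab0)
    rad <- sqrt(s$particles$x^2 + s$particles$y^2)
    expect_true(all(rad < geom$vessel_radius))
  }
  # revolutions column = RPM * t / 60
  expect_equal(traj[[6]]$revolutions, 120 * 0.5 / 60)
})

test_that("identical seeds reproduce identical trajectories", {
  p <- desk_params(80, cake_height = 0.03)
  run_a <- run_simulation(p, vessel_geometry(), duration_s = 0.2,
                       snapshot_interval_s = 0.1, seed = 9)
  run_b <- run_simulation(p, vessel_geometry(), duration_s = 0.2,
                       snapshot_interval_s = 0.1, seed = 9)
  expect_identical(run_a[[3]]$particles, run_b[[3]]$particles)
})

test_that("a diverging integration raises an instability error naming dt", {
  p <- material_process_params(restitution = 1, cohesion = 0, friction = 0,
                               n_particles = 2)
  ct <- contact_model_params(p, dt_safety = 0.9)
  ct$gravity <- 0
  R <- p$particle_radius
  # closing speed crosses more than a radius per step: contacts unresolvable
  s0 <- make_snapshot(rbind(c(-2 * R, 0, 0), c(2 * R, 0, 0)), c(1, 2),
                      radius = R,
                      vel = rbind(c(10, 0, 0), c(-10, 0, 0)))
  expect_error(dem_step(s0, p, free_geom, ct, n_steps = 500),
               "instability.*dt")
})

test_that("trajectory CSV writer and reader round-trip", {
  p <- desk_params(30, cake_height = 0.03)
  traj <- run_simulation(p, vessel_geometry(), duration_s = 0.2,
                         snapshot_interval_s = 0.1, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f, rpm = p$rpm, density = p$density)
  expect_length(back, length(traj))
  expect_equal(back[[2]]$particles$x, traj[[2]]$particles$x)
  expect_equal(back[[2]]$particles$label, traj[[2]]$particles$label)
})

test_that("LIGGGHTS-style dumps are parsed", {
  txt <- c("ITEM: TIMESTEP", "0", "ITEM: NUMBER OF ATOMS", "2",
           "ITEM: BOX BOUNDS pp pp pp", "0 1", "0 1", "0 1",
           "ITEM: ATOMS id type x y z vx vy vz radius",
           "2 2 0.1 0.2 0.3 0 0 0 0.003",
           "1 1 0.0 0.0 0.003 0.1 0 0 0.003",
           "ITEM: TIMESTEP", "100", "ITEM: NUMBER OF ATOMS", "2",
           "ITEM: BOX BOUNDS pp pp pp", "0 1", "0 1", "0 1",
           "ITEM: ATOMS id type x y z vx vy vz radius",
           "1 1 0.01 0.0 0.003 0.1 0 0 0.003",
           "2 2 0.1 0.2 0.3 0 0 0 0.003")
  f <- withr::local_tempfile(fileext = ".dump")
  writeLines(txt, f)
  traj <- read_liggghts_dump(f, dt = 1e-3)
  expect_length(traj, 2)
  expect_equal(traj[[2]]$time, 0.1)
  expect_equal(traj[[1]]$particles$label, c(1L, 2L))  # sorted by id
  expect_equal(traj[[1]]$particles$x, c(0.0, 0.1))
  expect_error(read_liggghts_dump(f2 <- withr::local_tempfile(lines = "x")),
               "TIMESTEP")
})
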