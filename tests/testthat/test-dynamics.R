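test_that("Stokes drag is linear in slip velocity and diameter", {
  expect_equal(stokes_drag(1.9e-5, 1e-6, c(0, 0)), c(0, 0))
  f <- stokes_drag(1.9e-5, 1e-6, c(1e-3, 0))
  expect_equal(f[1], 3 * pi * 1.9e-5 * 1e-6 * 1e-3, tolerance = 1e-12)
  expect_equal(f[1], 1.79e-13, tolerance = 0.01)
  expect_equal(f[2], 0)
  expect_equal(stokes_drag(1.9e-5, 2e-6, c(1e-3, 0)), 2 * f, tolerance = 1e-12)
})

test_that("Brownian force has the closed-form per-step amplitude", {
  expect_equal(brownian_force(1.9e-5, 0, 1e-7, 1e-4, zeta = c(1, 1))[1, ],
               c(0, 0))
  expect_equal(brownian_force(1.9e-5, 310.15, 1e-7, 1e-4, zeta = c(0, 0))[1, ],
               c(0, 0))
  amp <- sqrt(6 * pi * 1.380649e-23 * 1.9e-5 * 310.15 * 1e-7 / 1e-4)
  expect_equal(amp, 3.92e-14, tolerance = 0.01)
  set.seed(42)
  draws <- brownian_force(1.9e-5, 310.15, 1e-7, 1e-4, n = 1e5)
  expect_equal(sd(draws[, 1]), amp, tolerance = 0.02)
  expect_equal(mean(draws[, 1]), 0, tolerance = 3 * amp / sqrt(1e5))
  expect_error(brownian_force(1.9e-5, 310, 1e-7, -1), "dt")
})

test_that("buoyant weight and settling velocity follow the force balance", {
  p900 <- particle_properties(900e-9, 1180)
  air <- air_properties(); water <- media_properties()
  # neutral buoyancy
  expect_equal(buoyant_weight(particle_properties(1e-6, 1000), 1000), c(0, 0))
  expect_equal(settling_velocity(particle_properties(1e-6, 1000), water), 0)
  # direct evaluation, gravity down with zero streamwise component
  fw <- buoyant_weight(p900, 1.123)
  expect_equal(fw[1], 0)
  expect_equal(fw[2], -p900$mp * (1 - 1.123 / 1180) * 9.81, tolerance = 1e-12)
  # vacuum limit
  expect_equal(buoyant_weight(p900, 0)[2], -p900$mp * 9.81, tolerance = 1e-12)
  # closed forms
  expect_equal(settling_velocity(p900, air), 2.7e-5, tolerance = 0.02)
  expect_equal(settling_velocity(particle_properties(1e-6, 2200), water),
               9.1e-7, tolerance = 0.02)
  # aqueous vs aerosol buoyant-weight ratio for the density 1180 tracer
  ratio <- (1 - 1000 / 1180) / (1 - 1.123 / 1180)
  expect_equal(ratio, 0.153, tolerance = 0.01)
  expect_equal(buoyant_weight(p900, 1000)[2] / buoyant_weight(p900, 1.123)[2],
               ratio, tolerance = 1e-12)
})

test_that("the inertial step solves the linear drag ODE to machine precision", {
  part <- particle_properties(10e-6, 1470)   # tau large enough to matter
  fluid <- media_properties()
  tau <- relaxation_time(part, fluid)
  U <- c(3e-4, 0); up0 <- c(0, 0)
  dt <- tau / 3
  pos <- c(0, 0); vel <- up0
  for (k in 1:30) {
    st <- step_particle(pos, vel, U, part, fluid, dt, mode = "inertial")
    pos <- st$pos; vel <- st$vel
  }
  t_end <- 30 * dt
  expect_equal(vel, U + (up0 - U) * exp(-t_end / tau), tolerance = 1e-12)
  # exact position of the exponential relaxation
  pos_exact <- U * t_end + tau * (up0 - U) * (1 - exp(-t_end / tau))
  expect_equal(pos, pos_exact, tolerance = 1e-12)
})

test_that("gravity-only kinematics match the closed forms in both modes", {
  part <- particle_properties(900e-9, 1180)
  air <- air_properties()
  vs <- settling_velocity(part, air)
  tau <- relaxation_time(part, air)
  fld <- field_quiescent()
  y0 <- fld$domain$y_mem_top + fld$domain$geometry$h_air / 2
  T_run <- 1
  run1 <- function(mode) {
    cfg <- sim_config(u_air_inlet = 0, u_media_inlet = 0, n_particles = 1,
                      dt = 1e-3, seed = 3, brownian = FALSE,
                      integrator = mode, max_time = T_run)
    run_tracing(fld, part, cfg, injection = list(y0 = y0, y1 = y0))
  }
  r_od <- run1("overdamped")
  expect_equal(y0 - r_od$y, vs * T_run, tolerance = 1e-9)
  r_in <- run1("inertial")
  fall_exact <- vs * (T_run - tau * (1 - exp(-T_run / tau)))
  expect_equal(y0 - r_in$y, fall_exact, tolerance = 1e-9)
})

test_that("passive tracers follow streamlines in plane Poiseuille flow", {
  fld <- channel_field("100 um", "15 mm", "0.3 mm/s", profile = "parabolic")
  part <- particle_properties(500e-9)
  cfg <- sim_config(n_particles = 20, dt = 0.01, seed = 5, brownian = FALSE,
                    gravity = FALSE, max_time = 5)
  res <- run_tracing(fld, part, cfg)
  y0 <- fld$domain$y_mem_top +
    c(0.2, 0.5, 0.8) * fld$domain$geometry$h_air
  res2 <- run_tracing(fld, part, cfg, injection = list(y0 = y0[2], y1 = y0[2]))
  expect_equal(res2$y, rep(y0[2], 20), tolerance = 1e-12)
  expect_true(all(res2$x > 0))
  # all particles remain active or exit through the air outlet only
  expect_true(all(res$status %in% c("active_air", "exited_air")))
})

test_that("tracing is bit-reproducible and scheduling-independent", {
  fld <- field_small_p()
  part <- particle_properties(200e-9)
  cfg <- sim_config(n_particles = 50, seed = 11, max_time = 20)
  r1 <- run_tracing(fld, part, cfg)
  r2 <- run_tracing(fld, part, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # a particle's trajectory does not depend on the ensemble size
  cfg1 <- sim_config(n_particles = 10, seed = 11, max_time = 20)
  r3 <- run_tracing(fld, part, cfg1)
  for (col in c("status", "x", "y", "t", "t_transfer", "t_exit", "x_deposit")) {
    expect_identical(r1[[col]][1:10], r3[[col]])
  }
  # and differs under another seed
  cfg2 <- sim_config(n_particles = 50, seed = 12, max_time = 20)
  expect_false(identical(r1$y, run_tracing(fld, part, cfg2)$y))
})

test_that("particle fates always partition the released ensemble", {
  fld <- field_small_p()
  for (cfg in list(
    sim_config(n_particles = 40, seed = 2, max_time = 10),
    sim_config(n_particles = 40, seed = 2, brownian = FALSE, max_time = 10),
    sim_config(n_particles = 40, seed = 2, gravity = FALSE, max_time = 2),
    sim_config(n_particles = 40, seed = 2, integrator = "inertial", max_time = 10)
  )) {
    res <- run_tracing(fld, particle_properties(300e-9), cfg)
    fs <- fate_summary(res)
    expect_equal(sum(fs$n), 40)
    expect_equal(sum(fs$fraction), 1, tolerance = 1e-12)
    # transfer bookkeeping is consistent with fates
    expect_equal(sum(!is.na(res$t_transfer)),
                 sum(res$status %in% c("active_media", "exited_media")))
  }
})

test_that("boundary resolution honours the sticky/pass-through/reflect contract", {
  dom <- build_domain(geom_small_p())
  ymt <- dom$y_mem_top; ymb <- dom$y_mem_bot
  pore1 <- dom$pores[1, ]                      # [0, 10 um] at the default tiling
  solid_x <- pore1$x1 + 2e-6                   # over the first sticky segment

  # sticky: proposed position below the membrane top over solid -> deposited
  hit <- apply_boundaries(dom, solid_x, ymt + 2e-6, solid_x, ymt - 2e-6)
  expect_equal(hit$status, "deposited")
  expect_equal(hit$y, ymt)
  expect_equal(hit$x_deposit, solid_x, tolerance = 1e-12)

  # pass-through: proposed position inside a pore slot -> still active
  mid_pore <- (pore1$x0 + pore1$x1) / 2
  thr <- apply_boundaries(dom, mid_pore, ymt + 2e-6, mid_pore, ymt - 2e-6)
  expect_equal(thr$status, "active_air")
  expect_false(thr$transferred)

  # full crossing into the media channel flags the transfer
  tr <- apply_boundaries(dom, mid_pore, ymt + 1e-6, mid_pore, ymb - 2e-6)
  expect_equal(tr$status, "active_media")
  expect_true(tr$transferred)

  # ceiling reflection keeps the particle active at the mirrored position
  y_top <- dom$y_top
  rf <- apply_boundaries(dom, 1e-4, y_top - 1e-6, 1e-4, y_top + 3e-6)
  expect_equal(rf$status, "active_air")
  expect_equal(rf$y, y_top - 3e-6, tolerance = 1e-12)

  # media outlet crossing records the interpolated exit height
  ex <- apply_boundaries(dom, dom$geometry$l - 1e-6, 5e-5,
                         dom$geometry$l + 1e-6, 5.2e-5, status = "active_media")
  expect_equal(ex$status, "exited_media")
  expect_equal(ex$y_exit, 5.1e-5, tolerance = 1e-9)

  # membrane underside reflects media-phase particles (one-way transfer)
  un <- apply_boundaries(dom, mid_pore, ymb - 1e-6, mid_pore, ymb + 1e-6,
                         status = "active_media")
  expect_equal(un$status, "active_media")
  expect_equal(un$y, ymb - 1e-6, tolerance = 1e-12)
})

test_that("Brownian-only ensembles diffuse at the Stokes-Einstein rate", {
  fld <- field_quiescent()
  part <- particle_properties(100e-9)
  D <- particle_diffusivity(part, air_properties())
  T_run <- 0.05
  y0 <- fld$domain$y_mem_top + fld$domain$geometry$h_air / 2
  cfg <- sim_config(u_air_inlet = 0, u_media_inlet = 0, n_particles = 1e4,
                    dt = 1e-3, seed = 21, gravity = FALSE, max_time = T_run)
  res <- run_tracing(fld, part, cfg, injection = list(x = 2.5e-4, y0 = y0, y1 = y0))
  msd_x <- mean((res$x - 2.5e-4)^2)
  msd_y <- mean((res$y - y0)^2)
  expect_equal(msd_x, 2 * D * T_run, tolerance = 0.05)
  expect_equal(msd_y, 2 * D * T_run, tolerance = 0.05)
})

test_that("absorbing-floor kinetics match a finite-difference diffusion oracle", {
  fld <- field_quiescent()
  dom <- fld$domain
  part <- particle_properties(100e-9)
  D <- particle_diffusivity(part, air_properties())
  h <- dom$geometry$h_air
  y0_rel <- 0.5
  T_run <- 5
  cfg <- sim_config(u_air_inlet = 0, u_media_inlet = 0, n_particles = 2000,
                    dt = 5e-3, seed = 31, gravity = FALSE, max_time = T_run)
  res <- run_tracing(fld, part, cfg,
                     injection = list(x = 2.5e-4,
                                      y0 = dom$y_mem_top + y0_rel * h,
                                      y1 = dom$y_mem_top + y0_rel * h))
  p_mc <- deposition_rate(res)
  p_fd <- fd_absorbed_fraction(D, h, y0_rel * h, T_run)
  se <- sqrt(p_fd * (1 - p_fd) / 2000)
  # sampling error plus the O(sqrt(D dt)) first-passage bias of the walk
  expect_lt(abs(p_mc - p_fd), 3 * se + 0.02)
})

test_that("inertial and overdamped integrators agree for submicron particles", {
  fld <- field_small_p()
  part <- particle_properties(900e-9)
  n <- 400
  run_mode <- function(mode) {
    cfg <- sim_config(n_particles = n, seed = 17, integrator = mode,
                      max_time = 60)
    res <- run_tracing(fld, part, cfg)
    c(deposition_rate(res), transfer_rate(res))
  }
  od <- run_mode("overdamped"); iv <- run_mode("inertial")
  for (k in 1:2) {
    se <- sqrt(od[k] * (1 - od[k]) / n + iv[k] * (1 - iv[k]) / n)
    expect_lt(abs(od[k] - iv[k]), 4 * se + 0.01)
  }
})

test_that("suggested time steps resolve the finest boundary feature", {
  fld <- field_small_p()
  part <- particle_properties(10e-9)
  cfg <- sim_config()
  dt <- suggest_dt(fld, part, cfg)
  L <- min(fld$domain$geometry$d, fld$domain$geometry$b) / 4
  umax <- max(max(abs(fld$u)), max(abs(fld$v))) +
    settling_velocity(part, air_properties())
  D <- particle_diffusivity(part, air_properties())
  expect_lte(umax * dt, L * (1 + 1e-9))
  expect_lte(sqrt(2 * D * dt), L * (1 + 1e-9))
})
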