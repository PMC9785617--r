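# Particle force models and the Lagrangian tracer front end.
#
# The equation of motion balances Stokes drag, Brownian forcing and buoyant
# weight: mp dup/dt = Fd + Fb + mp (1 - rho_i/rho_p) g. For submicron
# particles the relaxation time tau = rho_p dp^2/(18 mu) is <= 1e-7 s, far
# below any resolvable time step, so the default integrator is the overdamped
# limit; the inertial (exponential) integrator is retained for validation and
# for >1 um particles.

#' Stokes drag force
#'
#' `F = 3 pi mu dp (u_fluid - u_particle)`, the creeping-flow drag on a
#' sphere; valid while the particle Reynolds number stays well below 1.
#'
#' @param mu Fluid dynamic viscosity (Pa.s).
#' @param dp Particle diameter (m).
#' @param u_rel Relative velocity vector `u_fluid - u_particle` (m/s),
#'   length-2 numeric.
#' @return Force vector (N), parallel to `u_rel`.
#' @export
stokes_drag <- function(mu, dp, u_rel) {
  .check_pos(mu, "mu"); .check_pos(dp, "dp")
  3 * pi * mu * dp * u_rel
}

#' Brownian force samples
#'
#' Per-step stochastic force `F = zeta * sqrt(6 pi kB mu T dp / dt)` with
#' `zeta` standard normal; each component has variance
#' `6 pi kB mu T dp / dt` over the draw distribution. Driving the Stokes-drag
#' equation with this force reproduces Stokes-Einstein diffusion
#' `D = kB T / (3 pi mu dp)` in the overdamped limit.
#'
#' @param mu Viscosity (Pa.s).
#' @param T Temperature (K).
#' @param dp Particle diameter (m).
#' @param dt Time step (s).
#' @param zeta Optional matrix/vector of standard-normal draws; sampled with
#'   [stats::rnorm()] when omitted.
#' @param n Number of force vectors to draw when `zeta` is missing.
#' @return An `n` x 2 matrix of force components (N).
#' @export
brownian_force <- function(mu, T, dp, dt, zeta = NULL, n = 1) {
  .check_pos(mu, "mu"); .check_pos(dp, "dp")
  if (!is.numeric(T) || T < 0) abort("`T` must be >= 0.")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0.")
  if (is.null(zeta)) zeta <- matrix(rnorm(2 * n), ncol = 2)
  zeta <- matrix(zeta, ncol = 2)
  zeta * sqrt(6 * pi * .kB * mu * T * dp / dt)
}

#' Buoyant weight of a particle
#'
#' Net gravity force `mp (1 - rho_fluid/rho_p) g`, directed along `-y`.
#'
#' @param particle A [particle_properties()] object.
#' @param rho_fluid Carrier fluid density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @return Length-2 force vector (N), zero streamwise component.
#' @export
buoyant_weight <- function(particle, rho_fluid, g = 9.81) {
  stopifnot(inherits(particle, "lc_particle"))
  c(0, -particle$mp * (1 - rho_fluid / particle$rho_p) * g)
}

#' Terminal settling velocity
#'
#' Stationary balance of Stokes drag and buoyant weight:
#' `v_s = (rho_p - rho_fluid) g dp^2 / (18 mu)`.
#'
#' @param particle A [particle_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @param g Gravitational acceleration (m/s^2).
#' @return Settling speed (m/s), positive downward.
#' @export
settling_velocity <- function(particle, fluid, g = 9.81) {
  stopifnot(inherits(particle, "lc_particle"), inherits(fluid, "lc_fluid"))
  (particle$rho_p - fluid$rho) * g * particle$dp^2 / (18 * fluid$mu)
}

#' Stokes relaxation time
#'
#' `tau = rho_p dp^2 / (18 mu)`: the e-folding time of the particle velocity
#' toward the local fluid velocity.
#'
#' @param particle A [particle_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @return Relaxation time (s).
#' @export
relaxation_time <- function(particle, fluid) {
  stopifnot(inherits(particle, "lc_particle"), inherits(fluid, "lc_fluid"))
  particle$rho_p * particle$dp^2 / (18 * fluid$mu)
}

#' Stokes-Einstein diffusivity
#'
#' @param particle A [particle_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @return Diffusion coefficient `kB T / (3 pi mu dp)` (m^2/s).
#' @export
particle_diffusivity <- function(particle, fluid) {
  stopifnot(inherits(particle, "lc_particle"), inherits(fluid, "lc_fluid"))
  .kB * fluid$T / (3 * pi * fluid$mu * particle$dp)
}

#' Single unconstrained integration step (reference implementation)
#'
#' Advances one particle through one time step in a uniform fluid velocity,
#' without boundary handling — the analytic reference for the integrators:
#' the inertial mode applies the exact exponential solution of the linear
#' drag ODE, the overdamped mode the position-Langevin update.
#'
#' @param pos,vel Length-2 position (m) and particle velocity (m/s).
#' @param u_fluid Length-2 fluid velocity (m/s).
#' @param particle A [particle_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @param dt Time step (s).
#' @param mode `"inertial"` or `"overdamped"`.
#' @param zeta Length-2 standard-normal draw for the Brownian kick (0 = off).
#' @param gravity,g Gravity switch and magnitude.
#' @return List with `pos` and `vel` after `dt`.
#' @export
step_particle <- function(pos, vel, u_fluid, particle, fluid, dt,
                          mode = c("inertial", "overdamped"),
                          zeta = c(0, 0), gravity = FALSE, g = 9.81) {
  stopifnot(inherits(particle, "lc_particle"), inherits(fluid, "lc_fluid"))
  mode <- match.arg(mode)
  .check_pos(dt, "dt")
  ag <- c(0, if (gravity) -(1 - fluid$rho / particle$rho_p) * g else 0)
  if (mode == "inertial") {
    tau <- relaxation_time(particle, fluid)
    Famp <- sqrt(6 * pi * .kB * fluid$mu * fluid$T * particle$dp / dt)
    ab <- Famp * zeta / particle$mp
    Ustar <- u_fluid + tau * (ab + ag)
    e <- exp(-dt / tau)
    list(pos = pos + Ustar * dt + tau * (vel - Ustar) * (1 - e),
         vel = Ustar + (vel - Ustar) * e)
  } else {
    D <- particle_diffusivity(particle, fluid)
    vs <- settling_velocity(particle, fluid, g)
    drift <- u_fluid + c(0, if (gravity) -vs else 0)
    list(pos = pos + drift * dt + sqrt(2 * D * dt) * zeta,
         vel = drift)
  }
}

#' Resolve a proposed particle displacement against the device boundaries
#'
#' Applies the boundary contract to the segment from the current to the
#' proposed position: the membrane top is sticky (deposition), pore mouths
#' pass particles through (the carrier phase switches to media on exiting a
#' slot into the bottom channel), the channel outlets terminate particles,
#' and every other wall reflects specularly.
#'
#' @param domain A [build_domain()] result.
#' @param x0,y0 Current position (m).
#' @param x1,y1 Proposed position (m).
#' @param status Current status string.
#' @return A one-row tibble with the resolved position, status and any event
#'   records (`x_deposit`, `y_exit`, `transferred`).
#' @export
apply_boundaries <- function(domain, x0, y0, x1, y1, status = "active_air") {
  stopifnot(inherits(domain, "lc_domain"))
  codes <- c(active_air = 1L, active_media = 2L, deposited = 3L,
             exited_air = 4L, exited_media = 5L)
  if (!status %in% names(codes)) abort("Unknown particle status.")
  reg <- .region_of(domain, x0, y0)
  if (reg == "solid") abort("Particle starts inside the solid membrane.")
  region <- c(air = 0L, pore = 1L, media = 2L)[[reg]]
  pores <- domain$pores
  pitch <- if (nrow(pores) > 0) domain$geometry$d + domain$geometry$p2p else 1
  pore_k <- if (reg == "pore") {
    as.integer(floor((x0 - domain$geometry$porous_x0) / pitch))
  } else -1L
  out <- apply_boundaries_cpp(x0, y0, x1, y1, codes[[status]], region, pore_k,
                              domain$geometry$l, domain$y_mem_bot,
                              domain$y_mem_top, domain$y_top,
                              domain$geometry$porous_x0, pitch,
                              domain$geometry$d, nrow(pores))
  tibble(x = out$x, y = out$y,
         status = names(codes)[out$status],
         x_deposit = out$x_deposit, y_exit = out$y_exit,
         transferred = out$transferred)
}

#' Suggest a stable tracing time step
#'
#' Chooses `dt` so that both the advective sub-step (peak fluid speed plus
#' settling) and the r.m.s. Brownian sub-step stay below a quarter of the
#' smallest boundary feature (pore width and membrane thickness; a tenth of
#' the channel height for an impermeable membrane).
#'
#' @param field An [solve_flow()] result.
#' @param particle A [particle_properties()] object.
#' @param config An [sim_config()] object.
#' @return Time step (s).
#' @export
suggest_dt <- function(field, particle, config) {
  stopifnot(inherits(field, "lc_flow"), inherits(particle, "lc_particle"))
  geom <- field$domain$geometry
  L <- if (geom$d > 0) min(geom$d, geom$b) / 4 else min(geom$h_air, geom$h_media) / 10
  vs <- if (config$gravity) {
    max(abs(settling_velocity(particle, field$fluid_top, config$g)),
        abs(settling_velocity(particle, field$fluid_bottom, config$g)))
  } else 0
  umax <- max(max(abs(field$u)), max(abs(field$v))) + vs
  Dmax <- if (config$brownian) {
    max(particle_diffusivity(particle, field$fluid_top),
        particle_diffusivity(particle, field$fluid_bottom))
  } else 0
  dt_adv <- if (umax > 0) L / umax else Inf
  dt_dif <- if (Dmax > 0) L^2 / (2 * Dmax) else Inf
  dt <- min(dt_adv, dt_dif, config$max_time / 10)
  if (!is.finite(dt)) dt <- config$max_time / 1000
  dt
}

#' Trace an ensemble of particles through the device
#'
#' Releases `n_particles` at the air-channel inlet (uniformly over the inlet
#' height by default), integrates each trajectory under drag, Brownian
#' forcing and buoyant weight through the pre-computed flow field, and
#' resolves boundary events until every particle reaches a terminal fate or
#' `max_time` elapses. Each particle consumes its own counter-based RNG
#' stream derived from `config$seed`, so the result is bit-reproducible and
#' independent of scheduling order.
#'
#' @param field An [solve_flow()] or [channel_field()] result.
#' @param particle A [particle_properties()] object.
#' @param config An [sim_config()] object.
#' @param injection Optional override list with elements `x`, `y0`, `y1`
#'   (release segment, m); defaults to the air inlet span or its midpoint
#'   per `config$injection`.
#' @param n_bands If positive, accumulate air-channel residence time in
#'   `n_bands` equal streamwise bands (for concentration profiles).
#' @param traj_stride If positive, record trajectories every `traj_stride`
#'   steps for up to `traj_max` particles.
#' @param traj_max Maximum number of recorded trajectories.
#' @return An `lc_result`: a tibble with one row per particle (`id`,
#'   `status`, final `x`, `y`, `t`, `t_transfer`, `t_exit`, `y_exit`,
#'   `x_deposit`) carrying attributes `n_released`, `dt`, `incomplete`,
#'   `band_occupancy` and `trajectory`.
#' @export
run_tracing <- function(field, particle, config, injection = NULL,
                        n_bands = 0, traj_stride = 0, traj_max = 20) {
  stopifnot(inherits(field, "lc_flow"), inherits(particle, "lc_particle"),
            inherits(config, "lc_config"))
  domain <- field$domain
  dt <- config$dt %||% suggest_dt(field, particle, config)
  margin <- min(domain$dy, domain$geometry$h_air) * 1e-6
  inj <- list(
    x = 0,
    y0 = if (config$injection == "midline") {
      domain$y_mem_top + domain$geometry$h_air / 2
    } else domain$y_mem_top + margin,
    y1 = if (config$injection == "midline") {
      domain$y_mem_top + domain$geometry$h_air / 2
    } else domain$y_top - margin
  )
  if (!is.null(injection)) inj <- modifyList(inj, injection)

  pores <- domain$pores
  pitch <- if (nrow(pores) > 0) domain$geometry$d + domain$geometry$p2p else 1

  raw <- trace_particles_cpp(
    field$u_pad, field$v_pad, field$dx, field$dy, field$nx, field$ny,
    domain$geometry$l, domain$y_mem_bot, domain$y_mem_top, domain$y_top,
    domain$geometry$porous_x0, pitch, domain$geometry$d, nrow(pores),
    c(field$fluid_top$rho, field$fluid_bottom$rho),
    c(field$fluid_top$mu, field$fluid_bottom$mu),
    c(field$fluid_top$T, field$fluid_bottom$T),
    particle$dp, particle$rho_p,
    config$n_particles, dt, as.double(config$seed), config$g,
    as.integer(config$integrator == "inertial"),
    as.integer(config$brownian), as.integer(config$gravity),
    as.integer(config$drag), config$max_time,
    inj$x, inj$y0, inj$y1,
    as.integer(config$init_velocity == "fluid"),
    as.integer(n_bands), as.integer(traj_stride), as.integer(traj_max)
  )

  lv <- c("active_air", "active_media", "deposited", "exited_air", "exited_media")
  res <- tibble(
    id = seq_len(config$n_particles),
    status = factor(lv[raw$status], levels = lv),
    x = raw$x, y = raw$y, t = raw$t,
    t_transfer = raw$t_transfer, t_exit = raw$t_exit,
    y_exit = raw$y_exit, x_deposit = raw$x_deposit
  )
  attr(res, "n_released") <- config$n_particles
  attr(res, "dt") <- dt
  attr(res, "incomplete") <- sum(raw$status <= 2L)
  attr(res, "band_occupancy") <- if (n_bands > 0) raw$band_occupancy else NULL
  attr(res, "trajectory") <- if (traj_stride > 0) {
    tibble(id = raw$trajectory[, 1], t = raw$trajectory[, 2],
           x = raw$trajectory[, 3], y = raw$trajectory[, 4])
  } else NULL
  attr(res, "particle") <- particle
  attr(res, "geometry") <- domain$geometry
  attr(res, "config") <- config
  class(res) <- c("lc_result", class(res))
  res
}
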