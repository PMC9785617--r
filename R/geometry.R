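#' Dual-channel device geometry
#'
#' Describes the simulated device: an air channel stacked on top of a
#' cell-culture media channel, separated by a thin membrane perforated by
#' vertical pore slots. The coordinate system puts `y = 0` at the media-channel
#' floor; the membrane occupies `y` in `[h_media, h_media + b]` and the air
#' channel sits above it. Gravity acts along `-y`, i.e. from the air channel
#' toward the media channel.
#'
#' Pores tile the perforated extent `[porous_x0, porous_x1]` left to right with
#' period `d + p2p`, starting at `porous_x0`; `p2p` is the edge-to-edge spacing
#' between neighbouring pores. In this 2D model a pore is a through-slot of
#' width `d` spanning the membrane thickness, the planar analogue of a
#' cylindrical pore. `d = 0` encodes an impermeable membrane.
#'
#' @param h_air,h_media Channel heights (m, or unit string such as `"100 um"`).
#' @param l Channel length (m).
#' @param b Membrane thickness (m).
#' @param d Pore slot width (m); `0` for an impermeable membrane.
#' @param p2p Pore-to-pore edge spacing (m); ignored when `d = 0`.
#' @param porous_x0,porous_x1 Streamwise extent of the perforated region (m);
#'   defaults to the full channel overlap `[0, l]`.
#' @param depth Optional out-of-plane channel depth (m) enabling the
#'   shallow-channel drag term in the flow solve; `NULL` means unbounded depth.
#' @return An object of class `lc_geometry`.
#' @examples
#' geom <- channel_geometry()            # device defaults
#' geom0 <- channel_geometry(d = 0)      # impermeable membrane
#' @export
channel_geometry <- function(h_air = "100 um", h_media = "100 um",
                             l = "2 mm", b = "10 um",
                             d = "10 um", p2p = "10 um",
                             porous_x0 = 0, porous_x1 = NULL,
                             depth = NULL) {
  g <- list(
    h_air = .q(h_air, "h_air"), h_media = .q(h_media, "h_media"),
    l = .q(l, "l"), b = .q(b, "b"),
    d = .q(d, "d"), p2p = .q(p2p, "p2p"),
    porous_x0 = .q(porous_x0, "porous_x0"),
    porous_x1 = if (is.null(porous_x1)) .q(l, "l") else .q(porous_x1, "porous_x1"),
    depth = if (is.null(depth)) NULL else .q(depth, "depth")
  )
  for (f in c("h_air", "h_media", "l", "b")) .check_pos(g[[f]], f)
  .check_pos(g$d, "d", strict = FALSE)
  if (g$d > 0) .check_pos(g$p2p, "p2p")
  .check_pos(g$porous_x0, "porous_x0", strict = FALSE)
  if (!is.null(g$depth)) .check_pos(g$depth, "depth")
  if (g$porous_x0 >= g$porous_x1 || g$porous_x1 > g$l) {
    abort("Perforated extent must satisfy porous_x0 < porous_x1 <= l.")
  }
  if (g$d > 0) {
    w <- g$porous_x1 - g$porous_x0
    if (floor((w + g$p2p) / (g$d + g$p2p)) < 1) {
      abort("No full pore fits in [porous_x0, porous_x1]; widen the region or shrink d.")
    }
  }
  structure(g, class = "lc_geometry")
}

#' @export
print.lc_geometry <- function(x, ...) {
  cat("<lc_geometry>\n")
  cat(sprintf("  air %g um / membrane %g um / media %g um, length %g mm\n",
              x$h_air * 1e6, x$b * 1e6, x$h_media * 1e6, x$l * 1e3))
  if (x$d > 0) {
    cat(sprintf("  pores: d = %g um, p-p = %g um over [%g, %g] mm (%d pores)\n",
                x$d * 1e6, x$p2p * 1e6, x$porous_x0 * 1e3, x$porous_x1 * 1e3,
                nrow(pore_intervals(x))))
  } else {
    cat("  impermeable membrane (d = 0)\n")
  }
  invisible(x)
}

#' Fluid phase properties
#'
#' @param rho Density (kg/m^3).
#' @param mu Dynamic viscosity (Pa.s).
#' @param T Temperature (K); defaults to 310.15 K (37 degC).
#' @param R Specific gas constant (J/(kg K)); gases only, used in the Knudsen
#'   check.
#' @param sigma Molecular collision diameter (m); gases only.
#' @param label Free-text phase label.
#' @return An object of class `lc_fluid`.
#' @export
fluid_properties <- function(rho, mu, T = .T_default, R = NULL, sigma = NULL,
                             label = "fluid") {
  f <- list(rho = .q(rho, "rho"), mu = .q(mu, "mu"), T = .q(T, "T"),
            R = if (is.null(R)) NULL else .q(R, "R"),
            sigma = if (is.null(sigma)) NULL else .q(sigma, "sigma"),
            label = label)
  for (nm in c("rho", "mu", "T")) .check_pos(f[[nm]], nm)
  if (!is.null(f$R)) .check_pos(f$R, "R")
  if (!is.null(f$sigma)) .check_pos(f$sigma, "sigma")
  structure(f, class = "lc_fluid")
}

#' Air at 37 degC
#'
#' Density 1.123 kg/m^3, viscosity 0.019 mPa.s, specific gas constant
#' ~290 J/(kg K) and hard-sphere collision diameter 346 pm.
#' @param ... Overrides passed to [fluid_properties()].
#' @export
air_properties <- function(...) {
  defaults <- list(rho = 1.123, mu = 0.019e-3, T = .T_default,
                   R = 290, sigma = 346e-12, label = "air")
  do.call(fluid_properties, modifyList(defaults, list(...)))
}

#' Cell-culture media at 37 degC (water-like)
#'
#' Density 1000 kg/m^3, viscosity 0.718 mPa.s.
#' @param ... Overrides passed to [fluid_properties()].
#' @export
media_properties <- function(...) {
  defaults <- list(rho = 1000, mu = 0.718e-3, T = .T_default, label = "media")
  do.call(fluid_properties, modifyList(defaults, list(...)))
}

#' Spherical particle properties
#'
#' @param dp Particle diameter (m).
#' @param rho_p Particle material density (kg/m^3); default 1180 kg/m^3
#'   (polystyrene-like tracer).
#' @return An object of class `lc_particle` with derived mass `mp` (kg).
#' @export
particle_properties <- function(dp, rho_p = 1180) {
  p <- list(dp = .q(dp, "dp"), rho_p = .q(rho_p, "rho_p"))
  .check_pos(p$dp, "dp"); .check_pos(p$rho_p, "rho_p")
  p$mp <- p$rho_p * pi * p$dp^3 / 6
  structure(p, class = "lc_particle")
}

#' Simulation run settings
#'
#' @param u_air_inlet,u_media_inlet Inlet velocities (m/s or unit strings).
#' @param n_particles Number of released particles.
#' @param dt Time step (s); `NULL` lets the tracer pick a step that resolves
#'   the pore width (advective and Brownian sub-steps at most a quarter of the
#'   smallest boundary feature).
#' @param seed Master RNG seed; every particle derives an independent
#'   counter-based stream from it, so results do not depend on scheduling.
#' @param g Gravitational acceleration magnitude (m/s^2), directed along `-y`.
#' @param integrator `"overdamped"` (default, position Langevin) or
#'   `"inertial"` (exact exponential update of the linear-drag velocity ODE).
#' @param brownian,gravity,drag Force switches.
#' @param max_time Wall-clock simulation horizon (s); particles still active
#'   at `max_time` are flagged incomplete.
#' @param injection `"uniform"` releases particles uniformly over the inlet
#'   height, `"midline"` releases a thin bolus at mid-height (the entrance
#'   bolus of the bench experiment).
#' @param init_velocity `"fluid"` starts particles at the local fluid
#'   velocity; `"zero"` starts them at rest (initially inert).
#' @param inlet_profile `"uniform"` (plug) or `"parabolic"` (fully developed)
#'   inlet condition for the flow solve.
#' @return An object of class `lc_config`.
#' @export
sim_config <- function(u_air_inlet = "0.3 mm/s", u_media_inlet = "0.3 mm/s",
                       n_particles = 1000, dt = NULL, seed = 1L,
                       g = 9.81,
                       integrator = c("overdamped", "inertial"),
                       brownian = TRUE, gravity = TRUE, drag = TRUE,
                       max_time = 120,
                       injection = c("uniform", "midline"),
                       init_velocity = c("fluid", "zero"),
                       inlet_profile = c("uniform", "parabolic")) {
  cfg <- list(
    u_air_inlet = .q(u_air_inlet, "u_air_inlet"),
    u_media_inlet = .q(u_media_inlet, "u_media_inlet"),
    n_particles = as.integer(n_particles),
    dt = if (is.null(dt)) NULL else .q(dt, "dt"),
    seed = as.integer(seed),
    g = .q(g, "g"),
    integrator = match.arg(integrator),
    brownian = isTRUE(brownian), gravity = isTRUE(gravity), drag = isTRUE(drag),
    max_time = .q(max_time, "max_time"),
    injection = match.arg(injection),
    init_velocity = match.arg(init_velocity),
    inlet_profile = match.arg(inlet_profile)
  )
  if (cfg$n_particles < 1L) abort("`n_particles` must be >= 1.")
  if (!is.null(cfg$dt)) .check_pos(cfg$dt, "dt")
  .check_pos(cfg$u_air_inlet, "u_air_inlet", strict = FALSE)
  .check_pos(cfg$u_media_inlet, "u_media_inlet", strict = FALSE)
  .check_pos(cfg$g, "g", strict = FALSE)
  .check_pos(cfg$max_time, "max_time")
  structure(cfg, class = "lc_config")
}

#' Channel Knudsen number (hard-sphere collision model)
#'
#' Ratio of the gas mean free path to twice the channel height,
#' `Kn = kB / (sqrt(2) pi sigma^2 rho R 2h)`. Values below 0.01 justify the
#' continuum, no-slip treatment of the airflow.
#'
#' @param air An [air_properties()] object with `sigma` and `R` set.
#' @param h Channel height (m).
#' @return Dimensionless Knudsen number.
#' @examples
#' knudsen_number(air_properties(), 100e-6)  # ~4e-4
#' @export
knudsen_number <- function(air, h) {
  stopifnot(inherits(air, "lc_fluid"))
  if (is.null(air$sigma)) abort("`sigma` (collision diameter) missing from fluid.")
  if (is.null(air$R)) abort("`R` (specific gas constant) missing from fluid.")
  h <- .q(h, "h"); .check_pos(h, "h")
  .kB / (sqrt(2) * pi * air$sigma^2 * air$rho * air$R * 2 * h)
}

#' Flow/particle regime report
#'
#' Computes the dimensionless numbers that justify the model assumptions:
#' particle Reynolds number `Re_p = rho u dp / mu`, Stokes relaxation time
#' `tau = rho_p dp^2 / (18 mu)`, Stokes number `tau u / h`, and (for gases)
#' the Knudsen number. Flags are raised when `Re_p >= 1` (Stokes drag
#' questionable) or `Kn >= 0.01` (continuum hypothesis questionable).
#'
#' @param fluid An [fluid_properties()] object.
#' @param particle A [particle_properties()] object.
#' @param u_ref Reference velocity (m/s).
#' @param geom A [channel_geometry()]; `h_air` is the reference length.
#' @return A one-row tibble.
#' @export
validate_regime <- function(fluid, particle, u_ref, geom) {
  stopifnot(inherits(fluid, "lc_fluid"), inherits(particle, "lc_particle"),
            inherits(geom, "lc_geometry"))
  u_ref <- .q(u_ref, "u_ref")
  re_p <- fluid$rho * u_ref * particle$dp / fluid$mu
  tau <- relaxation_time(particle, fluid)
  stk <- tau * u_ref / geom$h_air
  kn <- if (!is.null(fluid$sigma) && !is.null(fluid$R)) {
    knudsen_number(fluid, geom$h_air)
  } else NA_real_
  tibble(
    re_p = re_p, tau = tau, stokes_number = stk, knudsen = kn,
    flag_re = re_p >= 1,
    flag_kn = !is.na(kn) && kn >= 0.01
  )
}

#' Pore slot intervals
#'
#' Streamwise `[x0, x1]` intervals of the membrane pore slots implied by the
#' tiling convention (period `d + p2p` starting at `porous_x0`).
#'
#' @param geom A [channel_geometry()].
#' @return A tibble with columns `pore`, `x0`, `x1`; zero rows when `d = 0`.
#' @export
pore_intervals <- function(geom) {
  stopifnot(inherits(geom, "lc_geometry"))
  if (geom$d <= 0) return(tibble(pore = integer(), x0 = numeric(), x1 = numeric()))
  w <- geom$porous_x1 - geom$porous_x0
  n <- floor((w + geom$p2p) / (geom$d + geom$p2p))
  x0 <- geom$porous_x0 + (seq_len(n) - 1) * (geom$d + geom$p2p)
  tibble(pore = seq_len(n), x0 = x0, x1 = x0 + geom$d)
}

#' Discretize the device into a 2D simulation domain
#'
#' Builds the uniform staggered-grid representation of the connected
#' two-channel region: every grid cell is classified as exactly one of
#' `solid`, `air`, `media` or `pore`, and the membrane-top line is split into
#' sticky (deposition) segments and pass-through pore mouths.
#'
#' The grid is uniform; the cell size defaults to one sixth of the pore width
#' (or of the membrane thickness when `d = 0`) so that each pore is resolved
#' by at least six cells. Channel heights and membrane thickness must be
#' commensurate with the cell size.
#'
#' @param geom A [channel_geometry()].
#' @param cell Optional cell size (m); default `d/6` (or `b/6` if `d = 0`).
#' @return An object of class `lc_domain`: grid spacings, cell classification
#'   matrix, exact membrane/pore segment tables, and the parent geometry.
#' @export
build_domain <- function(geom, cell = NULL) {
  stopifnot(inherits(geom, "lc_geometry"))
  base <- if (geom$d > 0) geom$d else geom$b
  cell <- if (is.null(cell)) base / 6 else .q(cell, "cell")
  .check_pos(cell, "cell")

  nx <- max(4L, as.integer(round(geom$l / cell)))
  dx <- geom$l / nx
  # vertical layering must align with cell faces
  n_med <- as.integer(round(geom$h_media / cell))
  n_b <- max(1L, as.integer(round(geom$b / cell)))
  n_air <- as.integer(round(geom$h_air / cell))
  dy <- cell
  if (abs(n_med * dy - geom$h_media) > 1e-9 * geom$h_media ||
      abs(n_b * dy - geom$b) > 1e-9 * geom$b ||
      abs(n_air * dy - geom$h_air) > 1e-9 * geom$h_air) {
    abort(paste0("Grid cell size ", format(cell), " m does not divide the channel ",
                 "heights and membrane thickness; choose a commensurate `cell`."))
  }
  ny <- n_med + n_b + n_air
  y_mem_bot <- geom$h_media
  y_mem_top <- geom$h_media + geom$b
  y_top <- y_mem_top + geom$h_air

  pores <- pore_intervals(geom)
  if (nrow(pores) > 0 && any(pores$x1 > geom$porous_x1 + 1e-12)) {
    abort("Pore tiling extends beyond the perforated region.")
  }

  # classification by cell center
  xc <- (seq_len(nx) - 0.5) * dx
  cls <- matrix(0L, nx, ny) # 0 solid
  cls[, seq_len(n_med)] <- 2L # media
  cls[, n_med + n_b + seq_len(n_air)] <- 1L # air
  if (nrow(pores) > 0) {
    in_pore <- rep(FALSE, nx)
    for (k in seq_len(nrow(pores))) {
      in_pore <- in_pore | (xc > pores$x0[k] & xc < pores$x1[k])
    }
    cls[in_pore, n_med + seq_len(n_b)] <- 3L # pore slots
  }

  # exact membrane-top partition: sticky segments are the complement of the
  # pore mouths within [porous_x0, porous_x1]; outside the perforated region
  # the membrane top is also sticky (it is the air-channel floor).
  if (nrow(pores) > 0) {
    cuts <- sort(unique(c(0, geom$l, pores$x0, pores$x1)))
    seg <- tibble(x0 = head(cuts, -1), x1 = tail(cuts, -1))
    is_pore <- purrr::map_lgl(seq_len(nrow(seg)), function(i) {
      mid <- (seg$x0[i] + seg$x1[i]) / 2
      any(mid > pores$x0 & mid < pores$x1)
    })
    sticky <- seg[!is_pore, ]
  } else {
    sticky <- tibble(x0 = 0, x1 = geom$l)
  }

  structure(list(
    geometry = geom, nx = nx, ny = ny, dx = dx, dy = dy,
    n_media = n_med, n_mem = n_b, n_air = n_air,
    y_mem_bot = y_mem_bot, y_mem_top = y_mem_top, y_top = y_top,
    cls = cls, pores = pores, sticky = sticky
  ), class = "lc_domain")
}

#' @export
print.lc_domain <- function(x, ...) {
  cat(sprintf("<lc_domain> %d x %d cells (dx = %.3g um), %d pores, %d sticky segments\n",
              x$nx, x$ny, x$dx * 1e6, nrow(x$pores), nrow(x$sticky)))
  invisible(x)
}
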