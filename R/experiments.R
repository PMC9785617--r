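# Case drivers: end-to-end pipeline (flow solve -> tracing -> metrics),
# parametric sweeps over particle diameter / membrane porosity / inlet
# velocity, and the limiting-case verification suite.

.pkg_flow_cache <- new.env(parent = emptyenv())

#' Create (or clear) a flow-field cache
#'
#' Flow solves are cached per (geometry, fluids, inlet velocities, options)
#' so that sweeps over particle properties reuse the same field.
#'
#' @return An empty cache environment.
#' @export
flow_cache <- function() new.env(parent = emptyenv())

#' @rdname flow_cache
#' @export
clear_flow_cache <- function() {
  rm(list = ls(.pkg_flow_cache), envir = .pkg_flow_cache)
  invisible(NULL)
}

.flow_key <- function(geometry, fluid_top, fluid_bottom, u_top, u_bot,
                      inlet_profile, shallow_depth, cell, pore_flow) {
  hash(list(unclass(geometry), fluid_top$rho, fluid_top$mu, fluid_top$T,
            fluid_bottom$rho, fluid_bottom$mu, fluid_bottom$T,
            u_top, u_bot, inlet_profile, shallow_depth, cell, pore_flow))
}

#' Solve (or fetch) the flow field for a case
#'
#' @inheritParams solve_flow
#' @param geometry A [channel_geometry()].
#' @param cell Optional grid cell size forwarded to [build_domain()].
#' @param pore_flow Pore-flow model forwarded to [solve_flow()].
#' @param cache Cache environment from [flow_cache()]; `NULL` disables
#'   caching.
#' @return An `lc_flow`.
#' @export
cached_flow <- function(geometry, fluid_top = air_properties(),
                        fluid_bottom = media_properties(),
                        u_top_inlet = "0.3 mm/s", u_bottom_inlet = "0.3 mm/s",
                        inlet_profile = "uniform", shallow_depth = NULL,
                        pore_flow = "closed",
                        cell = NULL, cache = .pkg_flow_cache) {
  u_top <- .q(u_top_inlet, "u_top_inlet"); u_bot <- .q(u_bottom_inlet, "u_bottom_inlet")
  key <- .flow_key(geometry, fluid_top, fluid_bottom, u_top, u_bot,
                   inlet_profile, shallow_depth, cell, pore_flow)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  domain <- build_domain(geometry, cell = cell)
  field <- solve_flow(domain, fluid_top, fluid_bottom, u_top, u_bot,
                      shallow_depth = shallow_depth,
                      inlet_profile = inlet_profile, pore_flow = pore_flow)
  if (!is.null(cache)) cache[[key]] <- field
  field
}

#' Run one complete simulation case
#'
#' Solves (or reuses) the flow field, traces the particle ensemble and
#' summarizes every transport metric in one tibble row. Deterministic for a
#' fixed `config$seed`.
#'
#' @param particle A [particle_properties()] object.
#' @param config An [sim_config()] object; its `u_air_inlet`/`u_media_inlet`
#'   drive the flow solve.
#' @param geometry A [channel_geometry()].
#' @param fluid_top,fluid_bottom Phase properties (pass media properties as
#'   `fluid_top` for aqueous injection).
#' @param cell Optional grid cell size.
#' @param cache Flow cache environment (`NULL` disables).
#' @return A one-row tibble (class `lc_case`): resolved parameters, rates,
#'   distribution statistics, concentration-peak parameters and binomial
#'   standard errors.
#' @export
run_case <- function(particle, config = sim_config(),
                     geometry = channel_geometry(),
                     fluid_top = air_properties(),
                     fluid_bottom = media_properties(),
                     cell = NULL, cache = .pkg_flow_cache) {
  t0 <- proc.time()[["elapsed"]]
  field <- cached_flow(geometry, fluid_top, fluid_bottom,
                       config$u_air_inlet, config$u_media_inlet,
                       inlet_profile = config$inlet_profile,
                       shallow_depth = geometry$depth,
                       cell = cell, cache = cache)
  res <- run_tracing(field, particle, config)
  n <- attr(res, "n_released")
  eps <- deposition_rate(res)
  tr <- transfer_rate(res)
  dd <- deposit_distribution(res)
  od <- outlet_distribution(res)
  n_exit <- sum(!is.na(res$t_exit))
  cv <- if (n_exit >= 5) concentration_time(res) else NULL
  se_bin <- function(p) sqrt(p * (1 - p) / n)
  out <- tibble(
    dp = particle$dp, rho_p = particle$rho_p,
    d = geometry$d, p2p = geometry$p2p,
    pore_fraction = if (geometry$d > 0) geometry$d / (geometry$d + geometry$p2p) else 0,
    u_air = config$u_air_inlet, u_media = config$u_media_inlet,
    injection_phase = fluid_top$label,
    n_particles = n, seed = config$seed,
    deposition_rate = eps, transfer_rate = tr,
    exited_air = sum(res$status == "exited_air") / n,
    incomplete = attr(res, "incomplete") / n,
    dep_mean = dd$mean_norm, dep_std = dd$std_norm,
    out_mean = od$mean_norm, out_std = od$std_norm,
    cmax = if (!is.null(cv)) cv$cmax else NA_real_,
    tmax = if (!is.null(cv)) cv$tmax else NA_real_,
    se_deposition = se_bin(eps), se_transfer = se_bin(tr),
    runtime_s = proc.time()[["elapsed"]] - t0
  )
  class(out) <- c("lc_case", class(out))
  out
}

#' Aqueous-injection counterpart of a case
#'
#' Same pipeline with the top channel carrying media-phase fluid: nanoparticles
#' suspended in liquid rather than aerosolized. Enables the aerosol-vs-aqueous
#' comparison of deposition and translocation efficiency.
#'
#' @inheritParams run_case
#' @return A one-row tibble as [run_case()].
#' @export
media_injection_case <- function(particle, config = sim_config(),
                                 geometry = channel_geometry(),
                                 cell = NULL, cache = .pkg_flow_cache) {
  run_case(particle, config, geometry,
           fluid_top = media_properties(), fluid_bottom = media_properties(),
           cell = cell, cache = cache)
}

#' Define a parameter sweep
#'
#' @param dp Particle diameters (m or unit strings).
#' @param pores A data frame with columns `d` and `p2p` (m), one row per
#'   membrane configuration.
#' @param u_inlet Inlet velocities (m/s or unit strings), applied to both
#'   channels.
#' @param replicates Independent seeds per case.
#' @param rho_p Particle density (kg/m^3).
#' @param config Base [sim_config()].
#' @param geometry Base [channel_geometry()]; `d`/`p2p` are overridden per
#'   pore configuration.
#' @return A `lc_sweep_spec` list.
#' @export
sweep_spec <- function(dp, pores = tibble(d = 10e-6, p2p = 10e-6),
                       u_inlet = "0.3 mm/s", replicates = 1,
                       rho_p = 1180, config = sim_config(),
                       geometry = channel_geometry()) {
  dp <- vapply(dp, .q, numeric(1), what = "dp")
  u <- vapply(u_inlet, .q, numeric(1), what = "u_inlet")
  pores <- as_tibble(pores)
  if (!all(c("d", "p2p") %in% names(pores)) || nrow(pores) < 1) {
    abort("`pores` needs columns `d` and `p2p` with at least one row.")
  }
  if (length(dp) < 1 || length(u) < 1 || replicates < 1) {
    abort("Sweep axes must be non-empty and `replicates` >= 1.")
  }
  structure(list(dp = dp, pores = pores, u = u,
                 replicates = as.integer(replicates),
                 rho_p = .q(rho_p, "rho_p"), config = config,
                 geometry = geometry),
            class = "lc_sweep_spec")
}

# deterministic, order-independent per-case seed below 2^31
.case_seed <- function(base_seed, pars) {
  h <- hash(c(list(base = base_seed), pars))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Run a parameter sweep
#'
#' Executes the Cartesian product of diameters, pore configurations, inlet
#' velocities and replicate seeds. Flow fields are cached per (geometry,
#' velocity); per-case seeds are derived from the case parameters, so results
#' are independent of execution order. With `checkpoint_dir` set, completed
#' cases are written to per-case CSV files and skipped on re-run.
#'
#' @param spec A [sweep_spec()].
#' @param checkpoint_dir Optional directory for resumable execution.
#' @param cache Flow cache environment.
#' @return A tibble with one row per case x replicate (class `lc_sweep`).
#' @export
parameter_sweep <- function(spec, checkpoint_dir = NULL, cache = .pkg_flow_cache) {
  stopifnot(inherits(spec, "lc_sweep_spec"))
  grid <- tidyr::expand_grid(
    dp = spec$dp,
    pore = seq_len(nrow(spec$pores)),
    u = spec$u,
    replicate = seq_len(spec$replicates)
  )
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  rows <- purrr::pmap(grid, function(dp, pore, u, replicate) {
    d <- spec$pores$d[pore]; p2p <- spec$pores$p2p[pore]
    pars <- list(dp = dp, d = d, p2p = p2p, u = u, rep = replicate)
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0("case-", hash(pars), ".csv"))
    } else NULL
    if (!is.null(ck) && file.exists(ck)) {
      return(as_tibble(read.csv(ck)))
    }
    geom <- channel_geometry(
      h_air = spec$geometry$h_air, h_media = spec$geometry$h_media,
      l = spec$geometry$l, b = spec$geometry$b, d = d, p2p = p2p,
      porous_x0 = spec$geometry$porous_x0, porous_x1 = spec$geometry$porous_x1,
      depth = spec$geometry$depth)
    cfg <- spec$config
    cfg$u_air_inlet <- u; cfg$u_media_inlet <- u
    cfg$seed <- .case_seed(spec$config$seed, pars)
    out <- tryCatch(
      dplyr::mutate(
        run_case(particle_properties(dp, spec$rho_p), cfg, geom, cache = cache),
        replicate = replicate, error = NA_character_),
      error = function(e) {
        tibble(dp = dp, d = d, p2p = p2p, u_air = u, replicate = replicate,
               error = conditionMessage(e))
      })
    if (!is.null(ck)) write.csv(out, ck, row.names = FALSE)
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lc_sweep", class(out))
  out
}

#' Aggregate sweep replicates
#'
#' One row per case with replicate means; standard errors come from the
#' replicate spread when `replicates > 1` and from the binomial formula
#' otherwise.
#'
#' @param sweep A [parameter_sweep()] result.
#' @return A tibble, one row per (dp, d, p2p, u_air).
#' @export
summarize_sweep <- function(sweep) {
  sweep |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$dp, .data$d, .data$p2p, .data$u_air) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      se_deposition = if (dplyr::n() > 1) {
        sd(.data$deposition_rate) / sqrt(dplyr::n())
      } else .data$se_deposition[1],
      se_transfer = if (dplyr::n() > 1) {
        sd(.data$transfer_rate) / sqrt(dplyr::n())
      } else .data$se_transfer[1],
      deposition_rate = mean(.data$deposition_rate),
      transfer_rate = mean(.data$transfer_rate),
      exited_air = mean(.data$exited_air),
      cmax = mean(.data$cmax), tmax = mean(.data$tmax),
      .groups = "drop"
    )
}

#' Plot deposition/transfer rates of a sweep against particle diameter
#'
#' @param object An `lc_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lc_sweep <- function(object, ...) {
  df <- object |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(c("deposition_rate", "transfer_rate"),
                        names_to = "metric", values_to = "rate") |>
    dplyr::mutate(case = sprintf("d=%g um, p-p=%g um, u=%g mm/s",
                                 .data$d * 1e6, .data$p2p * 1e6, .data$u_air * 1e3))
  ggplot2::ggplot(df, ggplot2::aes(.data$dp * 1e9, .data$rate,
                                   colour = .data$case, linetype = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "particle diameter (nm)", y = "rate (fraction)")
}

#' Limiting-case verification suite
#'
#' Runs the impermeable-membrane verification battery:
#' (a) the numerical cross-channel profile against the analytic
#' parallel-plate solution; (b) band-averaged concentration decay of a
#' diffusing ensemble along a channel at a Peclet number scaled so the decay
#' completes within the channel, with full mass accounting; (c) independence
#' of the deposition rate from the out-of-plane depth when the shallow-channel
#' drag is enabled; (d) the bench-experiment twins: settling of 1 um / 2200
#' kg/m3 and 10 um / 1470 kg/m3 particles in water, checking the wash-out,
#' entrance-concentrated and spread-deposition regimes.
#'
#' @param n_particles Ensemble size per check.
#' @param seed Master seed.
#' @return A tibble with one row per check (`check`, `metric`, `value`,
#'   `criterion`, `pass`).
#' @export
verification_suite <- function(n_particles = 500, seed = 1) {
  checks <- list()
  add <- function(check, metric, value, criterion, pass) {
    checks[[length(checks) + 1]] <<- tibble(
      check = check, metric = metric, value = value,
      criterion = criterion, pass = pass)
  }

  # (a) plane-Poiseuille profile, impermeable membrane
  geom_a <- channel_geometry(l = "0.5 mm", d = 0)
  dom_a <- build_domain(geom_a)
  fl_a <- solve_flow(dom_a, u_top_inlet = "0.3 mm/s", u_bottom_inlet = "0.3 mm/s")
  x_st <- 0.8 * geom_a$l
  yq <- dom_a$y_mem_top + seq(0.05, 0.95, by = 0.05) * geom_a$h_air
  prof <- sample_velocity(fl_a, rep(x_st, length(yq)), yq)
  ana <- poiseuille_profile(3e-4, geom_a$h_air, yq - dom_a$y_mem_top)
  err_a <- max(abs(prof$u - ana)) / max(ana)
  add("poiseuille", "max relative profile error", err_a, "< 0.01", err_a < 0.01)

  # (b) band-concentration decay at a channel-scaled Peclet number
  h_b <- 1e-3; l_b <- 2e-2
  part_b <- particle_properties(1e-6)
  D_b <- particle_diffusivity(part_b, air_properties())
  Pe_b <- 8 * l_b / (3 * h_b)          # puts the decay length 3 h Pe/16 at l/2
  u_b <- Pe_b * D_b / (2 * h_b)
  fl_b <- channel_field(h_b, l_b, u_b, air_properties(), profile = "parabolic",
                        n_cells = 40)
  cfg_b <- sim_config(u_air_inlet = u_b, u_media_inlet = 0,
                      n_particles = n_particles, seed = seed,
                      gravity = FALSE, max_time = 4e5)
  res_b <- run_tracing(fl_b, part_b, cfg_b, n_bands = 20)
  occ <- attr(res_b, "band_occupancy")
  dec <- occ[2:20]
  rho_s <- suppressWarnings(stats::cor(seq_along(dec), dec, method = "spearman"))
  add("band_decay", "spearman(band, concentration)", rho_s, "< -0.9", rho_s < -0.9)
  mass_ok <- sum(table(res_b$status)) == n_particles && attr(res_b, "incomplete") == 0
  add("band_decay", "mass accounting complete", as.numeric(mass_ok), "== 1", mass_ok)

  # (c) deposition rate vs out-of-plane depth (shallow-channel drag)
  geom_c <- channel_geometry(l = "1 mm", d = 0)
  part_c <- particle_properties(500e-9)
  cfg_c <- sim_config(n_particles = n_particles, seed = seed)
  eps_c <- purrr::map_dbl(list(NULL, 2e-3), function(depth) {
    fld <- cached_flow(channel_geometry(l = "1 mm", d = 0, depth = depth),
                       shallow_depth = depth)
    deposition_rate(run_tracing(fld, part_c, cfg_c))
  })
  p_c <- max(mean(eps_c), 1 / n_particles)
  se_diff <- sqrt(2 * p_c * (1 - p_c) / n_particles)
  diff_c <- abs(diff(eps_c))
  add("shallow_depth", "|eps(2 mm) - eps(unbounded)|", diff_c,
      "<= 4 Monte-Carlo SE", diff_c <= 4 * se_diff + 1e-12)

  # (d) settling twins of the bench experiment (water, entrance bolus released
  # in the upper part of the inlet; the bench release profile is not recorded)
  water <- media_properties()
  run_d <- function(dp, rho_p, h, u, mode) {
    fld <- channel_field(h, 15e-3, u, water, profile = "parabolic", n_cells = 40)
    cfg <- sim_config(u_air_inlet = u, u_media_inlet = 0,
                      n_particles = n_particles, seed = seed,
                      integrator = mode, max_time = 2000)
    ymt <- fld$domain$y_mem_top
    run_tracing(fld, particle_properties(dp, rho_p), cfg,
                injection = list(y0 = ymt + 0.6 * h, y1 = ymt + 0.9 * h))
  }
  res_d1 <- run_d(1e-6, 2200, 1e-4, 3e-4, "overdamped")
  eps_d1 <- deposition_rate(res_d1)
  add("washout_1um_0.3mms", "deposition rate", eps_d1, "< 0.05", eps_d1 < 0.05)
  res_d2 <- run_d(10e-6, 1470, 3e-4, 1e-4, "inertial")
  dd2 <- deposit_distribution(res_d2, l = 15e-3)
  add("entrance_10um_0.1mms", "deposition rate", deposition_rate(res_d2),
      "> 0.95", deposition_rate(res_d2) > 0.95)
  add("entrance_10um_0.1mms", "normalized mean deposit position", dd2$mean_norm,
      "< 0.2", is.finite(dd2$mean_norm) && dd2$mean_norm < 0.2)
  res_d3 <- run_d(10e-6, 1470, 3e-4, 3e-4, "inertial")
  dd3 <- deposit_distribution(res_d3, l = 15e-3)
  spread_ok <- is.finite(dd3$mean_norm) && dd3$mean_norm > dd2$mean_norm
  add("spread_10um_0.3mms", "mean position vs 0.1 mm/s case",
      dd3$mean_norm, "> entrance case", spread_ok)

  dplyr::bind_rows(checks)
}
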