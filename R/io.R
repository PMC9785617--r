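# Configuration files and result serialization.
#
# Config files are flat YAML key/value documents; values may carry explicit
# unit suffixes ("100 um", "0.3 mm/s", "0.718 mPa.s") and everything is
# normalized to SI on load. Unknown keys are rejected so that typos cannot
# silently fall back to defaults.

.config_keys <- list(
  geometry = c("h_air", "h_media", "l", "b", "d", "p2p",
               "porous_x0", "porous_x1", "depth"),
  air = c("air_rho", "air_mu", "air_T", "air_R", "air_sigma"),
  media = c("media_rho", "media_mu", "media_T"),
  particle = c("dp", "rho_p"),
  run = c("u_air_inlet", "u_media_inlet", "n_particles", "dt", "seed", "g",
          "integrator", "brownian", "gravity", "drag", "max_time",
          "injection", "init_velocity", "inlet_profile")
)

#' Load a simulation configuration file
#'
#' Reads a flat YAML document, validates every key and unit, and resolves the
#' device, fluids, particle and run settings; unspecified keys take the
#' package defaults (the standard device dimensions and 37 degC air/media
#' properties). The default particle is a 100 nm, 1180 kg/m^3 tracer.
#'
#' @param path Path to a YAML file; `NULL` returns the full default set.
#' @return A list with elements `geometry`, `air`, `media`, `particle`,
#'   `config` (classed objects) and `raw` (the resolved flat list, SI units).
#' @export
load_config <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- unlist(.config_keys, use.names = FALSE)
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(bad, collapse = ", ")))
  }
  gv <- function(key, default = NULL) if (key %in% names(vals)) vals[[key]] else default

  geometry <- channel_geometry(
    h_air = gv("h_air", "100 um"), h_media = gv("h_media", "100 um"),
    l = gv("l", "2 mm"), b = gv("b", "10 um"),
    d = gv("d", "10 um"), p2p = gv("p2p", "10 um"),
    porous_x0 = gv("porous_x0", 0), porous_x1 = gv("porous_x1"),
    depth = gv("depth"))
  air_args <- list(rho = gv("air_rho", 1.123), mu = gv("air_mu", "0.019 mPa.s"),
                   T = gv("air_T", .T_default), R = gv("air_R", 290),
                   sigma = gv("air_sigma", 346e-12))
  air <- do.call(air_properties, air_args)
  media <- media_properties(rho = gv("media_rho", 1000),
                            mu = gv("media_mu", "0.718 mPa.s"),
                            T = gv("media_T", .T_default))
  particle <- particle_properties(dp = gv("dp", "100 nm"),
                                  rho_p = gv("rho_p", 1180))
  config <- sim_config(
    u_air_inlet = gv("u_air_inlet", "0.3 mm/s"),
    u_media_inlet = gv("u_media_inlet", "0.3 mm/s"),
    n_particles = gv("n_particles", 1000), dt = gv("dt"),
    seed = gv("seed", 1L), g = gv("g", 9.81),
    integrator = gv("integrator", "overdamped"),
    brownian = gv("brownian", TRUE), gravity = gv("gravity", TRUE),
    drag = gv("drag", TRUE), max_time = gv("max_time", 120),
    injection = gv("injection", "uniform"),
    init_velocity = gv("init_velocity", "fluid"),
    inlet_profile = gv("inlet_profile", "uniform"))

  raw <- c(
    unclass(geometry)[!vapply(unclass(geometry), is.null, logical(1))],
    setNames(list(air$rho, air$mu, air$T, air$R, air$sigma), .config_keys$air),
    setNames(list(media$rho, media$mu, media$T), .config_keys$media),
    list(dp = particle$dp, rho_p = particle$rho_p),
    unclass(config)[!vapply(unclass(config), is.null, logical(1))]
  )
  list(geometry = geometry, air = air, media = media, particle = particle,
       config = config, raw = raw)
}

#' Save a resolved configuration
#'
#' Writes the fully resolved configuration (SI units, defaults included) as a
#' flat YAML document; reloading it reproduces an identical configuration.
#'
#' @param cfg A [load_config()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg$raw, path, precision = 17)
  invisible(path)
}

#' Event log of a tracing run
#'
#' One record per particle event: release, transfer, deposit, exit.
#'
#' @param result An [run_tracing()] result.
#' @return A tibble with `id`, `event`, `t`, `x`, `y`.
#' @export
result_events <- function(result) {
  rel <- tibble(id = result$id, event = "release", t = 0,
                x = NA_real_, y = NA_real_)
  tr <- result |> dplyr::filter(!is.na(.data$t_transfer)) |>
    dplyr::transmute(.data$id, event = "transfer", t = .data$t_transfer,
                     x = NA_real_, y = NA_real_)
  dep <- result |> dplyr::filter(.data$status == "deposited") |>
    dplyr::transmute(.data$id, event = "deposit", t = .data$t,
                     x = .data$x_deposit, y = .data$y)
  ex <- result |> dplyr::filter(.data$status %in% c("exited_air", "exited_media")) |>
    dplyr::transmute(.data$id, event = paste0("exit_", sub("exited_", "", .data$status)),
                     t = .data$t, x = .data$x, y = .data$y)
  dplyr::arrange(dplyr::bind_rows(rel, tr, dep, ex), .data$t, .data$id)
}

#' Write case results, event log and run manifest
#'
#' Appends the case summary row(s) to `summary.csv` (header written once),
#' dumps the per-particle event log as JSON lines, and writes a manifest with
#' the resolved configuration, seed, package version, timestamps and file
#' digests for full provenance.
#'
#' @param case A [run_case()] row (or several).
#' @param dir Output directory (created if needed).
#' @param result Optional [run_tracing()] result for the event log.
#' @param cfg Optional [load_config()] result echoed into the manifest.
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(case, dir, result = NULL, cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  csv <- file.path(dir, "summary.csv")
  utils::write.table(case, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv),
                     qmethod = "double")
  paths <- c(paths, csv)
  if (!is.null(result)) {
    ev <- file.path(dir, "events.jsonl")
    con <- file(ev, "w")
    jsonlite::stream_out(result_events(result), con, verbose = FALSE)
    close(con)
    paths <- c(paths, ev)
  }
  manifest <- list(
    package = "lungchip",
    version = as.character(utils::packageVersion("lungchip")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(cfg)) cfg$config$seed else unique(case$seed),
    config = if (!is.null(cfg)) cfg$raw else NULL,
    files = as.list(tools::md5sum(paths))
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, mf))
}
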