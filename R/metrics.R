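# Summary statistics of a tracing run: deposition/transfer rates, deposit and
# outlet distribution indexes, band-averaged concentrations and the
# concentration-time curve of the media outlet.

.n_released <- function(result) {
  n <- attr(result, "n_released") %||% nrow(result)
  if (is.null(n) || n < 1) abort("Result has no released particles.")
  n
}

#' Deposition rate
#'
#' Fraction of released particles deposited on the membrane-top substrate of
#' the air channel.
#'
#' @param result An [run_tracing()] result.
#' @return Fraction in `[0, 1]`.
#' @export
deposition_rate <- function(result) {
  sum(result$status == "deposited") / .n_released(result)
}

#' Transfer (translocation) rate
#'
#' Fraction of released particles that crossed a membrane pore into the media
#' channel (whether or not they have already left it).
#'
#' @param result An [run_tracing()] result.
#' @return Fraction in `[0, 1]`.
#' @export
transfer_rate <- function(result) {
  sum(!is.na(result$t_transfer)) / .n_released(result)
}

#' Particle fate bookkeeping
#'
#' @param result An [run_tracing()] result.
#' @return A tibble with one row per fate (count and fraction); fractions sum
#'   to 1.
#' @export
fate_summary <- function(result) {
  n <- .n_released(result)
  result |>
    dplyr::count(.data$status, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / !!n)
}

.dist_stats <- function(z, label) {
  n <- length(z)
  if (n == 0) {
    return(tibble(mean_norm = NA_real_, std_norm = NA_real_, n = 0L))
  }
  m <- mean(z)
  s <- sqrt(mean((z - m)^2))  # population moments: a lone deposit has spread 0
  tibble(mean_norm = m, std_norm = s, n = n)
}

#' Deposit distribution statistics
#'
#' Mean and standard deviation of deposit positions normalized by the channel
#' length; an ideally uniform deposition has mean 0.5 and standard deviation
#' `1/sqrt(12)`.
#'
#' @param result An [run_tracing()] result.
#' @param l Channel length (m); defaults to the geometry the run was traced in.
#' @return A one-row tibble (`mean_norm`, `std_norm`, `n`); `n = 0` with `NA`
#'   statistics when nothing deposited.
#' @export
deposit_distribution <- function(result, l = NULL) {
  l <- l %||% attr(result, "geometry")$l
  if (is.null(l)) abort("Channel length `l` unavailable; pass it explicitly.")
  .dist_stats(result$x_deposit[!is.na(result$x_deposit)] / l, "deposit")
}

#' Media-outlet distribution statistics
#'
#' Mean and standard deviation of the vertical crossing positions of
#' transferred particles at the media-channel outlet, normalized by the
#' media-channel height with the floor at 0 and the membrane side at 1.
#'
#' @param result An [run_tracing()] result.
#' @param h_media Media-channel height (m); defaults to the traced geometry.
#' @return A one-row tibble (`mean_norm`, `std_norm`, `n`).
#' @export
outlet_distribution <- function(result, h_media = NULL) {
  h_media <- h_media %||% attr(result, "geometry")$h_media
  if (is.null(h_media)) abort("`h_media` unavailable; pass it explicitly.")
  .dist_stats(result$y_exit[!is.na(result$y_exit)] / h_media, "outlet")
}

#' Band-averaged particle concentration along the channel
#'
#' Partitions `[0, l]` into equal bands, divides the particle count in each
#' band by the band measure (band length x channel height, unit depth) and by
#' the reference areal concentration `C0`. The streamwise axis is returned
#' normalized by the convective-diffusive length `3 h Pe / 16` with
#' `Pe = 2 u_mean h / D`.
#'
#' @param positions Streamwise particle positions (m) in `[0, l]`.
#' @param l Channel length (m).
#' @param n_bands Number of equal bands (>= 1).
#' @param C0 Reference areal concentration (1/m^2).
#' @param h Channel height (m).
#' @param u_mean Mean velocity (m/s).
#' @param D Particle diffusivity (m^2/s).
#' @param weights Optional per-position weights (e.g. residence times).
#' @return A tibble with `band`, `x_mid`, `x_norm`, `count`, `c_norm`.
#' @export
band_concentration <- function(positions, l, n_bands, C0 = 1e5, h,
                               u_mean, D, weights = NULL) {
  l <- .q(l, "l"); h <- .q(h, "h")
  if (n_bands < 1) abort("`n_bands` must be >= 1.")
  if (length(positions) && any(positions < 0 | positions > l)) {
    abort("All positions must lie in [0, l].")
  }
  Pe <- peclet_number(u_mean, h, D)
  x_scale <- 3 * h * Pe / 16
  band_len <- l / n_bands
  idx <- pmin(pmax(floor(positions / band_len) + 1, 1), n_bands)
  w <- weights %||% rep(1, length(positions))
  counts <- as.numeric(tapply(w, factor(idx, levels = seq_len(n_bands)), sum))
  counts[is.na(counts)] <- 0
  x_mid <- (seq_len(n_bands) - 0.5) * band_len
  tibble(
    band = seq_len(n_bands), x_mid = x_mid, x_norm = x_mid / x_scale,
    count = counts,
    c_norm = counts / (band_len * h) / C0
  )
}

#' Peclet number
#'
#' Convection-to-diffusion ratio `Pe = 2 u_mean h / D`.
#'
#' @param u_mean Mean velocity (m/s).
#' @param h Channel height (m).
#' @param D Diffusivity (m^2/s).
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(u_mean, h, D) {
  2 * .q(u_mean, "u_mean") * .q(h, "h") / .q(D, "D")
}

#' Concentration-time curve of the media outlet
#'
#' Records the relative concentration — the cumulative fraction of injected
#' particles that have flowed out of the media-channel outlet — on a time
#' grid, differentiates it numerically and fits a Gaussian
#' `A exp(-(t - tmax)^2 / (2 w^2))` to the rate by nonlinear least squares.
#' The fitted peak gives `cmax` (peak rate, 1/s) and `tmax` (peak time, s);
#' the area under the rate curve equals the transfer rate realized at the
#' outlet.
#'
#' @param result An [run_tracing()] result (complete run).
#' @param t_grid Optional time grid (s); default 200 uniform bins spanning
#'   the observed exit times.
#' @param n_bins Number of default grid points.
#' @return An object of class `lc_curve`.
#' @export
concentration_time <- function(result, t_grid = NULL, n_bins = 200) {
  n <- .n_released(result)
  te <- sort(result$t_exit[!is.na(result$t_exit)])
  if (is.null(t_grid)) {
    t_hi <- if (length(te)) max(te) * 1.02 else attr(result, "config")$max_time %||% 1
    t_grid <- seq(0, t_hi, length.out = n_bins)
  }
  c_cum <- vapply(t_grid, function(tt) sum(te <= tt), numeric(1)) / n
  m <- length(t_grid)
  c_rate <- numeric(m)
  if (m >= 3) {
    c_rate[2:(m - 1)] <- (c_cum[3:m] - c_cum[1:(m - 2)]) /
      (t_grid[3:m] - t_grid[1:(m - 2)])
    c_rate[1] <- (c_cum[2] - c_cum[1]) / (t_grid[2] - t_grid[1])
    c_rate[m] <- (c_cum[m] - c_cum[m - 1]) / (t_grid[m] - t_grid[m - 1])
  }
  dat <- tibble(t = t_grid, c_cum = c_cum, c_rate = c_rate)

  fit <- NULL; cmax <- 0; tmax <- NA_real_; fit_ok <- FALSE
  if (length(te) >= 5) {
    i0 <- which.max(c_rate)
    start <- list(A = max(c_rate), t0 = t_grid[i0], w = max(sd(te), diff(range(t_grid)) / 50))
    fit <- tryCatch(
      minpack.lm::nlsLM(c_rate ~ A * exp(-(t - t0)^2 / (2 * w^2)),
                        data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      cmax <- unname(cf[["A"]]); tmax <- unname(cf[["t0"]]); fit_ok <- TRUE
      dat$fit <- predict(fit)
    }
  }
  if (!fit_ok) dat$fit <- NA_real_
  structure(list(
    data = dat, fit = fit, cmax = cmax, tmax = tmax, fit_ok = fit_ok,
    n_released = n, n_exits = length(te),
    transfer_realized = length(te) / n
  ), class = "lc_curve")
}

#' @export
print.lc_curve <- function(x, ...) {
  cat(sprintf("<lc_curve> %d/%d media exits; cmax = %.3g 1/s at tmax = %.3g s%s\n",
              x$n_exits, x$n_released, x$cmax, x$tmax,
              if (x$fit_ok) "" else " (Gaussian fit unavailable)"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the Gaussian peak fit of a concentration-time curve
#'
#' @param x An `lc_curve`.
#' @param ... Unused.
#' @return A tibble of fitted parameters (amplitude, center, width).
#' @export
tidy.lc_curve <- function(x, ...) {
  if (!x$fit_ok) {
    return(tibble(term = character(), estimate = numeric(), std.error = numeric()))
  }
  sm <- summary(x$fit)$coefficients
  tibble(term = c("cmax", "tmax", "width"),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"])
}

#' One-row summary of a concentration-time curve
#'
#' @param x An `lc_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `cmax`, `tmax`, realized transfer, exit count,
#'   fit status.
#' @export
glance.lc_curve <- function(x, ...) {
  tibble(cmax = x$cmax, tmax = x$tmax,
         transfer_realized = x$transfer_realized,
         n_exits = x$n_exits, fit_ok = x$fit_ok)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concentration-time curve
#'
#' @param object An `lc_curve`.
#' @param ... Unused.
#' @return A ggplot: binned concentration rate and its Gaussian fit.
#' @export
autoplot.lc_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c_rate), colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "relative concentration rate (1/s)")
  if (object$fit_ok) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "firebrick")
  }
  p
}

#' Plot particle fates of a tracing run
#'
#' Deposits along the membrane top and outlet crossings of the media channel.
#'
#' @param object An `lc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lc_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e6,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "x (mm)", y = "y (um)", colour = "fate")
}

#' Plot the speed field of a flow solution
#'
#' @param object An `lc_flow`.
#' @param ... Unused.
#' @return A ggplot raster of the cell-centered speed.
#' @export
autoplot.lc_flow <- function(object, ...) {
  nx <- object$nx; ny <- object$ny
  uc <- (object$u[1:nx, ] + object$u[2:(nx + 1), ]) / 2
  vc <- (object$v[, 1:ny] + object$v[, 2:(ny + 1)]) / 2
  sp <- sqrt(uc^2 + vc^2)
  sp[object$domain$cls == 0L] <- NA
  df <- tidyr::expand_grid(i = seq_len(nx), j = seq_len(ny)) |>
    dplyr::mutate(x = (.data$i - 0.5) * object$dx * 1e3,
                  y = (.data$j - 0.5) * object$dy * 1e6,
                  speed = as.vector(sp[cbind(.data$i, .data$j)]) * 1e3)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$speed)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "x (mm)", y = "y (um)", fill = "speed (mm/s)")
}
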