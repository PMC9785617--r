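# Shared fixtures and independent oracles.
#
# Flow fields are built lazily through the package-level cache, so every test
# file reuses the same solves within one run.

geom_small_np <- function() channel_geometry(l = "0.5 mm", d = 0)
geom_small_p <- function() channel_geometry(l = "0.5 mm")
geom_full <- function() channel_geometry()

field_small_np <- function() cached_flow(geom_small_np())
field_small_p <- function() cached_flow(geom_small_p())
field_quiescent <- function() {
  cached_flow(geom_small_np(), u_top_inlet = 0, u_bottom_inlet = 0)
}

# one-sided 95% Monte-Carlo comparison of two binomial fractions
mc_greater <- function(p_hi, p_lo, n_hi, n_lo = n_hi) {
  se <- sqrt(p_hi * (1 - p_hi) / n_hi + p_lo * (1 - p_lo) / n_lo)
  (p_hi - p_lo) > 1.645 * se
}
mc_geq <- function(p_hi, p_lo, n_hi, n_lo = n_hi) {
  se <- sqrt(p_hi * (1 - p_hi) / n_hi + p_lo * (1 - p_lo) / n_lo)
  (p_hi - p_lo) > -1.645 * se - 1e-12
}

# Independent finite-difference oracle: fraction of Brownian particles
# absorbed by time T, starting from a delta at y0 between an absorbing floor
# (y = 0) and a reflecting ceiling (y = h). Explicit scheme, fine grid.
fd_absorbed_fraction <- function(D, h, y0, T, n_nodes = 400) {
  dy <- h / n_nodes
  y <- (seq_len(n_nodes) - 0.5) * dy
  c0 <- numeric(n_nodes)
  i0 <- which.min(abs(y - y0))
  c0[i0] <- 1 / dy
  dt <- 0.2 * dy^2 / D
  nt <- ceiling(T / dt)
  dt <- T / nt
  lam <- D * dt / dy^2
  cc <- c0
  for (k in seq_len(nt)) {
    # ghost: floor absorbing (c = 0 at wall), ceiling reflecting
    cl <- c(-cc[1], cc[-n_nodes])
    cr <- c(cc[-1], cc[n_nodes])
    cc <- cc + lam * (cl - 2 * cc + cr)
  }
  1 - sum(cc) * dy
}

# synthetic tracing-result tibble for metric unit tests
fake_result <- function(n, status, x_deposit = NA_real_, t_exit = NA_real_,
                        y_exit = NA_real_, t_transfer = NA_real_) {
  lv <- c("active_air", "active_media", "deposited", "exited_air", "exited_media")
  out <- tibble::tibble(
    id = seq_len(n),
    status = factor(rep_len(status, n), levels = lv),
    x = 0, y = 0, t = 0,
    t_transfer = rep_len(t_transfer, n),
    t_exit = rep_len(t_exit, n),
    y_exit = rep_len(y_exit, n),
    x_deposit = rep_len(x_deposit, n)
  )
  attr(out, "n_released") <- n
  out
}
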