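test_that("flow-rate bookkeeping reproduces the bench operating points", {
  expect_equal(flow_rate("0.03 mm/s", "2000 um", "100 um"), 0.36,
               tolerance = 1e-12)
  expect_equal(flow_rate("0.3 mm/s", "2000 um", "300 um"), 10.8,
               tolerance = 1e-12)
  expect_equal(flow_rate(0, 2e-3, 1e-4), 0)
})

test_that("analytic parallel-plate profile behaves", {
  expect_equal(poiseuille_profile(1e-3, 1e-4, c(0, 1e-4)), c(0, 0))
  expect_equal(poiseuille_profile(1e-3, 1e-4, 0.5e-4), 1.5e-3)
  y <- seq(0, 1e-4, length.out = 2001)
  u <- poiseuille_profile(1e-3, 1e-4, y)
  avg <- sum((u[-1] + u[-2001]) / 2 * diff(y)) / 1e-4
  expect_equal(avg, 1e-3, tolerance = 1e-5)
  expect_error(poiseuille_profile(1e-3, 1e-4, 2e-4), "within")
})

test_that("null forcing returns an identically zero field", {
  fld <- field_quiescent()
  expect_equal(max(abs(fld$u)), 0)
  expect_equal(max(abs(fld$v)), 0)
  expect_equal(max(abs(fld$p)), 0)
})

test_that("impermeable-membrane solve recovers plane Poiseuille within 1%", {
  fld <- field_small_np()
  dom <- fld$domain
  u_ref <- 3e-4
  # far from the inlet, across each channel
  for (base in list(c(dom$y_mem_top, dom$geometry$h_air),
                    c(0, dom$geometry$h_media))) {
    yq <- base[1] + seq(0.05, 0.95, by = 0.05) * base[2]
    prof <- sample_velocity(fld, rep(0.8 * dom$geometry$l, length(yq)), yq)
    ana <- poiseuille_profile(u_ref, base[2], yq - base[1])
    expect_lt(max(abs(prof$u - ana)) / max(ana), 0.01)
  }
  # centerline ratio of the developed profile
  mid <- sample_velocity(fld, 0.8 * dom$geometry$l,
                         dom$y_mem_top + dom$geometry$h_air / 2)
  expect_equal(mid$u / u_ref, 1.5, tolerance = 0.01)
})

test_that("converged solves are discretely divergence-free and conservative", {
  for (fld in list(field_small_np(), field_small_p())) {
    u_scale <- max(abs(fld$u)) / fld$dx
    expect_lt(max_divergence(fld), 1e-6 * u_scale)
    bal <- flux_balance(fld)
    imbalance <- abs(bal$inlet - bal$outlet + bal$pore)
    expect_lt(max(imbalance / bal$inlet), 1e-5)
  }
})

test_that("the Stokes field scales linearly with the inlet velocities", {
  fld1 <- field_small_np()
  fld2 <- cached_flow(geom_small_np(), u_top_inlet = 6e-4, u_bottom_inlet = 6e-4)
  expect_equal(fld2$u, 2 * fld1$u, tolerance = 1e-7)
  expect_equal(fld2$v, 2 * fld1$v, tolerance = 1e-7)
})

test_that("symmetric device with identical fluids exchanges no net pore flow", {
  med <- media_properties()
  fld <- cached_flow(geom_small_p(), fluid_top = med, fluid_bottom = med,
                     pore_flow = "open")
  inflow <- sum(flux_balance(fld)$inlet)
  expect_lt(abs(pore_flux(fld)) / inflow, 1e-3)
})

test_that("refining the grid reduces the profile error", {
  g <- channel_geometry(l = "0.3 mm", d = 0)
  err <- vapply(c(5e-6, 2.5e-6), function(cell) {
    fld <- solve_flow(build_domain(g, cell = cell))
    yq <- fld$domain$y_mem_top + seq(0.1, 0.9, by = 0.1) * g$h_air
    prof <- sample_velocity(fld, rep(0.8 * g$l, length(yq)), yq)
    ana <- poiseuille_profile(3e-4, g$h_air, yq - fld$domain$y_mem_top)
    max(abs(prof$u - ana)) / max(ana)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("velocity sampling is exact at nodes, on walls, and for linear fields", {
  fld <- field_small_np()
  dom <- fld$domain
  # node identity: u stored at (x = (i-1) dx, y = (j-0.5) dy)
  i <- 40L; j <- dom$n_media + dom$n_mem + 10L
  s <- sample_velocity(fld, (i - 1) * fld$dx, (j - 0.5) * fld$dy)
  expect_equal(s$u, fld$u[i, j], tolerance = 1e-14)
  # no-slip on the channel ceiling and on the membrane top
  w <- sample_velocity(fld, c(2e-4, 2e-4), c(dom$y_top, dom$y_mem_top))
  expect_equal(w$u, c(0, 0), tolerance = 1e-18)
  expect_equal(w$v, c(0, 0), tolerance = 1e-18)
  # queries inside the solid membrane are rejected
  expect_error(sample_velocity(fld, 2e-4, dom$y_mem_bot + dom$geometry$b / 2),
               "solid")

  # bilinear interpolation reproduces a linear velocity field exactly
  lin <- fld
  xs <- matrix(rep(seq(0, dom$geometry$l, length.out = fld$nx + 1), fld$ny),
               fld$nx + 1, fld$ny)
  ys <- matrix(rep((seq_len(fld$ny) - 0.5) * fld$dy, each = fld$nx + 1),
               fld$nx + 1, fld$ny)
  lin$u <- 2 * xs + 3 * ys
  lin$v <- matrix(0, fld$nx, fld$ny + 1)
  lin <- lungchip:::.finalize_field(lin)
  q <- sample_velocity(lin, c(1.23e-4, 2.7e-4), dom$y_mem_top +
                         c(0.37, 0.61) * dom$geometry$h_air)
  expect_equal(q$u, 2 * q$x + 3 * q$y, tolerance = 1e-10)
})
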