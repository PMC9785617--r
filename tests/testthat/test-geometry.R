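test_that("Knudsen number matches the hard-sphere evaluation and its scalings", {
  air <- air_properties()
  kn <- knudsen_number(air, "100 um")
  expect_equal(kn, 3.985e-4, tolerance = 1e-3)
  expect_lt(kn, 0.01)                       # continuum regime for the device
  # hand evaluation at h = 1 mm
  expect_equal(knudsen_number(air, 1e-3), 3.985e-5, tolerance = 1e-3)

  # exact inverse proportionality to h and to sigma^2 over a parameter grid
  for (h in c(5e-5, 1e-4, 3e-4, 1e-3)) {
    expect_equal(knudsen_number(air, h) * h, kn * 1e-4, tolerance = 1e-12)
  }
  for (sig in c(2e-10, 346e-12, 5e-10)) {
    a2 <- air_properties(sigma = sig)
    expect_equal(knudsen_number(a2, 1e-4) * sig^2, kn * (346e-12)^2,
                 tolerance = 1e-12)
  }
  expect_error(knudsen_number(fluid_properties(1.1, 1.9e-5), 1e-4), "sigma")
  expect_error(knudsen_number(air_properties(R = NULL), 1e-4), "R")
})

test_that("regime report computes Re_p, relaxation time and Stokes number", {
  air <- air_properties()
  geom <- geom_full()
  rep1 <- validate_regime(air, particle_properties(900e-9), 1e-3, geom)
  expect_equal(rep1$re_p, 1.123 * 1e-3 * 900e-9 / 1.9e-5, tolerance = 1e-12)
  expect_equal(rep1$re_p, 5.3e-5, tolerance = 0.01)
  expect_false(rep1$flag_re)
  expect_false(rep1$flag_kn)

  rep0 <- validate_regime(air, particle_properties(900e-9), 0, geom)
  expect_equal(rep0$re_p, 0)
  expect_equal(rep0$stokes_number, 0)

  rep2 <- validate_regime(air, particle_properties(10e-9), 1e-3, geom)
  expect_equal(rep2$tau, 1180 * (1e-8)^2 / (18 * 1.9e-5), tolerance = 1e-12)
  expect_equal(rep2$tau, 3.45e-10, tolerance = 0.01)

  # channel Reynolds numbers of the operating points stay deeply laminar
  expect_lt(1.123 * 1e-3 * 1e-4 / 1.9e-5, 2)    # air at 1 mm/s
  expect_lt(1000 * 1e-3 * 1e-4 / 0.718e-3, 2)   # media at 1 mm/s
})

test_that("geometry validation rejects inconsistent devices", {
  expect_error(channel_geometry(h_air = -1), "h_air")
  expect_error(channel_geometry(porous_x0 = "1.5 mm", porous_x1 = "1 mm"),
               "porous")
  expect_error(channel_geometry(porous_x1 = "3 mm"), "porous")
  # no full pore fits
  expect_error(channel_geometry(l = "5 um", d = "10 um", p2p = "10 um"),
               "pore")
})

test_that("pore tiling follows the edge-to-edge convention", {
  expect_equal(nrow(pore_intervals(channel_geometry(d = 0))), 0)
  g <- channel_geometry(d = "10 um", p2p = "10 um", l = "2 mm")
  p <- pore_intervals(g)
  expect_equal(nrow(p), 100)               # floor((2000 + 10)/(10 + 10))
  expect_equal(p$x1 - p$x0, rep(10e-6, 100), tolerance = 1e-12)
  expect_equal(diff(p$x0), rep(20e-6, 99), tolerance = 1e-12)
  expect_lte(max(p$x1), g$porous_x1 + 1e-15)
})

test_that("domain classification partitions the device", {
  dom <- build_domain(geom_small_p())
  # every cell carries exactly one class
  expect_true(all(dom$cls %in% 0:3))
  # layer structure: media rows below, air rows above, membrane band between
  expect_true(all(dom$cls[, seq_len(dom$n_media)] == 2L))
  expect_true(all(dom$cls[, dom$n_media + dom$n_mem + seq_len(dom$n_air)] == 1L))
  band <- dom$cls[, dom$n_media + seq_len(dom$n_mem), drop = FALSE]
  expect_true(all(band %in% c(0L, 3L)))
  # pore columns: 6 cells per 10 um pore at the default cell size
  expect_equal(sum(band[, 1] == 3L), 6 * nrow(dom$pores))

  # membrane-top line partition: sticky + pore mouths = full length
  sticky_len <- sum(dom$sticky$x1 - dom$sticky$x0)
  pore_len <- sum(dom$pores$x1 - dom$pores$x0)
  expect_equal(sticky_len + pore_len, dom$geometry$l, tolerance = 1e-12)

  # impermeable membrane: two disjoint channels
  dom0 <- build_domain(geom_small_np())
  expect_equal(nrow(dom0$pores), 0)
  expect_true(all(dom0$cls[, dom0$n_media + seq_len(dom0$n_mem)] == 0L))
})

test_that("domains rebuild identically from a round-tripped configuration", {
  cfg <- load_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  d1 <- build_domain(cfg$geometry)
  d2 <- build_domain(cfg2$geometry)
  expect_identical(d1$cls, d2$cls)
  expect_identical(d1$pores, d2$pores)
  expect_identical(d1$sticky, d2$sticky)
})

test_that("incommensurate grids are rejected", {
  g <- channel_geometry(h_air = "97 um", d = 0)   # not a multiple of b/6
  expect_error(build_domain(g), "commensurate")
})
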