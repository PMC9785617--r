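test_that("rates are simple fate fractions with the right edge cases", {
  res <- fake_result(100, c(rep("deposited", 95), rep("exited_air", 5)),
                     x_deposit = c(runif(95, 0, 2e-3), rep(NA, 5)))
  expect_equal(deposition_rate(res), 0.95)
  expect_equal(transfer_rate(res), 0)

  res2 <- fake_result(10, "exited_media", t_exit = 1:10, y_exit = 5e-5,
                      t_transfer = 0.5)
  expect_equal(transfer_rate(res2), 1)
  expect_equal(deposition_rate(res2), 0)

  res3 <- fake_result(0, character(0))
  expect_error(deposition_rate(res3), "released")
})

test_that("deposit distribution uses exact normalized population moments", {
  # uniform deposits: mean 1/2, spread 1/sqrt(12)
  set.seed(99)
  l <- 2e-3
  xs <- runif(5e4, 0, l)
  res <- fake_result(5e4, "deposited", x_deposit = xs)
  dd <- deposit_distribution(res, l = l)
  expect_equal(dd$mean_norm, 0.5, tolerance = 0.01)
  expect_equal(dd$std_norm, 1 / sqrt(12), tolerance = 0.01)
  expect_lte(dd$std_norm, 0.5)

  # a lone deposit has zero spread
  one <- fake_result(1, "deposited", x_deposit = l / 4)
  d1 <- deposit_distribution(one, l = l)
  expect_equal(d1$mean_norm, 0.25)
  expect_equal(d1$std_norm, 0)

  # no deposits: empty-statistics signal, not an error
  none <- fake_result(5, "exited_air")
  d0 <- deposit_distribution(none, l = l)
  expect_equal(d0$n, 0)
  expect_true(is.na(d0$mean_norm))

  # ordering invariance
  sh <- fake_result(5e4, "deposited", x_deposit = sample(xs))
  expect_equal(deposit_distribution(sh, l = l)$mean_norm, dd$mean_norm)
})

test_that("outlet distribution reads high means at the membrane side", {
  h <- 1e-4
  top <- fake_result(20, "exited_media", t_exit = 1, y_exit = h)
  dt_ <- outlet_distribution(top, h_media = h)
  expect_equal(dt_$mean_norm, 1)
  expect_equal(dt_$std_norm, 0)

  two <- fake_result(2, "exited_media", t_exit = 1, y_exit = c(0, h))
  d2 <- outlet_distribution(two, h_media = h)
  expect_equal(d2$mean_norm, 0.5)
  expect_equal(d2$std_norm, 0.5)

  set.seed(7)
  unif <- fake_result(2e4, "exited_media", t_exit = 1, y_exit = runif(2e4, 0, h))
  expect_equal(outlet_distribution(unif, h_media = h)$mean_norm, 0.5,
               tolerance = 0.02)
})

test_that("band concentration counts, normalizes and scales axes correctly", {
  # Peclet number of the parallel-plate reference conditions
  Pe <- peclet_number(0.05, 1e-3, 2.96e-11)
  expect_equal(Pe, 2 * 0.05 * 1e-3 / 2.96e-11, tolerance = 1e-12)
  expect_equal(Pe, 3.38e6, tolerance = 0.01)

  l <- 1e-2; h <- 1e-3; nb <- 10
  bc <- band_concentration(rep(1e-4, 50), l, nb, C0 = 1e5, h = h,
                           u_mean = 0.05, D = 2.96e-11)
  expect_equal(nrow(bc), nb)
  expect_equal(bc$count, c(50, rep(0, 9)))
  expect_equal(bc$c_norm[1], 50 / (l / nb * h) / 1e5, tolerance = 1e-12)
  expect_equal(bc$x_norm, bc$x_mid / (3 * h * Pe / 16), tolerance = 1e-12)

  # uniform positions give a flat profile within sampling error
  set.seed(3)
  bu <- band_concentration(runif(2e4, 0, l), l, nb, C0 = 1e5, h = h,
                           u_mean = 0.05, D = 2.96e-11)
  expect_lt(max(abs(bu$count - 2000)) / 2000, 0.1)

  expect_error(band_concentration(c(-1e-3), l, nb, C0 = 1e5, h = h,
                                  u_mean = 0.05, D = 2.96e-11), "positions")
})

test_that("concentration-time curves integrate to the realized transfer", {
  set.seed(11)
  n <- 1e4
  te <- rnorm(n, 10, 2)
  res <- fake_result(n, "exited_media", t_exit = te, y_exit = 5e-5,
                     t_transfer = te - 1)
  cv <- concentration_time(res)
  expect_true(cv$fit_ok)
  # parameter recovery on synthetic draws
  expect_equal(cv$tmax, 10, tolerance = 0.01)
  expect_lt(abs(cv$tmax - 10), 0.1)
  # cumulative curve is monotone and bounded by the transfer rate
  expect_true(all(diff(cv$data$c_cum) >= 0))
  expect_lte(max(cv$data$c_cum), transfer_rate(res))
  # area under the rate curve equals the final cumulative value within 1%
  area <- sum((head(cv$data$c_rate, -1) + tail(cv$data$c_rate, -1)) / 2 *
                diff(cv$data$t))
  expect_equal(area, tail(cv$data$c_cum, 1), tolerance = 0.01)
  # the Gaussian amplitude approximates the peak rate of a normal pulse
  expect_equal(cv$cmax, 1 / (2 * sqrt(2 * pi)), tolerance = 0.05)

  # tidy/glance expose the fitted peak
  td <- tidy(cv)
  expect_setequal(td$term, c("cmax", "tmax", "width"))
  gl <- glance(cv)
  expect_equal(gl$tmax, cv$tmax)

  # zero transfers: flat curve, no fit
  res0 <- fake_result(10, "exited_air")
  cv0 <- concentration_time(res0)
  expect_false(cv0$fit_ok)
  expect_equal(cv0$cmax, 0)
  expect_true(all(cv0$data$c_cum == 0))
})

test_that("metric and result plots build without evaluation errors", {
  set.seed(2)
  te <- rnorm(500, 5, 1)
  res <- fake_result(500, "exited_media", t_exit = te, y_exit = 5e-5,
                     t_transfer = te - 1)
  p1 <- autoplot(concentration_time(res))
  expect_s3_class(p1, "ggplot")
  fld <- field_small_np()
  expect_s3_class(autoplot(fld), "ggplot")
  cfg <- sim_config(n_particles = 20, seed = 1, max_time = 5)
  expect_s3_class(autoplot(run_tracing(fld, particle_properties(2e-7), cfg)),
                  "ggplot")
  expect_no_error(print(fld))
})
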