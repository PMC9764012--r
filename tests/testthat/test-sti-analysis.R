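opt <- optics_config()
cal <- so2_calibration(opt)

test_that("streak velocimetry recovers constant velocities within 5%", {
  for (v in c(50, 300, 600)) {
    ser <- constant_series(4, velocity = v, lineal_density = 50)
    pair <- render_sti(ser, opt, seed = v)
    est <- estimate_velocity(pair$sti420)
    expect_true(all(est$quality > 0))
    expect_true(all(abs(est$velocity - v) / v < 0.05),
                label = sprintf("velocity %g recovered", v))
  }
})

test_that("stationary cells give zero velocity; blank blocks give NA", {
  ser <- constant_series(3, velocity = 0, lineal_density = 50)
  pair <- render_sti(ser, opt, seed = 2)
  est <- estimate_velocity(pair$sti420)
  expect_true(all(abs(est$velocity) <= opt$um_per_px * opt$fps / 2))

  empty <- constant_series(2, velocity = 300, lineal_density = 0)
  pe <- render_sti(empty, opt, seed = 1)
  ee <- estimate_velocity(pe$sti420)
  expect_true(all(is.na(ee$velocity)))
  expect_true(all(ee$quality == 0))
})

test_that("velocity estimates agree across frame rates", {
  v <- 250
  ests <- sapply(c(30, 60), function(fps) {
    o <- optics_config(fps = fps)
    pair <- render_sti(constant_series(4, v, 50), o, seed = 3)
    mean(estimate_velocity(pair$sti420)$velocity)
  })
  expect_lt(abs(ests[1] - v) / v, 0.05)
  expect_lt(abs(ests[2] - v) / v, 0.05)
  expect_lt(abs(ests[1] - ests[2]) / v, 0.05)
})

test_that("cell counting recovers lineal density within 10%", {
  # fast flow, window sized for ~250 cell transits so count-sampling
  # noise stays well below the asserted tolerance
  for (d in c(10, 50, 100)) {
    secs <- ceiling(250 * 1000 / (600 * d))
    ser <- constant_series(secs, velocity = 600, lineal_density = d)
    pair <- render_sti(ser, opt, seed = d)
    est <- estimate_lineal_density(pair$sti420)
    expect_lt(abs(mean(est$lineal_density) - d) / d, 0.1)
  }
  # empty image scores an exact zero
  pe <- render_sti(constant_series(2, 300, 0), opt, seed = 1)
  expect_true(all(estimate_lineal_density(pe$sti420)$lineal_density == 0))
})

test_that("doubling the cell spacing halves the estimated density", {
  est_at <- function(d) {
    ser <- constant_series(10, velocity = 600, lineal_density = d)
    pair <- render_sti(ser, opt, seed = 17)
    mean(estimate_lineal_density(pair$sti420)$lineal_density)
  }
  expect_equal(est_at(40) / est_at(20), 2, tolerance = 0.15)
})

test_that("ratiometric oximetry inverts the forward model exactly without noise", {
  ser <- constant_series(3, velocity = 300, lineal_density = 50, so2 = 50)
  pair <- render_sti(ser, opt, seed = 4)
  est <- estimate_so2(pair$sti420, pair$sti438, cal)
  expect_equal(est$so2, rep(50, 3), tolerance = 1e-6)
  expect_true(all(est$quality > 0))
})

test_that("oximetry tracks a saturation ramp within 2% under noise", {
  so2r <- seq(90, 40, length.out = 8)
  noisy <- optics_config(noise_sd = 100)
  ser <- tibble::tibble(t = 1:8, velocity = 1000, lineal_density = 50,
                        so2 = so2r)
  pair <- render_sti(ser, noisy, seed = 12)
  est <- estimate_so2(pair$sti420, pair$sti438, cal)
  expect_true(all(abs(est$so2 - so2r) < 2))
})

test_that("cells without measurable absorbance are skipped, not scored 0", {
  # a 438-only absorber with a transparent 420 channel is a degenerate cell:
  # no isosbestic contrast means no detection, so the second is missing
  o <- optics_config(od420 = 1e-9, od438_deoxy = 0.45, od438_oxy = 0.15)
  ser <- constant_series(2, velocity = 300, lineal_density = 50, so2 = 0)
  pair <- render_sti(ser, o, seed = 5)
  est <- estimate_so2(pair$sti420, pair$sti438, so2_calibration(o))
  expect_true(all(is.na(est$so2)))
  expect_true(all(est$quality == 0))
})

test_that("simulate -> render -> analyze closes the loop on all measures", {
  # step response rendered over a short window around the transition
  kin <- list(velocity = mono_exp_params(200, 3, 150, 2),
              lineal_density = mono_exp_params(50, 3, 0, 1),
              so2 = mono_exp_params(70, 3, -20, 1.5))
  spec <- constant_spec(n = 1, velocity = 200, lineal_density = 50, so2 = 70)
  spec$amplitude$velocity <- c(mean = 150, sd = 0)
  spec$amplitude$so2 <- c(mean = -20, sd = 0)
  proto <- make_protocol("mini", segments = data.frame(duration = 8, o2 = 7,
                                                       co2 = 5))
  pop <- simulate_population(proto, spec, kin, seed = 8)
  pair <- render_sti(pop, opt, seed = 8)
  rec <- analyze_sti_pair(pair$sti420, pair$sti438, cal)
  truth <- pop[match(rec$t, pop$t), ]
  expect_true(all(abs(rec$velocity - truth$velocity) / truth$velocity < 0.05))
  # per-second cell counts fluctuate with the handful of cells in view;
  # the window mean is the meaningful density comparison
  expect_lt(abs(mean(rec$lineal_density) - 50) / 50, 0.1)
  expect_true(all(abs(rec$lineal_density - truth$lineal_density) /
                    truth$lineal_density < 0.5))
  expect_true(all(abs(rec$so2 - truth$so2) < 2))
  expect_equal(rec$supply_rate,
               abs(rec$velocity) * rec$lineal_density / 1000,
               tolerance = 1e-9)
})

test_that("oximetry requires a co-registered dual-wavelength pair", {
  ser <- constant_series(2, velocity = 300, lineal_density = 50)
  pair <- render_sti(ser, opt, seed = 6)
  expect_error(estimate_so2(pair$sti420, pair$sti420, cal))
  bad_cal <- list(r0 = 1, r100 = 1)
  expect_error(estimate_so2(pair$sti420, pair$sti438, bad_cal), "calibration")
})
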