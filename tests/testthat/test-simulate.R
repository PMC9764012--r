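test_that("null amplitudes and zero noise give constant series", {
  proto <- make_protocol("O2_7to2")
  pop <- simulate_population(proto, constant_spec(), null_kinetics(), seed = 1)
  expect_equal(nrow(pop), 3 * 180)
  expect_true(all(pop$velocity == 300))
  expect_true(all(pop$lineal_density == 50))
  expect_true(all(pop$so2 == 70))
  expect_true(all(pop$supply_rate == 300 * 50 / 1000))
})

test_that("per-capillary baseline draws center on the population mean", {
  proto <- make_protocol("O2_7to2")
  spec <- population_spec(
    10000,
    baseline = list(velocity = c(mean = 228.5, sd = 50),
                    lineal_density = c(mean = 50, sd = 5),
                    so2 = c(mean = 70, sd = 5)),
    amplitude = list(velocity = c(mean = 0, sd = 0),
                     lineal_density = c(mean = 0, sd = 0),
                     so2 = c(mean = 0, sd = 0)),
    noise = c(velocity = 0, lineal_density = 0, so2 = 0))
  # only the first second is needed; shorten the protocol for speed
  short <- make_protocol("short", segments = data.frame(duration = 2, o2 = 7,
                                                        co2 = 5))
  pop <- simulate_population(short, spec, null_kinetics(X0 = 1), seed = 99)
  b <- pop$velocity[pop$t == 1]
  se <- 50 / sqrt(10000)
  expect_lt(abs(mean(b) - 228.5), 3 * se)
})

test_that("a deterministic capillary reproduces the kinetic closed form", {
  proto <- make_protocol("O2_7to2")
  kin <- list(velocity = mono_exp_params(228.5, 60, 116.5, 35.5),
              lineal_density = mono_exp_params(50, 60, 0, 1),
              so2 = mono_exp_params(70, 60, 0, 1))
  spec <- constant_spec(n = 1, velocity = 228.5)
  spec$amplitude$velocity <- c(mean = 116.5, sd = 0)
  pop <- simulate_population(proto, spec, kin, seed = 5)
  expect_equal(pop$velocity[pop$t == 180],
               228.5 + 116.5 * (1 - exp(-120 / 35.5)), tolerance = 1e-12)
  # noiseless population means equal the model at every second
  mu <- eval_mono(1:180, mono_exp_params(228.5, 60, 116.5, 35.5))
  expect_equal(pop$velocity, mu, tolerance = 1e-9)
})

test_that("supply-rate identity holds for every simulated capillary", {
  proto <- make_protocol("CO2_5to10")
  d <- default_population_spec("CO2_5to10", n_capillaries = 8)
  pop <- suppressWarnings(
    simulate_population(proto, d$spec, d$kinetics, seed = 11))
  expect_equal(pop$supply_rate, pop$velocity * pop$lineal_density / 1000,
               tolerance = 1e-9)
  expect_true(all(pop$so2 >= 0 & pop$so2 <= 100))
  expect_true(all(pop$lineal_density >= 0))
})

test_that("simulation is reproducible under a fixed seed and clips with a warning", {
  proto <- make_protocol("O2_7to2")
  d <- default_population_spec("O2_7to2", n_capillaries = 6)
  p1 <- suppressWarnings(simulate_population(proto, d$spec, d$kinetics, seed = 7))
  p2 <- suppressWarnings(simulate_population(proto, d$spec, d$kinetics, seed = 7))
  expect_identical(p1$velocity, p2$velocity)
  expect_identical(p1$so2, p2$so2)
  p3 <- suppressWarnings(simulate_population(proto, d$spec, d$kinetics, seed = 8))
  expect_false(identical(p1$velocity, p3$velocity))

  # an SO2 amplitude that must exceed 100% gets clipped, with a count
  spec <- constant_spec(n = 2, so2 = 90)
  kin <- null_kinetics()
  kin$so2 <- mono_exp_params(90, 61, 40, 5)
  spec$amplitude$so2 <- c(mean = 40, sd = 0)
  expect_warning(pop <- simulate_population(proto, spec, kin, seed = 3),
                 "clipped")
  expect_true(all(pop$so2 <= 100))
  expect_gt(attr(pop, "clipped")[["so2"]], 0)
})

test_that("kinetic delays outside the protocol are rejected", {
  proto <- make_protocol("O2_7to2")  # 180 s
  kin <- null_kinetics()
  kin$velocity <- mono_exp_params(300, 200, 10, 5)
  expect_error(simulate_population(proto, constant_spec(), kin, seed = 1),
               "outside the protocol")
})

test_that("ground truth round-trips through CSV with its JSON sidecar", {
  proto <- make_protocol("O2_7to2")
  pop <- simulate_population(proto, constant_spec(n = 2), null_kinetics(),
                             seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(pop, path)
  back <- read_ground_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
  expect_equal(attr(back, "seed"), 2)
  expect_equal(attr(back, "protocol_name"), "O2_7to2")
})
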