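test_that("delayed mono-exponential evaluates to its closed form", {
  p <- mono_exp_params(Yb = 228.5, X0 = 60, Y0 = 116.5, tau = 35.5)
  # flat baseline before and at the onset instant
  expect_equal(eval_mono(c(1, 30, 59.9, 60), p), rep(228.5, 4))
  # closed-form value one time constant after onset
  expect_equal(eval_mono(95.5, p), 228.5 + 116.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  # asymptote
  expect_equal(eval_mono(1e7, p), 228.5 + 116.5, tolerance = 1e-9)
  expect_error(eval_mono(10, list(Yb = 1, X0 = 1, Y0 = 1, tau = -1)), "tau")
})

test_that("time constant marks 63% of the full response", {
  for (tau in c(1.44, 20, 85.78)) {
    p <- mono_exp_params(Yb = 50, X0 = 61, Y0 = 40, tau = tau)
    frac <- (eval_mono(61 + tau, p) - 50) / 40
    expect_equal(frac, 1 - exp(-1), tolerance = 1e-12)
    expect_equal(round(100 * frac), 63)
  }
})

test_that("two-component model gates each component by its own delay", {
  p <- bi_exp_params(Yb = 259.2, X1 = 60, Y1 = 76.4, tau1 = 23.3,
                     X2 = 120, Y2 = 213.6, tau2 = 85.78)
  expect_equal(eval_bi(c(10, 59.5), p), rep(259.2, 2))
  # second component dormant: equals the mono model between the delays
  pm <- mono_exp_params(259.2, 60, 76.4, 23.3)
  tt <- seq(60, 119.5, by = 0.5)
  expect_equal(eval_bi(tt, p), eval_mono(tt, pm), tolerance = 1e-12)
  # closed-form value at the end of the combined window
  expect_equal(eval_bi(240, p),
               259.2 + 76.4 * (1 - exp(-180 / 23.3)) +
                 213.6 * (1 - exp(-120 / 85.78)),
               tolerance = 1e-12)
  expect_equal(eval_bi(240, p), 496.4366, tolerance = 1e-4)
  expect_error(bi_exp_params(1, 60, 1, 1, 50, 1, 1), "X2")
})

test_that("eval_bi with a null second component equals eval_mono everywhere", {
  p2 <- bi_exp_params(100, 65, 50, 20, 120, 0, 30)
  p1 <- mono_exp_params(100, 65, 50, 20)
  tt <- seq(1, 240, by = 0.25)
  expect_equal(eval_bi(tt, p2), eval_mono(tt, p1), tolerance = 1e-12)
})

test_that("models with positive amplitudes are non-decreasing in time", {
  tt <- seq(1, 240, by = 0.5)
  set.seed(42)
  for (i in 1:20) {
    pm <- mono_exp_params(runif(1, 0, 100), runif(1, 55, 80),
                          runif(1, 1, 100), runif(1, 0.5, 90))
    expect_true(all(diff(eval_mono(tt, pm)) >= 0))
    x1 <- runif(1, 55, 80)
    pb <- bi_exp_params(runif(1, 0, 100), x1, runif(1, 1, 100),
                        runif(1, 0.5, 90), x1 + runif(1, 0, 100),
                        runif(1, 1, 100), runif(1, 0.5, 90))
    expect_true(all(diff(eval_bi(tt, pb)) >= 0))
  }
})

test_that("r_squared matches hand computation and flags degenerate input", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_lt(r_squared(y, c(5, 5, 5)), 0)       # worse than the mean
  expect_warning(r2 <- r_squared(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  expect_true(is.na(r2))
})

test_that("constrained mono fit recovers noiseless generators exactly", {
  t <- 1:180
  cons <- fit_constraints(window = c(51, 180),
                          lower = c(X0 = constraint_gt(60)))
  cases <- list(
    mono_exp_params(100, 65, 50, 20),       # interior delay on the grid
    mono_exp_params(228.5, 60, 116.5, 35.54), # delay at the bound
    mono_exp_params(69.7, 62.3, -27.8, 1.44), # off-grid delay, fast tau
    mono_exp_params(20.3, 75.25, 4.1, 74.75)) # off-grid, slow tau
  for (p in cases) {
    y <- eval_mono(t, p)
    fit <- fit_mono(t, y, cons)
    expect_true(fit$converged)
    expect_lt(fit$ssr, 1e-12 * sum((y - mean(y))^2) + 1e-12)
    for (nm in c("Yb", "Y0", "tau")) {
      expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-6)
    }
    expect_equal(fit$params$X0, p$X0, tolerance = 1e-4)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("mono fit honors pinned delays and restricted windows", {
  t <- 1:180
  p <- mono_exp_params(62.1, 60, 6.1, 5.339)
  y <- eval_mono(t, p)
  fit <- fit_mono(t, y, fit_constraints(window = c(51, 180), pin = c(X0 = 60)))
  expect_equal(fit$params$X0, 60)
  expect_equal(fit$params$tau, 5.339, tolerance = 1e-6)
  # short bolded window, as used for fast saturation transients
  p2 <- mono_exp_params(69.7, 62.3, -27.8, 1.44)
  y2 <- eval_mono(t, p2)
  fit2 <- fit_mono(t, y2, fit_constraints(window = c(51, 90),
                                          lower = c(X0 = constraint_gt(60))))
  expect_equal(fit2$params$tau, 1.44, tolerance = 1e-6)
})

test_that("flat series yields a flagged, tau-free fit", {
  t <- 1:180
  fit <- fit_mono(t, rep(100, 180),
                  options = list(noise_floor = 1e-6))
  expect_true(fit$converged)
  expect_false(fit$identifiable)
  expect_equal(fit$params$Y0, 0, tolerance = 1e-8)
  expect_true(is.na(fit$params$tau))
})

test_that("constrained bi fit recovers noiseless generators", {
  t <- 1:240
  cons <- fit_constraints(window = c(51, 240),
                          lower = c(X1 = constraint_gt(60),
                                    X2 = constraint_gt(120)))
  cases <- list(
    bi_exp_params(259.2, 60, 76.4, 23.3, 120, 213.6, 85.78),
    bi_exp_params(50, 61, 10, 15, 121, 30, 60))
  for (p in cases) {
    y <- eval_bi(t, p)
    fit <- fit_bi(t, y, cons)
    expect_true(fit$converged)
    for (nm in c("Yb", "Y1", "tau1", "Y2", "tau2")) {
      expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-4)
    }
    expect_equal(fit$params$X1, p$X1, tolerance = 1e-3)
    expect_equal(fit$params$X2, p$X2, tolerance = 1e-3)
  }
})

test_that("bi fit on a single-component generator matches the mono fit", {
  t <- 1:240
  p <- mono_exp_params(100, 65, 40, 25)
  y <- eval_mono(t, p)
  fb <- fit_bi(t, y, fit_constraints(window = c(51, 240),
                                     lower = c(X1 = constraint_gt(60),
                                               X2 = constraint_gt(120))))
  fm <- fit_mono(t, y, fit_constraints(window = c(51, 240),
                                       lower = c(X0 = constraint_gt(60))))
  expect_equal(fb$params$Yb, fm$params$Yb, tolerance = 1e-3)
  expect_equal(fb$params$X1, fm$params$X0, tolerance = 1e-2)
  expect_equal(fb$params$tau1, fm$params$tau, tolerance = 1e-2)
  expect_lt(abs(fb$params$Y2), 1e-3 * abs(fm$params$Y0) + 1e-6)
})

test_that("recovered tau is nearly unbiased under 5% amplitude noise", {
  # small-scale version of the full calibration (which the acceptance
  # suite runs with 200 replicates)
  t <- 1:180
  p <- mono_exp_params(228.5, 60, 116.5, 35.54)
  mu <- eval_mono(t, p)
  cons <- fit_constraints(window = c(51, 180),
                          lower = c(X0 = constraint_gt(60)))
  set.seed(101)
  taus <- replicate(30, {
    y <- mu + rnorm(length(t), 0, 0.05 * abs(p$Y0))
    fit_mono(t, y, cons)$params$tau
  })
  expect_lt(abs(mean(taus) / p$tau - 1), 0.1)
})
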