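test_that("second-by-second means are available-case with recorded n", {
  pop <- tibble::tibble(capillary_id = rep(1:3, each = 2),
                        t = rep(c(10, 11), 3),
                        velocity = c(1, 5, 2, 6, 3, NA))
  out <- aggregate_means(pop, "velocity")
  expect_equal(out$mean[out$t == 10], 2)
  expect_equal(out$sd[out$t == 10], 1)
  expect_equal(out$n[out$t == 10], 3L)
  expect_equal(out$n[out$t == 11], 2L)   # missing value excluded
  expect_equal(out$mean[out$t == 11], 5.5)
  expect_equal(out$sem[out$t == 10], 1 / sqrt(3))
})

test_that("noiseless population means reproduce the generating curve", {
  proto <- make_protocol("O2_7to2")
  kin <- list(velocity = mono_exp_params(228.5, 60, 116.5, 35.5),
              lineal_density = mono_exp_params(50, 60, 0, 1),
              so2 = mono_exp_params(70, 60, 0, 1))
  spec <- constant_spec(n = 4, velocity = 228.5)
  spec$amplitude$velocity <- c(mean = 116.5, sd = 0)
  pop <- simulate_population(proto, spec, kin, seed = 1)
  means <- aggregate_means(pop, "velocity")
  expect_equal(means$mean, eval_mono(1:180, kin$velocity), tolerance = 1e-9)
})

test_that("post data identical to baseline is never significant", {
  set.seed(1)
  n <- 25
  vals <- lapply(1:n, function(i) {
    bl <- rnorm(10, 100, 5)
    c(bl, rep(mean(bl), 120))
  })
  pop <- tibble::tibble(capillary_id = rep(1:n, each = 130),
                        t = rep(51:180, n), x = unlist(vals))
  cmp <- dunnett_vs_baseline(pop, "x")
  expect_false(any(cmp$significant))
})

test_that("adjusted p-values dominate raw ones and drop sparse seconds", {
  set.seed(2)
  pop <- null_population(30, t_end = 120)
  pop$x[pop$capillary_id <= 29 & pop$t == 70] <- NA  # one usable pair only
  cmp <- dunnett_vs_baseline(pop, "x", post_window = c(61, 120))
  expect_true(all(cmp$p_adj >= cmp$p_raw, na.rm = TRUE))
  expect_true(is.na(cmp$p_adj[cmp$t == 70]))
  expect_equal(cmp$n[cmp$t == 70], 1L)
})

test_that("a strong step is detected within seconds at scale", {
  set.seed(3)
  n <- 300
  Y <- matrix(rnorm(n * 130), n, 130)
  Y[, 11:130] <- Y[, 11:130] + 2  # 2 baseline-SD shift from t = 61 on
  pop <- tibble::tibble(capillary_id = rep(seq_len(n), each = 130),
                        t = rep(51:180, n), x = as.vector(t(Y)))
  cmp <- dunnett_vs_baseline(pop, "x")
  expect_lte(min(cmp$t[cmp$significant]), 65)
})

test_that("onset and peak extraction follows first-crossing and extremum rules", {
  tt <- 51:180
  means <- tibble::tibble(t = tt,
                          mean = ifelse(tt <= 60, 100, 100 + (tt - 60)),
                          sd = 5)
  cmp <- tibble::tibble(t = 61:180,
                        p_adj = c(0.2, 0.04, 0.03, rep(0.001, 117)))
  out <- find_onset_and_peak(means, cmp, step_time = 60)
  expect_equal(out$onset_time, 62)      # first adjusted p < 0.05
  expect_equal(out$peak_time, 180)      # boundary extremum, rising to the end
  expect_equal(out$direction, "up")
  expect_equal(out$baseline_mean, 100)
  expect_equal(out$percent_change, 100 * (220 - 100) / 100)
})

test_that("no significant second produces an all-NA summary row", {
  tt <- 51:180
  means <- tibble::tibble(t = tt, mean = rnorm(length(tt), 100, 0.1), sd = 5)
  cmp <- tibble::tibble(t = 61:180, p_adj = runif(120, 0.2, 1))
  out <- find_onset_and_peak(means, cmp, step_time = 60)
  expect_true(is.na(out$onset_time))
  expect_true(is.na(out$peak_time))
  expect_true(is.na(out$onset_p))
  expect_true(is.na(out$percent_change))
  expect_false(is.na(out$baseline_mean))  # baseline is still reported
})

test_that("onset times are invariant to affine rescaling of the measure", {
  set.seed(4)
  n <- 80
  Y <- matrix(rnorm(n * 130, 100, 10), n, 130)
  Y[, 20:130] <- Y[, 20:130] + 8
  mk <- function(a, b) {
    tibble::tibble(capillary_id = rep(seq_len(n), each = 130),
                   t = rep(51:180, n), x = as.vector(t(a * Y + b)))
  }
  base <- mk(1, 0); scaled <- mk(3.7, -250)
  c1 <- dunnett_vs_baseline(base, "x")
  c2 <- dunnett_vs_baseline(scaled, "x")
  m1 <- aggregate_means(base, "x")
  m2 <- aggregate_means(scaled, "x")
  o1 <- find_onset_and_peak(m1, c1, step_time = 60)
  o2 <- find_onset_and_peak(m2, c2, step_time = 60)
  expect_equal(o1$onset_time, o2$onset_time)
  expect_equal(o1$peak_time, o2$peak_time)
  # percent change is invariant under pure positive scaling (b = 0)
  c3 <- dunnett_vs_baseline(mk(3.7, 0), "x")
  m3 <- aggregate_means(mk(3.7, 0), "x")
  o3 <- find_onset_and_peak(m3, c3, step_time = 60)
  expect_equal(o3$percent_change, o1$percent_change, tolerance = 1e-9)
})

test_that("percent change follows its arithmetic definition", {
  expect_equal(percent_change(228.5, 353.2), 100 * (353.2 - 228.5) / 228.5)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 50), -50)
  expect_warning(pc <- percent_change(0, 10), "zero baseline")
  expect_true(is.na(pc))
})

test_that("fast high-gain responses onset before slow ones", {
  # SO2-like kinetics (tau ~ 1.4 s) versus velocity-like (tau ~ 35 s) at
  # matched signal-to-noise: the fast measure reaches significance first
  set.seed(5)
  n <- 120
  t_all <- 51:180
  fast <- eval_mono(t_all, mono_exp_params(0, 61, 5, 1.4))
  slow <- eval_mono(t_all, mono_exp_params(0, 61, 5, 35))
  wins <- replicate(20, {
    mk <- function(mu) tibble::tibble(
      capillary_id = rep(seq_len(n), each = length(t_all)),
      t = rep(t_all, n),
      x = rep(mu, n) + rnorm(n * length(t_all), 0, 5))
    cf <- dunnett_vs_baseline(mk(fast), "x")
    cs <- dunnett_vs_baseline(mk(slow), "x")
    of <- suppressWarnings(min(cf$t[cf$significant]))
    os <- suppressWarnings(min(cs$t[cs$significant]))
    of <= os
  })
  expect_gte(mean(wins), 0.95)
})

test_that("onset_table assembles one summary row per measure", {
  proto <- make_protocol("O2_7to2")
  d <- default_population_spec("O2_7to2", n_capillaries = 40)
  pop <- suppressWarnings(simulate_population(proto, d$spec, d$kinetics,
                                              seed = 6))
  tab <- onset_table(pop)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$measure, c("velocity", "lineal_density", "hematocrit",
                                 "supply_rate", "so2"))
  # the 7-2% challenge raises velocity and lowers saturation
  expect_equal(tab$direction[tab$measure == "velocity"], "up")
  expect_equal(tab$direction[tab$measure == "so2"], "down")
  expect_true(all(tab$onset_time > 60, na.rm = TRUE))
})
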