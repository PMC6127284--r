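# Crest (time-to-peak) and leading-edge velocity estimators, and the
# two-population summary.

triangle <- function(times, peak_t, width = 40) {
  pmax(0, 1 - abs(times - peak_t) / width)
}

test_that("time to peak converts to velocity as label / t", {
  times <- seq(0, 120, by = 5)
  w <- make_wave(list(distal_10 = triangle(times, 50),
                      distal_15 = triangle(times, 75)), times)
  est <- peak_velocity(w, bins = c(10, 15))
  expect_equal(est$per_bin$t_peak, c(50, 75))
  expect_equal(est$per_bin$velocity, c(0.2, 0.2))
  expect_equal(est$velocity, 0.2)
})

test_that("peaks on the window boundary exclude the bin", {
  times <- seq(0, 120, by = 15)
  w <- make_wave(list(distal_10 = rev(seq_along(times)),   # peak at t = 0
                      distal_15 = seq_along(times)),       # peak at final frame
                 times)
  est <- peak_velocity(w, bins = c(10, 15))
  expect_true(all(est$per_bin$excluded))
  expect_true(is.na(est$velocity))
  expect_equal(est$n_bins_used, 0L)
})

test_that("tied maxima resolve to the earliest timepoint", {
  times <- seq(0, 60, by = 15)
  v <- c(0, 1, 1, 1, 0)
  w <- make_wave(list(distal_10 = v), times)
  est <- peak_velocity(w, bins = 10)
  expect_equal(est$per_bin$t_peak, 15)
})

test_that("leading-edge appearance converts to velocity as label / t", {
  times <- seq(0, 120, by = 6)
  step <- function(t_on) as.numeric(times >= t_on) * 0.5
  w <- make_wave(list(distal_25 = step(30), distal_40 = step(48)), times)
  est <- edge_velocity(w, bins = c(25, 30, 35, 40))
  pb <- est$per_bin
  expect_equal(pb$t_appear[pb$bin == 25], 30)
  expect_equal(pb$t_appear[pb$bin == 40], 48)
  expect_equal(pb$velocity[pb$bin == 25], 25 / 30, tolerance = 1e-12)
  expect_equal(pb$velocity[pb$bin == 40], 40 / 48, tolerance = 1e-12)
  expect_equal(pb$reason[pb$bin %in% c(30, 35)], rep("absent", 2))
  expect_equal(est$velocity, mean(c(25 / 30, 40 / 48)), tolerance = 1e-12)
})

test_that("a slow-only wave never reaches the edge bins", {
  # slow pool reach within the window: v_slow * 90 s + ROI halfwidth =
  # 20.5 um, short of sustained presence in the 25-um bin
  cfg <- sim_config(frac_stationary = 0.3, frac_slow_distal = 0.35,
                    frac_slow_proximal = 0.35, frac_fast_distal = 0,
                    frac_fast_proximal = 0, diffusion_slow = 0,
                    noise_on = FALSE, seed = 21)
  w <- simulate_wave_set(1, cfg, window = 90)[[1]]
  est <- edge_velocity(w)
  expect_true(is.na(est$velocity))
  expect_true(all(est$per_bin$reason == "no appearance"))
})

test_that("pure advection recovers the configured velocity up to discretisation", {
  # fine time grid so the peak lands on a frame: v = 0.25, peaks at 40/60 s
  cfg <- sim_config(n_particles = 200, frac_stationary = 0,
                    frac_slow_distal = 1, frac_slow_proximal = 0,
                    frac_fast_distal = 0, frac_fast_proximal = 0,
                    v_slow = 0.25, diffusion_slow = 0, noise_on = FALSE,
                    frame_interval = 5, duration = 120, seed = 31)
  w <- simulate_wave_set(1, cfg, window = 120)[[1]]
  est <- peak_velocity(w, bins = c(10, 15))
  expect_equal(est$per_bin$t_peak, c(40, 60))
  expect_equal(est$velocity, 0.25, tolerance = 1e-9)

  cfgf <- sim_config(n_particles = 200, frac_stationary = 0,
                     frac_slow_distal = 0, frac_slow_proximal = 0,
                     frac_fast_distal = 1, frac_fast_proximal = 0,
                     v_fast = 0.5, v_fast_cv = 0, diffusion_slow = 0,
                     noise_on = FALSE, frame_interval = 5, duration = 120,
                     dendrite_length = 140, seed = 32)
  wf <- simulate_wave_set(1, cfgf, window = 120)[[1]]
  estf <- edge_velocity(wf)
  # appearance is detected as the plug enters each bin; with the label
  # distance convention the estimate sits within ~15% of the true speed
  expect_false(is.na(estf$velocity))
  expect_lt(abs(estf$velocity - 0.5) / 0.5, 0.15)
})

test_that("time to peak increases strictly with bin label for an advective pulse", {
  cfg <- sim_config(n_particles = 400, frac_stationary = 0,
                    frac_slow_distal = 1, frac_slow_proximal = 0,
                    frac_fast_distal = 0, frac_fast_proximal = 0,
                    v_slow = 0.3, diffusion_slow = 0, noise_on = FALSE,
                    frame_interval = 2, duration = 150, seed = 33)
  w <- simulate_wave_set(1, cfg, window = 150)[[1]]
  est <- peak_velocity(w, bins = seq(5, 35, by = 5))
  tp <- est$per_bin$t_peak[!est$per_bin$excluded]
  expect_true(all(diff(tp) > 0))
})

test_that("halving the frame interval reduces discretisation error", {
  err <- sapply(c(15, 7.5), function(dt) {
    cfg <- sim_config(n_particles = 400, frac_stationary = 0,
                      frac_slow_distal = 1, frac_slow_proximal = 0,
                      frac_fast_distal = 0, frac_fast_proximal = 0,
                      v_slow = 0.22, diffusion_slow = 0, noise_on = FALSE,
                      frame_interval = dt, duration = 120, seed = 34)
    w <- simulate_wave_set(1, cfg, window = 120)[[1]]
    abs(peak_velocity(w, bins = c(10, 15))$velocity - 0.22)
  })
  expect_lte(err[2], err[1])
})

test_that("estimators recover both population velocities over 50 simulations", {
  cfg <- sim_config(seed = 41)
  waves <- simulate_wave_set(50, cfg)
  tab <- velocity_table(waves)
  peak_bias <- abs(mean(tab$peak_velocity, na.rm = TRUE) - cfg$v_slow) / cfg$v_slow
  edge_bias <- abs(mean(tab$edge_velocity, na.rm = TRUE) - cfg$v_fast) / cfg$v_fast
  expect_lt(peak_bias, 0.15)
  expect_lt(edge_bias, 0.15)
  # RMSE is finite and reported at sane scale
  rmse <- sqrt(mean((tab$edge_velocity - cfg$v_fast)^2, na.rm = TRUE))
  expect_lt(rmse, cfg$v_fast)
})

test_that("population classification distinguishes slow and fast classes", {
  waves <- simulate_wave_set(20, sim_config(seed = 42))
  summ <- classify_populations(velocity_table(waves))
  expect_identical(summ$n_populations, 2L)
  expect_lt(summ$slow[["mean"]], summ$fast[["mean"]])

  # identical estimators -> one population
  same <- data.frame(neuron = 1:5, peak_velocity = rep(0.3, 5),
                     edge_velocity = rep(0.3, 5))
  expect_identical(classify_populations(same)$n_populations, 1L)

  # empty input -> zero populations
  empty <- data.frame(neuron = integer(), peak_velocity = numeric(),
                      edge_velocity = numeric())
  expect_identical(classify_populations(empty)$n_populations, 0L)

  # fewer than three usable neurons -> flagged undefined
  two <- data.frame(neuron = 1:2, peak_velocity = c(0.2, 0.21),
                    edge_velocity = c(0.8, 0.82))
  out <- classify_populations(two)
  expect_true(out$insufficient)
  expect_true(is.na(out$n_populations))
})
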