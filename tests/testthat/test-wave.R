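# Bin extraction geometry, raw intensity measurement and double
# normalisation.

test_that("straight centred trace yields complete 5..40-um bins both ways", {
  tr <- dendrite_trace(cbind(c(0, 100), c(3, 3)), local_width = 3.5,
                       roi_centre = 50, roi_halfwidth = 2.5)
  g <- extract_bins(tr, list(dims = c(30L, 500L), pixel_size = 0.2))
  for (dirn in c("distal", "proximal")) {
    b <- g$bins[g$bins$direction == dirn & !g$bins$truncated, ]
    expect_true(all(seq(5, 40, by = 5) %in% b$label))
  }
  expect_equal(g$bins$label[g$bins$direction == "centre"], 0)
  # interior bins span 5 x 3.5 um of ribbon
  interior <- g$bins[g$bins$direction == "distal" & g$bins$label <= 40, ]
  expect_equal(interior$area_um2, rep(5 * 3.5, nrow(interior)), tolerance = 0.05)
})

test_that("a trace extending 12 um distal gives bins 5, 10 complete and 15 truncated", {
  # ROI at 35 +/- 2.5 on a 50-um trace: distal extent = 50 - 37.5 = 12.5 um
  tr <- dendrite_trace(cbind(c(0, 50), c(2, 2)), local_width = 2,
                       roi_centre = 35, roi_halfwidth = 2.5)
  g <- extract_bins(tr, list(dims = c(20L, 250L), pixel_size = 0.2))
  d <- g$bins[g$bins$direction == "distal", ]
  expect_equal(d$label[!d$truncated], c(5, 10))
  expect_true(d$truncated[d$label == 15])
})

test_that("one-sided traces warn and return no bins on the short side", {
  tr <- dendrite_trace(cbind(c(0, 30), c(2, 2)), local_width = 2,
                       roi_centre = 3, roi_halfwidth = 2.5)
  expect_warning(
    g <- extract_bins(tr, list(dims = c(20L, 150L), pixel_size = 0.2)),
    "proximal")
  expect_equal(sum(g$bins$direction == "proximal"), 0L)
})

test_that("semicircular trace bins by arc length, matching dense-sampling oracle", {
  r <- 60 / pi  # semicircle arc length 60 um
  theta <- seq(0, pi, length.out = 101)
  poly <- cbind(25 + r * cos(theta), 25 - r * sin(theta))
  tr <- dendrite_trace(poly, local_width = 2, roi_centre = 30,
                       roi_halfwidth = 2.5)
  dims <- c(150L, 250L); px <- 0.2
  g <- extract_bins(tr, list(dims = dims, pixel_size = px))

  # oracle: nearest point on a densely sampled arc; pixels prefiltered by a
  # coarse distance to the trace vertices (keeps every pixel within the
  # 1-um ribbon, vertex spacing is 1.5 um)
  td <- seq(0, pi, length.out = 5001)
  dense <- cbind(25 + r * cos(td), 25 - r * sin(td))
  arc_d <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  xc <- rep((seq_len(dims[2]) - 0.5) * px, each = dims[1])
  yc <- rep((seq_len(dims[1]) - 0.5) * px, times = dims[2])
  dv <- apply(cbind(xc, yc), 1L, function(p) {
    min((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
  })
  cand <- which(dv <= 4)
  s <- rep(NA_real_, length(xc))
  in_rib <- rep(FALSE, length(xc))
  for (j in cand) {
    d2 <- (dense[, 1] - xc[j])^2 + (dense[, 2] - yc[j])^2
    i <- which.min(d2)
    s[j] <- arc_d[i]
    in_rib[j] <- sqrt(d2[i]) <= 1
  }
  lab_oracle <- function(direction) {
    if (direction == "distal") pmax(0, s - 32.5) else pmax(0, 27.5 - s)
  }
  for (dirn in c("distal", "proximal")) {
    ds <- lab_oracle(dirn)
    for (b in seq(5, 25, by = 5)) {
      n_oracle <- sum(in_rib & ds > b - 5 & ds <= b)
      n_pkg <- g$bins$n_px[g$bins$direction == dirn & g$bins$label == b]
      expect_lt(abs(n_pkg - n_oracle) / n_oracle, 0.01)
    }
  }
})

test_that("raw bin values equal brute-force per-pixel summation", {
  cfg <- sim_config(n_particles = 50, duration = 45, seed = 8)
  sim <- simulate_pulse_chase(cfg)
  g <- extract_bins(sim_trace(cfg), sim$movie)
  raw <- measure_bins(sim$movie, g)
  for (k in seq_along(raw$timepoints)) {
    fr <- sim$movie$frames[, , k]
    for (i in seq_len(nrow(g$bins))) {
      co <- arrayInd(g$masks[[i]], dim(fr))
      brute <- 0
      for (j in seq_len(nrow(co))) brute <- brute + fr[co[j, 1], co[j, 2]]
      expect_equal(unname(raw$values[i, k]), brute)
    }
  }
})

test_that("uniform frames and background handling behave arithmetically", {
  tr <- dendrite_trace(cbind(c(0, 20), c(2, 2)), local_width = 2,
                       roi_centre = 10, roi_halfwidth = 2.5)
  frames <- array(7, dim = c(20, 100, 3))
  mv <- pc_movie(frames, pixel_size = 0.2, frame_interval = 10)
  g <- extract_bins(tr, mv)
  raw0 <- measure_bins(mv, g)
  expect_equal(unname(raw0$values[1, ]), rep(g$bins$n_px[1] * 7, 3))
  # background equal to the frame value zeroes everything
  raw7 <- measure_bins(mv, g, background = 7)
  expect_true(all(abs(raw7$values) < 1e-9))
  # off-cell region mean matches the constant for a uniform frame
  bgmask <- matrix(FALSE, 20, 100); bgmask[1:2, ] <- TRUE
  rawm <- measure_bins(mv, g, background = bgmask)
  expect_equal(rawm$values, raw7$values)
})

test_that("background region overlapping the dendrite bins is rejected", {
  tr <- dendrite_trace(cbind(c(0, 20), c(2, 2)), local_width = 2,
                       roi_centre = 10, roi_halfwidth = 2.5)
  mv <- pc_movie(array(1, dim = c(20, 100, 2)), 0.2, 10)
  g <- extract_bins(tr, mv)
  bad <- matrix(TRUE, 20, 100)
  expect_error(measure_bins(mv, g, background = bad), "overlaps")
})

test_that("normalisation sets bin zero at t = 0 to exactly 1 and is gain-invariant", {
  cfg <- sim_config(n_particles = 80, duration = 60, seed = 10)
  sim <- simulate_pulse_chase(cfg)
  tr <- sim_trace(cfg)
  w1 <- pulse_wave(sim$movie, tr, background = sim_background_mask(cfg))
  expect_identical(w1$value[w1$direction == "centre" & w1$time_s == 0], 1)
  gained <- sim$movie
  gained$frames <- gained$frames * 3.7
  w2 <- pulse_wave(gained, tr, background = sim_background_mask(cfg))
  expect_equal(w2$value, w1$value, tolerance = 1e-12)
})

test_that("bins proportional to area at t0 normalise to 1 everywhere", {
  # uniform frame: every bin's density equals bin zero's density
  tr <- dendrite_trace(cbind(c(0, 40), c(2, 2)), local_width = 2,
                       roi_centre = 20, roi_halfwidth = 2.5)
  mv <- pc_movie(array(5, dim = c(20, 200, 2)), 0.2, 15)
  w <- normalise_wave(measure_bins(mv, extract_bins(tr, mv)))
  expect_equal(w$value, rep(1, nrow(w)), tolerance = 1e-9)
})

test_that("zero ROI signal is a hard error", {
  tr <- dendrite_trace(cbind(c(0, 20), c(2, 2)), local_width = 2,
                       roi_centre = 10, roi_halfwidth = 2.5)
  mv <- pc_movie(array(2, dim = c(20, 100, 2)), 0.2, 10)
  raw <- measure_bins(mv, extract_bins(tr, mv), background = 2)
  expect_error(normalise_wave(raw), "no photoconverted signal")
})

test_that("trace vertex density barely changes bin areas or wave values", {
  cfg <- sim_config(n_particles = 80, duration = 60, seed = 12)
  sim <- simulate_pulse_chase(cfg)
  t1 <- sim_trace(cfg)
  xs <- seq(0, cfg$dendrite_length, length.out = 21)
  t2 <- dendrite_trace(cbind(xs, rep(t1$polyline[1, 2], 21)),
                       local_width = t1$local_width,
                       roi_centre = t1$roi_centre,
                       roi_halfwidth = t1$roi_halfwidth)
  g1 <- extract_bins(t1, sim$movie); g2 <- extract_bins(t2, sim$movie)
  common <- intersect(names(g1$masks), names(g2$masks))
  a1 <- g1$bins$area_um2[match(common, names(g1$masks))]
  a2 <- g2$bins$area_um2[match(common, names(g2$masks))]
  expect_true(all(abs(a1 - a2) / a1 < 0.01))
  w1 <- normalise_wave(measure_bins(sim$movie, g1))
  w2 <- normalise_wave(measure_bins(sim$movie, g2))
  m <- merge(as.data.frame(w1), as.data.frame(w2),
             by = c("direction", "bin", "time_s"))
  big <- abs(m$value.x) > 0.05
  expect_true(all(abs(m$value.x - m$value.y)[big] / abs(m$value.x[big]) < 0.01))
})

test_that("noise-free area-weighted wave mass is conserved over time", {
  # duration short enough that no particle reaches the absorbing tip
  cfg <- sim_config(n_particles = 150, noise_on = FALSE, duration = 30,
                    seed = 13)
  sim <- simulate_pulse_chase(cfg)
  w <- pulse_wave(sim$movie, sim_trace(cfg), window = NULL)
  areas <- attr(w, "areas")
  w$area <- areas[paste(w$direction, w$bin, sep = "_")]
  mass <- tapply(w$value * w$area, w$time_s, sum)
  expect_lt(diff(range(mass)) / mean(mass), 0.01)
})
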