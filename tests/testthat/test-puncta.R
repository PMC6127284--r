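# 3D puncta segmentation, dendrite-normalised metrics, nanodomain detection
# and cluster profiling.

test_that("an empty volume yields an empty puncta set", {
  vol <- array(0, c(16, 16, 8))
  ps <- segment_puncta(vol, c(0.05, 0.05, 0.125), threshold = 0.5)
  expect_identical(nrow(ps$objects), 0L)
  m <- puncta_metrics(ps, array(TRUE, dim(vol)))
  expect_identical(m$n_objects, 0L)
  expect_identical(m$puncta_density, 0)
})

test_that("disjoint spheres are segmented with near-analytic volumes", {
  vox <- c(0.05, 0.05, 0.05)
  shape <- c(60L, 60L, 60L)
  centres <- as.matrix(expand.grid(x = c(0.8, 1.6, 2.4), y = c(0.8, 1.6, 2.4),
                                   z = c(1, 2)))[1:10, ]
  axes <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * vox[ax])
  vol <- array(0, shape)
  r <- 0.3
  for (i in seq_len(nrow(centres))) {
    d2 <- outer(outer((axes[[1]] - centres[i, 1])^2,
                      (axes[[2]] - centres[i, 2])^2, "+"),
                (axes[[3]] - centres[i, 3])^2, "+")
    vol <- vol + (d2 <= r^2) * 1
  }
  ps <- segment_puncta(vol, vox, threshold = 0.5, split = FALSE)
  expect_identical(nrow(ps$objects), 10L)
  analytic <- 4 / 3 * pi * r^3
  expect_true(all(abs(ps$objects$volume_um3 - analytic) / analytic < 0.15))
})

test_that("touching blobs split with watershed, merge without", {
  vol <- two_blob_volume(sep_vox = 5)
  vox <- c(0.05, 0.05, 0.05)
  merged <- segment_puncta(vol, vox, threshold = 0.2, split = FALSE,
                           min_volume = 0)
  expect_identical(nrow(merged$objects), 1L)
  # oracle: the synthetic field has exactly two local maxima above threshold
  n_max <- length(dendrawave:::local_maxima_3d(vol, threshold = 0.2))
  expect_identical(n_max, 2L)
  split <- segment_puncta(vol, vox, threshold = 0.2, split = TRUE,
                          min_volume = 0, smoothing_sigma = 0.05,
                          tolerance = 0.01)
  expect_identical(nrow(split$objects), 2L)
})

test_that("plain segmentation equals brute-force 26-connected labelling", {
  set.seed(7)
  vol <- array(0, c(24, 24, 12))
  for (i in 1:6) {
    c0 <- c(sample(4:21, 2), sample(3:10, 1))
    vol[c0[1] + (-1:1), c0[2] + (-1:1), c0[3] + (0:1)] <- runif(18, 0.6, 1)
  }
  binary <- vol > 0.5
  lab_pkg <- label_components_3d(binary)
  lab_oracle <- flood_fill_labels(binary)
  expect_identical(max(lab_pkg), max(lab_oracle))
  # identical partitions: label pairs must be in bijection
  fg <- which(binary)
  expect_identical(length(unique(paste(lab_pkg[fg], lab_oracle[fg]))),
                   as.integer(max(lab_pkg)))
})

test_that("metrics are ratios to dendrite volume and scale accordingly", {
  vox <- c(0.1, 0.1, 0.1)
  vol <- array(0, c(40, 20, 20))
  vol[4:6, 4:6, 4:6] <- 1
  vol[14:16, 8:10, 8:10] <- 1
  ps <- segment_puncta(vol, vox, threshold = 0.5, split = FALSE)
  mask1 <- array(FALSE, dim(vol)); mask1[1:20, , ] <- TRUE
  mask2 <- array(TRUE, dim(vol))  # double the volume
  m1 <- puncta_metrics(ps, mask1)
  m2 <- puncta_metrics(ps, mask2)
  expect_equal(m1$puncta_density, 2 / (20 * 20 * 20 * 0.001))
  expect_equal(m2$puncta_density, m1$puncta_density / 2)
  expect_equal(m2$total_surface_volume, m1$total_surface_volume / 2)
  expect_equal(m2$mean_puncta_volume, m1$mean_puncta_volume / 2)
})

test_that("metrics ignore objects outside the dendrite mask", {
  vox <- c(0.1, 0.1, 0.1)
  vol <- array(0, c(40, 20, 20))
  vol[4:6, 4:6, 4:6] <- 1      # inside mask
  vol[30:32, 8:10, 8:10] <- 1  # outside mask
  ps <- segment_puncta(vol, vox, threshold = 0.5, split = FALSE)
  mask <- array(FALSE, dim(vol)); mask[1:20, , ] <- TRUE
  expect_identical(puncta_metrics(ps, mask)$n_objects, 1L)
})

test_that("segmentation with automatic threshold is gain-invariant", {
  v <- make_coloc_volume(volume_spec(seed = 9))
  ps1 <- segment_puncta(v$channelA, v$voxel_size, mask = v$mask)
  ps2 <- segment_puncta(v$channelA * 6.5, v$voxel_size, mask = v$mask)
  expect_identical(ps1$labels, ps2$labels)
  m1 <- puncta_metrics(ps1, v$mask); m2 <- puncta_metrics(ps2, v$mask)
  expect_equal(m1$puncta_density, m2$puncta_density)
  expect_equal(m1$total_surface_volume, m2$total_surface_volume)
})

test_that("generator ground truth matches segmented metrics within voxel error", {
  pun <- expand.grid(x = c(0.6, 1.3, 2.0, 2.7), y = c(1.1, 2.1), z = 2)
  pun$rx <- 0.15; pun$ry <- 0.15; pun$rz <- 0.2
  spec <- volume_spec(puncta = pun, cluster_sizes = c(1, 1),
                      background = 0, noise_sd = 0, seed = 14)
  v <- make_coloc_volume(spec)
  ps <- segment_puncta(v$channelA, v$voxel_size, threshold = 0.5, split = TRUE)
  expect_equal(nrow(ps$objects), nrow(v$truth$puncta))
  # per-object voxelised volumes near the analytic half-max volumes
  expect_equal(sum(ps$objects$volume_um3), sum(v$truth$puncta$volume_um3),
               tolerance = 0.2)
})

test_that("nanodomain detection finds isolated blobs and suppresses near pairs", {
  vox <- c(0.05, 0.05, 0.05)
  shape <- c(48L, 48L, 24L)
  mk <- function(centres) {
    axes <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * vox[ax])
    vol <- array(0, shape)
    for (i in seq_len(nrow(centres))) {
      vol <- vol + exp(-0.5 * (outer(outer(
        ((axes[[1]] - centres[i, 1]) / 0.1)^2,
        ((axes[[2]] - centres[i, 2]) / 0.1)^2, "+"),
        ((axes[[3]] - centres[i, 3]) / 0.1)^2, "+")))
    }
    vol
  }
  one <- mk(cbind(1.2, 1.2, 0.6))
  c1 <- detect_nanodomains(one, vox, threshold = 0.3)
  expect_identical(nrow(c1), 1L)
  expect_true(all(abs(c1 - c(1.2, 1.2, 0.6)) <= vox + 1e-9))

  far <- mk(rbind(c(0.8, 1.2, 0.6), c(1.6, 1.2, 0.6)))   # 0.8 um apart
  expect_identical(nrow(detect_nanodomains(far, vox, threshold = 0.3,
                                           min_separation = 0.2)), 2L)
  near <- mk(rbind(c(1.1, 1.2, 0.6), c(1.25, 1.2, 0.6))) # 0.15 um apart
  expect_identical(nrow(detect_nanodomains(near, vox, threshold = 0.3,
                                           min_separation = 0.2)), 1L)
})

test_that("cluster profiling recovers planted layouts exactly", {
  # layout {1, 1, 2, 3}: all inter-cluster gaps >> link, in-cluster gaps < link
  layout <- list(cbind(0.5, 0.5, 0.5),
                 cbind(2.5, 0.5, 0.5),
                 rbind(c(0.5, 2.5, 0.5), c(0.7, 2.5, 0.5)),
                 rbind(c(2.5, 2.5, 0.5), c(2.7, 2.5, 0.5), c(2.9, 2.5, 0.5)))
  centres <- do.call(rbind, layout)
  cp <- cluster_nanodomains(centres, linking_distance = 0.3,
                            dendrite_volume = 10)
  expect_equal(as.vector(cp$histogram), c(2, 1, 1))
  expect_equal(names(cp$histogram), c("1", "2", "3"))
  expect_equal(cp$single_nanodomain_density, 2 / 10)
  # chain transitivity: single linkage joins consecutive near neighbours
  chain <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.5, 0, 0))
  expect_equal(cluster_nanodomains(chain, 0.3)$sizes, 3L)
  # all-distant centres are all singletons
  apart <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(as.vector(cluster_nanodomains(apart, 0.3)$histogram), 3)
})

test_that("cluster profile is invariant to ordering and rigid translation", {
  set.seed(5)
  centres <- matrix(runif(30, 0, 3), ncol = 3)
  cp1 <- cluster_nanodomains(centres, 0.5)
  cp2 <- cluster_nanodomains(centres[sample(10), ], 0.5)
  cp3 <- cluster_nanodomains(sweep(centres, 2, c(5, -2, 1), "+"), 0.5)
  expect_equal(sort(cp1$sizes), sort(cp2$sizes))
  expect_identical(cp1$histogram, cp3$histogram)
})

test_that("size-weighted histogram total equals the nanodomain count", {
  set.seed(6)
  centres <- matrix(runif(45, 0, 2.5), ncol = 3)
  cp <- cluster_nanodomains(centres, 0.4)
  sizes <- as.integer(names(cp$histogram))
  expect_identical(sum(sizes * as.vector(cp$histogram)), 15L)
})

test_that("full volume pipeline recovers a planted cluster layout", {
  base <- c(1.6, 2)  # (y, z) around the dendrite axis
  layout <- list(cbind(0.5, base[1], base[2]),
                 cbind(2.7, base[1], base[2]),
                 rbind(c(1.3, base[1], base[2]), c(1.3, base[1] + 0.5, base[2])),
                 rbind(c(2.0, base[1], base[2]), c(2.0, base[1] + 0.5, base[2]),
                       c(2.0, base[1], base[2] + 0.5)))
  spec <- volume_spec(cluster_layout = layout, n_puncta = 2,
                      coloc_fraction = 0, background = 0, noise_sd = 0,
                      seed = 15)
  v <- make_coloc_volume(spec)
  nd <- detect_nanodomains(v$channelB, v$voxel_size, threshold = 0.3)
  expect_identical(nrow(nd), 7L)
  cp <- cluster_nanodomains(nd, linking_distance = 0.6)
  expect_equal(as.vector(cp$histogram), as.vector(v$truth$histogram))
})
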