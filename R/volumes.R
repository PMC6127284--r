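#' Specification of a synthetic two-channel 3D volume
#'
#' Describes a dendrite-segment volume with channel-A surface receptor
#' puncta (Gaussian ellipsoid blobs) and channel-B scaffold nanodomains
#' arranged in clusters, with a controlled co-placement probability between
#' the channels. Geometry ground truth (exact punctum count, per-punctum
#' voxelised volume, cluster-size histogram, planted overlap) is returned by
#' [make_coloc_volume()] alongside the rendered volumes.
#'
#' Blob "radii" are half-max semi-axes: the rendered Gaussian equals half its
#' peak intensity exactly on the ellipsoid with those semi-axes, so the
#' half-max voxelised volume of an isolated blob approximates
#' `4/3 * pi * prod(radii)`.
#'
#' @param shape volume dimensions in voxels `(nx, ny, nz)`.
#' @param voxel_size voxel edge lengths in um per axis (anisotropy allowed).
#' @param n_puncta number of channel-A puncta (ignored if `puncta` given).
#' @param puncta optional explicit channel-A punctum table: data frame with
#'   columns `x`, `y`, `z` (um), `rx`, `ry`, `rz` (um) and `intensity`.
#' @param radii default channel-A semi-axes (um) used when generating puncta.
#' @param cluster_sizes sizes of the channel-B nanodomain clusters, e.g.
#'   `c(1, 1, 2, 3)` (ignored if `cluster_layout` given).
#' @param cluster_layout optional explicit layout: list of matrices of
#'   nanodomain centres (um), one matrix per cluster.
#' @param nanodomain_radius channel-B blob half-max radius (um, isotropic).
#' @param cluster_spread RMS displacement of nanodomains about their cluster
#'   centre (um).
#' @param coloc_fraction probability that a channel-A punctum is co-placed
#'   with (centred on) a randomly chosen channel-B nanodomain.
#' @param dendrite_radius radius (um) of the cylindrical dendrite mask, axis
#'   along x through the volume centre.
#' @param background,noise_sd additive background level and Gaussian noise SD
#'   applied to both channels (set both 0 for noise-free bookkeeping tests).
#' @param intensity peak intensity of generated blobs.
#' @param seed integer seed.
#' @return A `volume_spec` object.
#' @export
volume_spec <- function(shape = c(64L, 64L, 32L),
                        voxel_size = c(0.05, 0.05, 0.125),
                        n_puncta = 12L,
                        puncta = NULL,
                        radii = c(0.15, 0.15, 0.2),
                        cluster_sizes = c(1L, 1L, 1L, 2L, 2L, 3L),
                        cluster_layout = NULL,
                        nanodomain_radius = 0.12,
                        cluster_spread = 0.25,
                        coloc_fraction = 0.5,
                        dendrite_radius = 1.2,
                        background = 0.02,
                        noise_sd = 0.01,
                        intensity = 1,
                        seed = 1L) {
  spec <- list(shape = as.integer(shape), voxel_size = rep(voxel_size, length.out = 3L),
               n_puncta = as.integer(n_puncta), puncta = puncta, radii = radii,
               cluster_sizes = as.integer(cluster_sizes),
               cluster_layout = cluster_layout,
               nanodomain_radius = nanodomain_radius,
               cluster_spread = cluster_spread,
               coloc_fraction = coloc_fraction,
               dendrite_radius = dendrite_radius,
               background = background, noise_sd = noise_sd,
               intensity = intensity, seed = as.integer(seed))
  if (spec$coloc_fraction < 0 || spec$coloc_fraction > 1) {
    stop("coloc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(spec$shape < 4L)) stop("volume too small", call. = FALSE)
  if (any(radii <= 0) || nanodomain_radius <= 0) {
    stop("blob radii must be positive", call. = FALSE)
  }
  class(spec) <- "volume_spec"
  spec
}

# voxel-centre coordinate grids in um
voxel_axes <- function(shape, voxel_size) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * voxel_size[ax])
}

# add a Gaussian ellipsoid blob (half-max semi-axes r) to a volume, in place
add_blob <- function(vol, axes, centre, r, intensity) {
  s <- r / sqrt(2 * log(2))  # half-max radius -> Gaussian sigma
  win <- lapply(1:3, function(ax) {
    which(abs(axes[[ax]] - centre[ax]) <= 3.5 * s[ax])
  })
  if (any(vapply(win, length, integer(1)) == 0L)) return(vol)
  gx <- exp(-0.5 * ((axes[[1]][win[[1]]] - centre[1]) / s[1])^2)
  gy <- exp(-0.5 * ((axes[[2]][win[[2]]] - centre[2]) / s[2])^2)
  gz <- exp(-0.5 * ((axes[[3]][win[[3]]] - centre[3]) / s[3])^2)
  vol[win[[1]], win[[2]], win[[3]]] <-
    vol[win[[1]], win[[2]], win[[3]]] +
    intensity * outer(outer(gx, gy), gz)
  vol
}

# analytic voxelised volume of one ellipsoid blob at half max
ellipsoid_voxels <- function(axes, centre, r) {
  dx2 <- ((axes[[1]] - centre[1]) / r[1])^2
  dy2 <- ((axes[[2]] - centre[2]) / r[2])^2
  dz2 <- ((axes[[3]] - centre[3]) / r[3])^2
  sum(outer(outer(dx2, dy2, "+"), dz2, "+") <= 1)
}

#' Generate a two-channel 3D volume with known colocalization ground truth
#'
#' Renders channel A (receptor surface puncta) and channel B (scaffold
#' nanodomains grouped into clusters) as Gaussian ellipsoid blobs inside a
#' cylindrical dendrite mask, co-placing a `coloc_fraction` of A puncta on
#' randomly chosen B nanodomains. Deterministic for a fixed spec and seed.
#'
#' @param spec a [volume_spec()].
#' @return A list: `channelA`, `channelB` (3D arrays), `mask` (logical 3D
#'   array), `voxel_size`, and `truth` with elements `puncta` (per-punctum
#'   table incl. analytic half-max voxel volumes and `coloc` flags),
#'   `nanodomains` (centre table with cluster id), `histogram` (named counts:
#'   nanodomains-per-cluster -> number of clusters), `coloc_fraction`
#'   (planted), `overlap_fraction` (realised fraction of noise-free
#'   channel-A signal lying inside the channel-B half-max support, i.e. the
#'   thresholded M1 of the noiseless volumes),
#'   and `n_collapsed` (duplicate A centres collapsed).
#' @examples
#' v <- make_coloc_volume(volume_spec(n_puncta = 6, seed = 3))
#' v$truth$histogram
#' @export
make_coloc_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  set.seed(spec$seed)
  axes <- voxel_axes(spec$shape, spec$voxel_size)
  ext <- spec$shape * spec$voxel_size

  # cylindrical dendrite mask, axis along x through the (y, z) centre
  cy <- ext[2] / 2; cz <- ext[3] / 2
  dy2 <- (axes[[2]] - cy)^2
  dz2 <- (axes[[3]] - cz)^2
  rad2 <- outer(dy2, dz2, "+")
  mask_yz <- rad2 <= spec$dendrite_radius^2
  mask <- aperm(array(mask_yz, c(spec$shape[2], spec$shape[3], spec$shape[1])),
                c(3, 1, 2))

  rand_centre <- function(n, margin) {
    lo <- pmin(margin[1], ext[1] / 2)
    hi <- pmax(ext[1] - margin[1], ext[1] / 2)
    cbind(stats::runif(n, lo, hi),
          cy + stats::runif(n, -1, 1) * max(0, min(spec$dendrite_radius * 0.6,
                                                   ext[2] / 2 - margin[2])),
          cz + stats::runif(n, -1, 1) * max(0, min(spec$dendrite_radius * 0.6,
                                                   ext[3] / 2 - margin[3])))
  }

  # --- channel B: clustered nanodomains ---
  if (is.null(spec$cluster_layout)) {
    ncl <- length(spec$cluster_sizes)
    margin <- rep(3 * spec$nanodomain_radius + spec$cluster_spread, 3)
    ccen <- rand_centre(ncl, margin)
    layout <- lapply(seq_len(ncl), function(i) {
      k <- spec$cluster_sizes[i]
      off <- matrix(stats::rnorm(3 * k, sd = spec$cluster_spread / sqrt(3)),
                    ncol = 3)
      sweep(off, 2, ccen[i, ], "+")
    })
  } else {
    layout <- lapply(spec$cluster_layout, function(m) {
      m <- as.matrix(m)
      stopifnot(ncol(m) == 3L)
      m
    })
  }
  nano <- do.call(rbind, layout)
  if (any(nano < 0) || any(sweep(nano, 2, ext, ">"))) {
    stop("nanodomain centres must lie inside the volume", call. = FALSE)
  }
  cluster_id <- rep(seq_along(layout), vapply(layout, nrow, integer(1)))
  sizes <- vapply(layout, nrow, integer(1))
  histogram <- table(factor(sizes, levels = sort(unique(sizes))))

  rB <- rep(spec$nanodomain_radius, 3)
  chB <- array(0, spec$shape)
  for (i in seq_len(nrow(nano))) {
    chB <- add_blob(chB, axes, nano[i, ], rB, spec$intensity)
  }

  # --- channel A: receptor puncta, a fraction co-placed on nanodomains ---
  if (is.null(spec$puncta)) {
    n <- spec$n_puncta
    co <- stats::runif(n) < spec$coloc_fraction & nrow(nano) > 0
    cen <- rand_centre(n, 3 * spec$radii)
    if (any(co)) {
      pick <- sample.int(nrow(nano), sum(co), replace = TRUE)
      cen[co, ] <- nano[pick, , drop = FALSE]
    }
    pun <- data.frame(x = cen[, 1], y = cen[, 2], z = cen[, 3],
                      rx = spec$radii[1], ry = spec$radii[2], rz = spec$radii[3],
                      intensity = spec$intensity, coloc = co)
  } else {
    pun <- spec$puncta
    if (is.null(pun$intensity)) pun$intensity <- spec$intensity
    pun$coloc <- NA
  }
  dup <- duplicated(pun[, c("x", "y", "z")])
  n_collapsed <- sum(dup)
  pun <- pun[!dup, , drop = FALSE]

  chA <- array(0, spec$shape)
  for (i in seq_len(nrow(pun))) {
    chA <- add_blob(chA, axes, c(pun$x[i], pun$y[i], pun$z[i]),
                    c(pun$rx[i], pun$ry[i], pun$rz[i]), pun$intensity[i])
  }
  pun$voxels_halfmax <- vapply(seq_len(nrow(pun)), function(i) {
    ellipsoid_voxels(axes, c(pun$x[i], pun$y[i], pun$z[i]),
                     c(pun$rx[i], pun$ry[i], pun$rz[i]))
  }, numeric(1))
  pun$volume_um3 <- pun$voxels_halfmax * prod(spec$voxel_size)

  # realised overlap: fraction of noise-free channel-A signal lying in the
  # channel-B half-max support (the thresholded M1 of the noiseless volumes)
  supB <- chB > spec$intensity / 2
  overlap_fraction <- if (sum(chA) > 0) sum(chA[supB]) / sum(chA) else NA_real_

  if (spec$background > 0 || spec$noise_sd > 0) {
    chA <- pmax(chA + spec$background +
                  array(stats::rnorm(length(chA), sd = spec$noise_sd), spec$shape), 0)
    chB <- pmax(chB + spec$background +
                  array(stats::rnorm(length(chB), sd = spec$noise_sd), spec$shape), 0)
  }

  list(channelA = chA, channelB = chB, mask = mask,
       voxel_size = spec$voxel_size,
       truth = list(
         puncta = pun,
         nanodomains = data.frame(x = nano[, 1], y = nano[, 2], z = nano[, 3],
                                  cluster = cluster_id),
         cluster_sizes = sizes,
         histogram = histogram,
         coloc_fraction = spec$coloc_fraction,
         overlap_fraction = overlap_fraction,
         n_collapsed = n_collapsed))
}
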