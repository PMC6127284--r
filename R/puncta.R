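#' Segment 3D puncta with optional watershed splitting
#'
#' Thresholds a calibrated 3D volume (automatic two-class Otsu threshold by
#' default, computed within the dendrite mask when one is supplied), groups
#' supra-threshold voxels by 26-connectivity and, when `split = TRUE`,
#' separates touching objects by an intensity watershed on the Gaussian-
#' smoothed volume so that each smoothed local intensity maximum seeds one
#' object. Objects smaller than `min_volume` are discarded.
#'
#' @param volume numeric 3D array.
#' @param voxel_size voxel edge lengths, um per axis.
#' @param mask optional logical array (same shape); restricts threshold
#'   estimation. Objects are segmented over the full volume; use
#'   [puncta_metrics()] to restrict metrics to mask-intersecting objects.
#' @param threshold `"otsu"` (default) or a fixed numeric value. Voxels
#'   strictly above the threshold are foreground.
#' @param min_volume minimum object volume in um^3; the default keeps objects
#'   of at least 8 voxels.
#' @param split separate touching objects (default `TRUE`).
#' @param smoothing_sigma Gaussian sigma (um) used for the watershed
#'   intensity landscape.
#' @param tolerance watershed intensity tolerance: neighbouring maxima closer
#'   than this in intensity are merged (suppresses noise-split objects).
#' @return A `puncta_set`: integer label array and a per-object table
#'   (`label`, `n_vox`, `volume_um3`, centroid `x`/`y`/`z` in um,
#'   `peak_intensity`), plus the segmentation parameter record.
#' @export
segment_puncta <- function(volume, voxel_size, mask = NULL,
                           threshold = "otsu",
                           min_volume = 8 * prod(voxel_size),
                           split = TRUE,
                           smoothing_sigma = 0.08,
                           tolerance = 0.05) {
  stopifnot(length(dim(volume)) == 3L)
  voxel_size <- rep(voxel_size, length.out = 3L)
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(volume)))

  thr <- if (identical(threshold, "otsu")) {
    threshold_otsu(if (is.null(mask)) volume else volume[mask])
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  binary <- volume > thr

  if (!any(binary)) {
    return(puncta_set(array(0L, dim(volume)), volume, voxel_size,
                      list(threshold = thr, min_volume = min_volume,
                           split = split)))
  }

  if (split) {
    sm <- gauss_smooth_3d(volume, smoothing_sigma, voxel_size)
    land <- sm - thr
    land[!binary] <- 0
    # EBImage watershed: splits the positive landscape at intensity saddles,
    # merging maxima within `tolerance`
    lab <- EBImage::watershed(land, tolerance = tolerance, ext = 1)
    lab <- array(as.integer(lab), dim(volume))
    lab[!binary] <- 0L
    # watershed on the smoothed landscape may relabel; compact labels
    lab <- compact_labels(lab)
  } else {
    lab <- label_components_3d(binary)
  }

  # min_volume filter
  if (max(lab) > 0L) {
    nv <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(nv * prod(voxel_size) < min_volume)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- compact_labels(lab)
  }
  puncta_set(lab, volume, voxel_size,
             list(threshold = thr, min_volume = min_volume, split = split,
                  smoothing_sigma = if (split) smoothing_sigma else NA,
                  tolerance = if (split) tolerance else NA))
}

compact_labels <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

puncta_set <- function(labels, volume, voxel_size, params) {
  n <- max(labels)
  if (n > 0L) {
    idx <- which(labels > 0L)
    l <- labels[idx]
    co <- arrayInd(idx, dim(labels))
    nv <- tabulate(l, nbins = n)
    cx <- vapply(1:3, function(ax) {
      as.numeric(tapply((co[, ax] - 0.5) * voxel_size[ax], l, mean))
    }, numeric(n))
    if (n == 1L) cx <- matrix(cx, nrow = 1L)
    pk <- as.numeric(tapply(volume[idx], l, max))
    tab <- data.frame(label = seq_len(n), n_vox = nv,
                      volume_um3 = nv * prod(voxel_size),
                      x = cx[, 1], y = cx[, 2], z = cx[, 3],
                      peak_intensity = pk)
  } else {
    tab <- data.frame(label = integer(), n_vox = integer(),
                      volume_um3 = numeric(), x = numeric(), y = numeric(),
                      z = numeric(), peak_intensity = numeric())
  }
  structure(list(labels = labels, objects = tab, voxel_size = voxel_size,
                 params = params),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("Puncta set: %d object(s), threshold %.4g, split %s\n",
              nrow(x$objects), x$params$threshold,
              if (isTRUE(x$params$split)) "on" else "off"))
  if (nrow(x$objects)) {
    cat(sprintf("  volumes %.4g-%.4g um^3 (median %.4g)\n",
                min(x$objects$volume_um3), max(x$objects$volume_um3),
                stats::median(x$objects$volume_um3)))
  }
  invisible(x)
}

#' Puncta metrics normalised to dendrite volume
#'
#' Density, total object volume and mean individual object volume of the
#' puncta intersecting the dendrite mask, each divided by the dendrite
#' segment volume (the normalisation used when comparing receptor surface
#' expression across genotypes).
#'
#' @param puncta a [segment_puncta()] result.
#' @param mask logical 3D dendrite mask.
#' @return A `puncta_metrics` list: `puncta_density` (1/um^3),
#'   `total_surface_volume` (um^3 per um^3), `mean_puncta_volume` (um^3 per
#'   um^3), `dendrite_volume_um3`, `n_objects`, and the per-object table.
#' @export
puncta_metrics <- function(puncta, mask) {
  stopifnot(inherits(puncta, "puncta_set"),
            identical(dim(mask), dim(puncta$labels)))
  vvox <- prod(puncta$voxel_size)
  vmask <- sum(mask) * vvox
  if (vmask <= 0) stop("dendrite mask has zero volume", call. = FALSE)
  in_mask <- sort(unique(puncta$labels[puncta$labels > 0L & mask]))
  obj <- puncta$objects[puncta$objects$label %in% in_mask, , drop = FALSE]
  structure(list(
    puncta_density = nrow(obj) / vmask,
    total_surface_volume = sum(obj$volume_um3) / vmask,
    mean_puncta_volume = if (nrow(obj)) mean(obj$volume_um3) / vmask else NA_real_,
    dendrite_volume_um3 = vmask,
    n_objects = nrow(obj),
    objects = obj), class = "puncta_metrics")
}

#' @export
print.puncta_metrics <- function(x, ...) {
  cat(sprintf("Puncta metrics over %.1f um^3 of dendrite: %d object(s)\n",
              x$dendrite_volume_um3, x$n_objects))
  cat(sprintf("  density %.4g /um^3, total volume %.4g, mean punctum volume %.4g (per um^3)\n",
              x$puncta_density, x$total_surface_volume, x$mean_puncta_volume))
  invisible(x)
}

#' Detect nanodomain centres in a 3D volume
#'
#' Centres are local maxima of the Gaussian-smoothed volume above a
#' threshold, with non-maximum suppression: maxima closer than
#' `min_separation` (um, anisotropy honoured) to a brighter retained maximum
#' are discarded.
#'
#' @param volume numeric 3D array.
#' @param voxel_size voxel edge lengths, um per axis.
#' @param smoothing_sigma Gaussian sigma, um.
#' @param min_separation minimum centre separation, um.
#' @param threshold `"otsu"` (on the smoothed volume) or a numeric value.
#' @return Matrix of centres (um), columns `x`, `y`, `z`, ordered by
#'   decreasing smoothed intensity.
#' @export
detect_nanodomains <- function(volume, voxel_size, smoothing_sigma = 0.06,
                               min_separation = 0.2, threshold = "otsu") {
  stopifnot(length(dim(volume)) == 3L)
  voxel_size <- rep(voxel_size, length.out = 3L)
  sm <- gauss_smooth_3d(volume, smoothing_sigma, voxel_size)
  thr <- if (identical(threshold, "otsu")) threshold_otsu(sm) else threshold
  idx <- local_maxima_3d(sm, threshold = thr)
  if (!length(idx)) return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  co <- arrayInd(idx, dim(volume))
  cen <- sweep(co - 0.5, 2L, voxel_size, "*")
  o <- order(sm[idx], decreasing = TRUE)
  cen <- cen[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cen))
  for (i in seq_len(nrow(cen))) {
    if (!keep[i]) next
    if (i < nrow(cen)) {
      j <- (i + 1):nrow(cen)
      d <- sqrt(rowSums(sweep(cen[j, , drop = FALSE], 2L, cen[i, ], "-")^2))
      keep[j[d < min_separation]] <- FALSE
    }
  }
  out <- cen[keep, , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Group nanodomain centres into clusters
#'
#' Single-linkage clustering: clusters are connected components of the graph
#' linking centres within `linking_distance` um (complete linkage available).
#' Returns the per-cluster membership, the nanodomains-per-cluster histogram
#' and, when a dendrite volume is supplied, the density of single (size-1)
#' nanodomain clusters.
#'
#' @param centres matrix of centres (um), columns x, y, z.
#' @param linking_distance maximum link length, um (default 0.3, about twice
#'   the lateral resolution of the imaging this emulates).
#' @param dendrite_volume dendrite segment volume in um^3 (optional; used for
#'   the single-nanodomain density).
#' @param method `"single"` (default, connected components) or `"complete"`.
#' @return A `cluster_profile`: `clusters` (list of member index vectors),
#'   `sizes`, `histogram` (size -> count), `single_nanodomain_density`
#'   (1/um^3 or `NA`), `linking_distance`.
#' @export
cluster_nanodomains <- function(centres, linking_distance = 0.3,
                                dendrite_volume = NULL,
                                method = c("single", "complete")) {
  method <- match.arg(method)
  centres <- as.matrix(centres)
  n <- nrow(centres)
  if (n == 0L) {
    return(structure(list(clusters = list(), sizes = integer(),
                          histogram = table(integer()),
                          single_nanodomain_density = NA_real_,
                          linking_distance = linking_distance),
                     class = "cluster_profile"))
  }
  if (n == 1L) {
    memb <- 1L
  } else if (method == "single") {
    d <- as.matrix(stats::dist(centres))
    adj <- d <= linking_distance
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::dist(centres), method = "complete")
    memb <- stats::cutree(hc, h = linking_distance)
  }
  memb <- as.integer(factor(memb, levels = unique(memb)))
  clusters <- split(seq_len(n), memb)
  sizes <- lengths(clusters)
  histogram <- table(factor(sizes, levels = sort(unique(sizes))))
  structure(list(
    clusters = unname(clusters), sizes = unname(sizes), histogram = histogram,
    single_nanodomain_density =
      if (is.null(dendrite_volume)) NA_real_ else sum(sizes == 1L) / dendrite_volume,
    linking_distance = linking_distance), class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("Nanodomain cluster profile: %d centre(s) in %d cluster(s) (link %.3g um)\n",
              sum(x$sizes), length(x$sizes), x$linking_distance))
  if (length(x$sizes)) {
    cat("  nanodomains per cluster: ")
    print(x$histogram)
  }
  invisible(x)
}

#' Derive a dendrite mask from a cytoskeleton channel
#'
#' Otsu threshold followed by morphological closing (box kernel), for use
#' when an explicit dendrite mask is not supplied; the cytoskeleton stain is
#' the usual proxy for dendritic volume.
#'
#' @param volume cytoskeleton-channel 3D array.
#' @param closing_radius half-width of the closing box, voxels per axis.
#' @return Logical 3D array.
#' @export
dendrite_mask_from_channel <- function(volume, closing_radius = c(2L, 2L, 1L)) {
  b <- (volume > threshold_otsu(volume)) * 1
  r <- rep(closing_radius, length.out = 3L)
  # separable box dilation / erosion via counting convolutions
  dilate <- function(a) {
    for (ax in 1:3) {
      if (r[ax] > 0) a <- (conv_axis(a, rep(1, 2L * r[ax] + 1L), ax) > 1e-9) * 1
    }
    a
  }
  erode <- function(a) {
    for (ax in 1:3) {
      if (r[ax] > 0) a <- (conv_axis(a, rep(1, 2L * r[ax] + 1L), ax) >
                             2L * r[ax] + 1L - 1e-9) * 1
    }
    a
  }
  erode(dilate(b)) > 0
}
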