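#' Otsu's two-class intensity threshold
#'
#' Histogram-based threshold maximising between-class variance, computed on a
#' plain numeric vector so it applies to volumes of any dimensionality (and
#' to masked subsets). Returned value is the upper edge of the background
#' class: voxels strictly above it are foreground.
#'
#' @param x numeric vector (or array) of intensities.
#' @param levels number of histogram bins.
#' @return The threshold value.
#' @export
threshold_otsu <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1L])
  br <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[levels]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Separable Gaussian smoothing of a 3D array; sigma given in um per axis
# (scalar recycled), voxel_size in um per axis. Zero-padded convolution with
# edge renormalisation (divide by the smoothed indicator).
gauss_smooth_3d <- function(vol, sigma_um, voxel_size) {
  stopifnot(length(dim(vol)) == 3L)
  sigma_um <- rep(sigma_um, length.out = 3L)
  voxel_size <- rep(voxel_size, length.out = 3L)
  sig_vox <- sigma_um / voxel_size
  out <- vol
  norm <- array(1, dim(vol))
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-hw:hw, sd = s)
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
    norm <- conv_axis(norm, k, ax)
  }
  out / norm
}

# convolve each line of `a` along axis `ax` with kernel k (zero padding)
conv_axis <- function(a, k, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  hw <- (length(k) - 1L) / 2L
  pad <- matrix(0, hw, ncol(m))
  mp <- rbind(pad, m, pad)
  # stats::filter applies the kernel to each column of a matrix
  f <- stats::filter(mp, k, sides = 2)
  res <- matrix(f[(hw + 1L):(hw + d[ax]), ], nrow = d[ax])
  aperm(array(res, d[perm]), order(perm))
}

# Linear voxel indices of the 26-neighbourhood offsets (as coordinate deltas)
neighbour_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
}

#' Label 26-connected components of a 3D binary volume
#'
#' Builds the adjacency between foreground voxels (26-neighbourhood) and
#' labels connected components via graph components. Suited to the volume
#' sizes of dendrite-segment imaging (tens of voxels cubed).
#'
#' @param binary logical (or 0/1) 3D array.
#' @return Integer array of the same shape: 0 = background, 1..n component
#'   labels (labelled in order of first voxel occurrence).
#' @export
label_components_3d <- function(binary) {
  stopifnot(length(dim(binary)) == 3L)
  d <- dim(binary)
  fg <- which(binary != 0)
  lab <- array(0L, d)
  if (!length(fg)) return(lab)
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- neighbour_offsets_26()
  # only half the offsets needed: each undirected edge found once
  offs <- offs[1:(nrow(offs) / 2), ]
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, as.numeric(offs[i, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- id[nb_lin]
    src <- id[fg[ok]]
    keep <- nb_id > 0L
    if (any(keep)) edges[[i]] <- cbind(src[keep], nb_id[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel in order of first occurrence for determinism
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[fg] <- relab[comp]
  lab
}

# Local maxima of a 3D array: voxels >= all 26 neighbours (missing neighbours
# treated as -Inf) and above `threshold`. Returns linear indices.
local_maxima_3d <- function(vol, threshold = -Inf) {
  d <- dim(vol)
  cand <- array(TRUE, d)
  offs <- neighbour_offsets_26()
  for (i in seq_len(nrow(offs))) {
    sh <- shift_3d(vol, as.integer(offs[i, ]))
    cand <- cand & (vol >= sh)
  }
  which(cand & vol > threshold)
}

# shift array by (dx, dy, dz), filling with -Inf
shift_3d <- function(a, delta) {
  d <- dim(a)
  out <- array(-Inf, d)
  src <- dst <- list()
  for (ax in 1:3) {
    if (delta[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - delta[ax])
      dst[[ax]] <- src[[ax]] + delta[ax]
    } else {
      src[[ax]] <- (1 - delta[ax]):d[ax]
      dst[[ax]] <- src[[ax]] + delta[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
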