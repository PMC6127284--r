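#' Pearson and Manders colocalization coefficients
#'
#' Voxel-wise colocalization of two channels within a mask, as used to relate
#' surface receptor signal to the postsynaptic scaffold. `coloc_pearson()` is
#' the Pearson correlation of the two channels over masked voxels.
#' `coloc_manders()` returns M1, the fraction of channel-A signal found in
#' voxels where channel B is above its threshold, and M2 with the roles
#' swapped; thresholds default to per-channel Otsu (set `thresholds = c(0, 0)`
#' for the raw, unthresholded variant). `coloc()` computes all three plus the
#' analysed voxel count.
#'
#' @param a,b numeric 3D arrays (identical shape), the two channels.
#' @param mask optional logical array restricting the analysis (e.g. the
#'   dendrite); default all voxels.
#' @param thresholds length-2 numeric `c(T_a, T_b)`, or `"otsu"` (default)
#'   for automatic per-channel two-class thresholds computed within the mask.
#' @return `coloc_pearson()`: correlation (`NA` with a warning when either
#'   channel has zero variance). `coloc_manders()`: named vector
#'   `c(M1, M2)` (`NA` where a channel has zero total signal).
#'   `coloc()`: a `coloc_result` list.
#' @examples
#' v <- make_coloc_volume(volume_spec(seed = 4))
#' coloc(v$channelA, v$channelB, v$mask)
#' @export
coloc_pearson <- function(a, b, mask = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  av <- a[mask]; bv <- b[mask]
  if (length(av) < 2L) stop("need at least two masked voxels", call. = FALSE)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    warning("zero variance in a channel; Pearson undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(av, bv)
}

#' @rdname coloc_pearson
#' @export
coloc_manders <- function(a, b, mask = NULL, thresholds = "otsu") {
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  av <- a[mask]; bv <- b[mask]
  thr <- manders_thresholds(av, bv, thresholds)
  m1 <- if (sum(av) > 0) sum(av[bv > thr[2L]]) / sum(av) else NA_real_
  m2 <- if (sum(bv) > 0) sum(bv[av > thr[1L]]) / sum(bv) else NA_real_
  if (anyNA(c(m1, m2))) {
    warning("zero total signal in a channel; Manders coefficient undefined",
            call. = FALSE)
  }
  c(M1 = m1, M2 = m2)
}

manders_thresholds <- function(av, bv, thresholds) {
  if (identical(thresholds, "otsu")) {
    c(threshold_otsu(av), threshold_otsu(bv))
  } else {
    stopifnot(is.numeric(thresholds), length(thresholds) == 2L)
    thresholds
  }
}

#' @rdname coloc_pearson
#' @export
coloc <- function(a, b, mask = NULL, thresholds = "otsu") {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  thr <- manders_thresholds(a[mask], b[mask], thresholds)
  m <- suppressWarnings(coloc_manders(a, b, mask, thr))
  r <- withCallingHandlers(
    coloc_pearson(a, b, mask),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(pearson_r = r, manders_m1 = unname(m[1L]),
                 manders_m2 = unname(m[2L]),
                 thresholds = thr, n_voxels = sum(mask),
                 flags = c(pearson_undefined = is.na(r),
                           manders_undefined = anyNA(m))),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d voxels: Pearson r = %s, M1 = %s, M2 = %s\n",
              x$n_voxels, fmt_or_na(x$pearson_r), fmt_or_na(x$manders_m1),
              fmt_or_na(x$manders_m2)))
  cat(sprintf("  thresholds: A %.4g, B %.4g\n", x$thresholds[1L], x$thresholds[2L]))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)

#' Mask of colocalised voxels
#'
#' Voxels where both channels are above their thresholds, for visual overlay
#' (no statistic depends on it).
#'
#' @inheritParams coloc_pearson
#' @return Logical array.
#' @export
coloc_overlap_mask <- function(a, b, mask = NULL, thresholds = "otsu") {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  thr <- manders_thresholds(a[mask], b[mask], thresholds)
  a > thr[1L] & b > thr[2L] & mask
}
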