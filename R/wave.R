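#' Measure raw bin intensities over time
#'
#' Sums background-subtracted pixel intensities over each bin mask in every
#' frame. Background is, per frame, the mean intensity over a user-supplied
#' off-cell pixel region (default strategy), a supplied constant, or zero.
#'
#' @param movie a [pc_movie()].
#' @param grid a [extract_bins()] result.
#' @param background `NULL` (no subtraction), a single number (constant photon
#'   level per pixel), or a logical matrix the size of one frame marking an
#'   off-cell region whose per-frame mean is subtracted. The region must not
#'   overlap any bin mask.
#' @return A `bin_intensity` object: matrix of raw intensities (bins x
#'   timepoints), the bin table, timepoints and the background record.
#' @export
measure_bins <- function(movie, grid, background = NULL) {
  stopifnot(inherits(movie, "pc_movie"), inherits(grid, "bin_grid"))
  d <- dim(movie$frames)
  if (!identical(d[1:2], as.integer(grid$dims))) {
    stop("bin grid was built for a different frame size", call. = FALSE)
  }
  if (any(vapply(grid$masks, length, integer(1)) == 0L &
          !grid$bins$truncated)) {
    stop("empty bin mask", call. = FALSE)
  }
  nt <- d[3L]
  npx_frame <- d[1L] * d[2L]

  bg_idx <- NULL
  if (is.matrix(background)) {
    stopifnot(is.logical(background), identical(dim(background), d[1:2]))
    bg_idx <- which(background)
    if (length(bg_idx) == 0L) stop("background region is empty", call. = FALSE)
    if (length(intersect(bg_idx, unlist(grid$masks)))) {
      stop("background region overlaps the dendrite bins", call. = FALSE)
    }
  } else if (!is.null(background) && (!is.numeric(background) || length(background) != 1L)) {
    stop("background must be NULL, a constant, or a logical frame mask",
         call. = FALSE)
  }

  bg <- numeric(nt)
  vals <- matrix(0, nrow = nrow(grid$bins), ncol = nt,
                 dimnames = list(names(grid$masks), NULL))
  for (k in seq_len(nt)) {
    fr <- movie$frames[, , k]
    bg[k] <- if (!is.null(bg_idx)) mean(fr[bg_idx])
             else if (is.numeric(background)) background else 0
    for (i in seq_len(nrow(vals))) {
      m <- grid$masks[[i]]
      if (length(m)) vals[i, k] <- sum(fr[m]) - length(m) * bg[k]
    }
  }
  structure(list(values = vals, bins = grid$bins, timepoints = movie$timepoints,
                 background = bg),
            class = "bin_intensity")
}

#' Doubly normalised fluorescence wave matrix
#'
#' Converts raw bin intensities to the assay's central derived object: each
#' bin's intensity is divided by the bin area (per-area density) and then by
#' the density of bin zero at time zero, so that `value(bin 0, t = 0) = 1`
#' exactly. The matrix is therefore invariant to any global intensity gain.
#' An analysis `window` (s) optionally restricts the timepoints retained
#' (e.g. 120 s of a 180-s acquisition).
#'
#' @param raw a [measure_bins()] result.
#' @param window analysis window in seconds, or `NULL` to keep all frames.
#' @return A `wave_matrix`: a data frame with columns `direction`, `bin`,
#'   `time_s`, `value`, `truncated`, carrying the normalisation record
#'   (per-frame background, bin areas, reference intensity) as attributes.
#' @export
normalise_wave <- function(raw, window = NULL) {
  stopifnot(inherits(raw, "bin_intensity"))
  keep <- if (is.null(window)) seq_along(raw$timepoints)
          else which(raw$timepoints <= window + 1e-9)
  tp <- raw$timepoints[keep]
  vals <- raw$values[, keep, drop = FALSE]
  bins <- raw$bins

  i0 <- which(bins$direction == "centre" & bins$label == 0)
  ref <- vals[i0, 1L] / bins$area_um2[i0]
  if (!is.finite(ref) || ref <= 0) {
    stop("no photoconverted signal in ROI (bin 0 intensity at t = 0 is not positive)",
         call. = FALSE)
  }
  dens <- vals / bins$area_um2 / ref

  out <- data.frame(
    direction = rep(bins$direction, times = length(tp)),
    bin = rep(bins$label, times = length(tp)),
    time_s = rep(tp, each = nrow(bins)),
    value = as.vector(dens),
    truncated = rep(bins$truncated, times = length(tp)),
    stringsAsFactors = FALSE)
  structure(out,
            class = c("wave_matrix", "data.frame"),
            areas = stats::setNames(bins$area_um2, paste(bins$direction, bins$label, sep = "_")),
            timepoints = tp,
            normalisation = list(background = raw$background[keep],
                                 reference_density = ref,
                                 roi_area_um2 = bins$area_um2[i0]))
}

#' Full wave-analysis pipeline for one movie
#'
#' Convenience wrapper: [extract_bins()], [measure_bins()], [normalise_wave()].
#'
#' @inheritParams measure_bins
#' @inheritParams extract_bins
#' @inheritParams normalise_wave
#' @param trace a [dendrite_trace()].
#' @return A `wave_matrix`.
#' @examples
#' cfg <- sim_config(n_particles = 100, duration = 60, seed = 3)
#' sim <- simulate_pulse_chase(cfg)
#' w <- pulse_wave(sim$movie, sim_trace(cfg), background = sim_background_mask(cfg))
#' head(w)
#' @export
pulse_wave <- function(movie, trace, bin_width = 5, window = 120,
                       background = NULL) {
  grid <- extract_bins(trace, movie, bin_width = bin_width)
  raw <- measure_bins(movie, grid, background = background)
  normalise_wave(raw, window = window)
}

#' Extract one bin's time series from a wave matrix
#'
#' @param wave a `wave_matrix`.
#' @param direction `"distal"`, `"proximal"` or `"centre"`.
#' @param bin bin label (um).
#' @return Named numeric vector of values, names = timepoints (s).
#' @export
wave_values <- function(wave, direction, bin) {
  rows <- wave$direction == direction & wave$bin == bin
  if (!any(rows)) return(NULL)
  stats::setNames(wave$value[rows], wave$time_s[rows])[order(wave$time_s[rows])]
}

#' Read or write a wave matrix as tidy CSV
#'
#' Columns: `direction`, `bin`, `time_s`, `value`, `truncated` (and `neuron`
#' if present).
#'
#' @param wave a `wave_matrix` (or plain data frame in the same layout).
#' @param path file path.
#' @return `read_wave()` returns a `wave_matrix`; `write_wave()` returns
#'   `path` invisibly.
#' @export
write_wave <- function(wave, path) {
  utils::write.csv(as.data.frame(wave), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wave
#' @export
read_wave <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("direction", "bin", "time_s", "value")
  if (!all(need %in% names(df))) {
    stop("wave CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$truncated)) df$truncated <- FALSE
  structure(df, class = c("wave_matrix", "data.frame"),
            timepoints = sort(unique(df$time_s)))
}
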