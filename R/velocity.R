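#' Crest velocity from time to peak fluorescence
#'
#' For each requested bin, the time to peak is the earliest timepoint within
#' the analysis window at which the bin's normalised fluorescence attains its
#' maximum; the bin velocity is the bin label (um, distance from the ROI edge
#' to the bin's outer boundary) divided by that time. A bin is excluded when
#' its maximum sits on the window boundary (t = 0 or the final frame: no
#' interior peak) or when the bin is truncated or absent. The estimate is the
#' mean velocity over non-excluded bins; the canonical bins are 10 and 15 um,
#' where the crest of the wave is clearly identifiable.
#'
#' @param wave a `wave_matrix` (see [normalise_wave()]).
#' @param bins bin labels to use (um), default `c(10, 15)`.
#' @param direction `"distal"` (default) or `"proximal"`.
#' @param distance `"label"` (default; v = label / t, matching the convention
#'   that 10 um / 50 s = 0.2 um/s) or `"centre"` (bin midpoint).
#' @return A `velocity_estimate`: per-bin table (`bin`, `t_peak`, `velocity`,
#'   `excluded`, `reason`) and `velocity`, the mean over usable bins (`NA` if
#'   none).
#' @export
peak_velocity <- function(wave, bins = c(10, 15), direction = "distal",
                          distance = c("label", "centre")) {
  distance <- match.arg(distance)
  per_bin <- lapply(bins, function(b) {
    v <- wave_values(wave, direction, b)
    trunc <- any(wave$truncated[wave$direction == direction & wave$bin == b])
    if (is.null(v)) {
      return(data.frame(bin = b, t_peak = NA_real_, velocity = NA_real_,
                        excluded = TRUE, reason = "absent"))
    }
    if (trunc) {
      return(data.frame(bin = b, t_peak = NA_real_, velocity = NA_real_,
                        excluded = TRUE, reason = "truncated"))
    }
    tp <- as.numeric(names(v))
    t_peak <- tp[which.max(v)]  # earliest timepoint attaining the maximum
    if (t_peak == tp[1L] || t_peak == tp[length(tp)]) {
      return(data.frame(bin = b, t_peak = t_peak, velocity = NA_real_,
                        excluded = TRUE, reason = "no interior peak"))
    }
    d <- if (distance == "label") b else b - bin_halfstep(wave, b)
    data.frame(bin = b, t_peak = t_peak, velocity = d / t_peak,
               excluded = FALSE, reason = "")
  })
  per_bin <- do.call(rbind, per_bin)
  velocity_estimate("peak", per_bin, direction)
}

# half a bin width, for the bin-centre distance convention
bin_halfstep <- function(wave, b) {
  labs <- sort(unique(wave$bin[wave$bin > 0]))
  w <- if (length(labs) > 1L) min(diff(labs)) else labs[1L]
  w / 2
}

#' Leading-edge velocity from time to fluorescence appearance
#'
#' Formalises the "appearance of the leading edge" as a threshold rule: the
#' appearance time of a bin is the earliest timepoint at which its value
#' exceeds `baseline + k_sigma * sigma_noise` for two consecutive frames,
#' where the baseline is the bin's value at t = 0 and `sigma_noise` is the
#' robust SD (MAD) of t = 0 values across all bins at or beyond the innermost
#' edge bin (default 25 um), over both directions. The bin velocity is the
#' bin label divided by the appearance time; the estimate is the mean over
#' bins with a detected appearance. Canonical bins are 25-40 um, which only
#' the fast-moving population reaches within the analysis window.
#'
#' @inheritParams peak_velocity
#' @param bins bin labels to use (um), default `c(25, 30, 35, 40)`.
#' @param k_sigma threshold multiplier (default 3).
#' @return A `velocity_estimate`: per-bin table (`bin`, `t_appear`,
#'   `velocity`, `excluded`, `reason`) and the mean over detected bins.
#' @export
edge_velocity <- function(wave, bins = c(25, 30, 35, 40), direction = "distal",
                          k_sigma = 3,
                          distance = c("label", "centre")) {
  distance <- match.arg(distance)
  far <- wave$time_s == 0 & wave$bin >= min(bins) & !wave$truncated &
    wave$direction %in% c("distal", "proximal")
  sigma <- stats::mad(wave$value[far])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-6 / k_sigma  # noise-free fallback

  per_bin <- lapply(bins, function(b) {
    v <- wave_values(wave, direction, b)
    trunc <- any(wave$truncated[wave$direction == direction & wave$bin == b])
    if (is.null(v) || trunc) {
      return(data.frame(bin = b, t_appear = NA_real_, velocity = NA_real_,
                        excluded = TRUE,
                        reason = if (is.null(v)) "absent" else "truncated"))
    }
    tp <- as.numeric(names(v))
    thr <- v[1L] + k_sigma * sigma
    above <- v > thr
    hit <- which(above[-length(above)] & above[-1L])  # two consecutive frames
    hit <- hit[tp[hit] > 0]
    if (!length(hit)) {
      return(data.frame(bin = b, t_appear = NA_real_, velocity = NA_real_,
                        excluded = TRUE, reason = "no appearance"))
    }
    t_app <- tp[hit[1L]]
    d <- if (distance == "label") b else b - bin_halfstep(wave, b)
    data.frame(bin = b, t_appear = t_app, velocity = d / t_app,
               excluded = FALSE, reason = "")
  })
  per_bin <- do.call(rbind, per_bin)
  est <- velocity_estimate("edge", per_bin, direction)
  est$k_sigma <- k_sigma
  est$sigma_noise <- sigma
  est
}

velocity_estimate <- function(type, per_bin, direction) {
  usable <- !per_bin$excluded
  structure(list(type = type, direction = direction, per_bin = per_bin,
                 velocity = if (any(usable)) mean(per_bin$velocity[usable]) else NA_real_,
                 n_bins_used = sum(usable)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("%s velocity (%s): %s um/s from %d bin(s)\n",
              if (x$type == "peak") "Crest (time-to-peak)" else "Leading-edge",
              x$direction,
              if (is.na(x$velocity)) "undefined" else sprintf("%.3f", x$velocity),
              x$n_bins_used))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' Classify slow and fast transport populations across neurons
#'
#' Takes per-neuron crest (slow-pool) and leading-edge (fast-pool) velocity
#' estimates and asks whether they support two kinematically distinct
#' classes: a paired two-tailed t test compares the two estimators across
#' neurons, and two populations are reported when the test rejects at
#' `alpha` and the leading-edge mean exceeds the crest mean.
#'
#' @param estimates a data frame with columns `neuron`, `peak_velocity`,
#'   `edge_velocity` (one row per neuron, a single direction; `NA` where an
#'   estimator was undefined).
#' @param alpha significance level (default 0.05).
#' @return A `population_summary`: `n_populations` (0, 1, 2, or `NA` with
#'   `insufficient = TRUE` when fewer than 3 neurons have both estimates),
#'   per-population mean, SEM and n, and the paired test statistic/p-value.
#' @export
classify_populations <- function(estimates, alpha = 0.05) {
  stopifnot(all(c("peak_velocity", "edge_velocity") %in% names(estimates)))
  ok <- stats::complete.cases(estimates[, c("peak_velocity", "edge_velocity")])
  res <- list(alpha = alpha, n_neurons = sum(ok), insufficient = FALSE,
              statistic = NA_real_, p_value = NA_real_)
  if (nrow(estimates) == 0L) {
    res$n_populations <- 0L
    res$slow <- res$fast <- c(mean = NA, sem = NA, n = 0)
    class(res) <- "population_summary"
    return(res)
  }
  slow <- estimates$peak_velocity[ok]
  fast <- estimates$edge_velocity[ok]
  res$slow <- c(mean = mean(slow), sem = stats::sd(slow) / sqrt(length(slow)),
                n = length(slow))
  res$fast <- c(mean = mean(fast), sem = stats::sd(fast) / sqrt(length(fast)),
                n = length(fast))
  if (sum(ok) < 3L) {
    res$n_populations <- NA_integer_
    res$insufficient <- TRUE
    class(res) <- "population_summary"
    return(res)
  }
  tt <- tryCatch(stats::t.test(fast, slow, paired = TRUE),
                 error = function(e) NULL)  # constant differences -> no test
  if (is.null(tt)) {
    res$statistic <- 0; res$p_value <- 1
  } else {
    res$statistic <- unname(tt$statistic); res$p_value <- tt$p.value
  }
  res$n_populations <-
    if (res$p_value < alpha && res$fast["mean"] > res$slow["mean"]) 2L else 1L
  class(res) <- "population_summary"
  res
}

#' @export
print.population_summary <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("Population summary: insufficient neurons (<3 with both estimators)\n")
    return(invisible(x))
  }
  cat(sprintf("Population summary: %s kinematic class(es) (paired t = %.3g, p = %.3g, n = %d)\n",
              x$n_populations, x$statistic, x$p_value, x$n_neurons))
  cat(sprintf("  slow (crest):        %.3f +/- %.3f um/s\n", x$slow["mean"], x$slow["sem"]))
  cat(sprintf("  fast (leading edge): %.3f +/- %.3f um/s\n", x$fast["mean"], x$fast["sem"]))
  invisible(x)
}

#' Per-neuron velocity table from a list of wave matrices
#'
#' Applies [peak_velocity()] and [edge_velocity()] to each neuron's wave
#' matrix and assembles the per-neuron estimate table used by
#' [classify_populations()].
#'
#' @param waves list of `wave_matrix` objects (one per neuron).
#' @param direction `"distal"` or `"proximal"`.
#' @param peak_bins,edge_bins bin labels for the two estimators.
#' @param k_sigma threshold multiplier for the leading edge.
#' @return Data frame: `neuron`, `peak_velocity`, `edge_velocity`.
#' @export
velocity_table <- function(waves, direction = "distal",
                           peak_bins = c(10, 15),
                           edge_bins = c(25, 30, 35, 40), k_sigma = 3) {
  rows <- lapply(seq_along(waves), function(i) {
    data.frame(
      neuron = i,
      peak_velocity = peak_velocity(waves[[i]], peak_bins, direction)$velocity,
      edge_velocity = edge_velocity(waves[[i]], edge_bins, direction,
                                    k_sigma = k_sigma)$velocity)
  })
  do.call(rbind, rows)
}
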