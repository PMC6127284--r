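#' Simulate a photoconversion pulse-chase movie
#'
#' Generates a time-lapse movie of a photoconverted particle pool spreading
#' along a straight dendrite, together with the per-particle ground truth.
#' Particles start uniformly within the ROI footprint at t = 0. Slow-pool
#' particles follow advection plus Brownian motion; fast-pool particles follow
#' advection with a small, sample-centred per-particle speed dispersion
#' (`v_fast_cv`); stationary particles do not move. Particles reaching either
#' dendrite tip are absorbed (removed from subsequent frames). Each frame is
#' rendered by placing a Gaussian PSF at every live particle position on a
#' ribbon-shaped dendrite, adding a constant background and, if `noise_on`,
#' Poisson-sampling the result.
#'
#' @param config a [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{movie}{a `pc_movie`: frames (y, x, t array of photon counts),
#'       `pixel_size` (um), `frame_interval` (s), `timepoints` (s).}
#'     \item{truth}{a `pc_truth`: per-particle table (population, direction,
#'       signed advection velocity, initial position), the noise-free arc
#'       trajectory matrix (particles x frames, NA after absorption),
#'       configured `v_slow`/`v_fast`, and flags (`any_absorbed`,
#'       `edge_bins_fit` -- whether the dendrite accommodates 40-um bins on
#'       both sides of the ROI).}
#'   }
#' @examples
#' sim <- simulate_pulse_chase(sim_config(n_particles = 50, seed = 2))
#' dim(sim$movie$frames)
#' @export
simulate_pulse_chase <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  kin <- simulate_kinematics(config)
  movie <- render_movie(kin, config)
  list(movie = movie, truth = kin$truth)
}

# Particle population assignment, initial positions and trajectories.
# Population sizes are deterministic rounded counts of the configured
# fractions so that ground truth composition is exact.
simulate_kinematics <- function(config) {
  set.seed(config$seed)
  n <- config$n_particles
  fr <- c(stationary = config$frac_stationary,
          slow_distal = config$frac_slow_distal,
          slow_proximal = config$frac_slow_proximal,
          fast_distal = config$frac_fast_distal,
          fast_proximal = config$frac_fast_proximal)
  counts <- diff(c(0L, round(cumsum(fr) * n)))
  grp <- rep(names(fr), counts)

  population <- sub("_(distal|proximal)$", "", grp)
  direction <- ifelse(population == "stationary", "none",
                      sub("^(slow|fast)_", "", grp))
  sign <- ifelse(direction == "distal", 1, ifelse(direction == "proximal", -1, 0))

  v <- numeric(n)
  v[population == "slow"] <- config$v_slow
  # fast-pool speeds: sample-centred per direction so each direction's mean
  # speed is exactly v_fast
  for (dirn in c("distal", "proximal")) {
    fast <- population == "fast" & direction == dirn
    nf <- sum(fast)
    if (!nf) next
    if (config$v_fast_cv > 0 && nf > 1) {
      z <- stats::rnorm(nf)
      z <- (z - mean(z)) / stats::sd(z)
      v[fast] <- config$v_fast * pmax(0.1, 1 + config$v_fast_cv * z)
    } else {
      v[fast] <- config$v_fast
    }
  }
  v <- v * sign

  x0 <- stats::runif(n, config$roi_centre - config$roi_halfwidth,
                     config$roi_centre + config$roi_halfwidth)
  y0 <- stats::runif(n, -config$dendrite_width / 2, config$dendrite_width / 2)

  nt <- ceiling(config$duration / config$frame_interval) + 1L
  tp <- (seq_len(nt) - 1L) * config$frame_interval

  # arc positions: advection + (slow pool) Brownian increments per frame
  traj <- outer(x0, rep(1, nt)) + outer(v, tp)
  slow <- population == "slow"
  if (any(slow) && config$diffusion_slow > 0) {
    sd_step <- sqrt(2 * config$diffusion_slow * config$frame_interval)
    steps <- matrix(stats::rnorm(sum(slow) * (nt - 1L), sd = sd_step),
                    nrow = sum(slow))
    traj[slow, -1L] <- traj[slow, -1L] + t(apply(steps, 1L, cumsum))
  }

  # absorbing tips: NA from the first frame a particle is out of bounds
  out <- traj < 0 | traj > config$dendrite_length
  if (any(out)) {
    first_out <- apply(out, 1L, function(o) if (any(o)) which(o)[1L] else NA_integer_)
    for (i in which(!is.na(first_out))) traj[i, first_out[i]:nt] <- NA_real_
  }

  edge_bins_fit <-
    config$roi_centre + config$roi_halfwidth + 40 <= config$dendrite_length &&
    config$roi_centre - config$roi_halfwidth - 40 >= 0
  if (!edge_bins_fit) {
    warning("dendrite too short for 40-um bins on both sides of the ROI",
            call. = FALSE)
  }

  truth <- structure(list(
    particles = data.frame(
      particle = seq_len(n), population = population, direction = direction,
      velocity = v, x0 = x0, y0 = y0, stringsAsFactors = FALSE),
    trajectory = traj,
    timepoints = tp,
    v_slow = config$v_slow, v_fast = config$v_fast,
    any_absorbed = any(out),
    edge_bins_fit = edge_bins_fit,
    config = config), class = "pc_truth")

  list(truth = truth, traj = traj, y0 = y0, tp = tp)
}

# Render frames: each live particle contributes a 2D Gaussian PSF stamp of
# total intensity photons_per_particle (integral approximated at pixel
# centres over a +/-4 sigma window).
render_movie <- function(kin, config) {
  px <- config$pixel_size
  nx <- round(config$dendrite_length / px)
  margin <- 2  # um of dark field either side of the ribbon
  ny <- round((config$dendrite_width + 2 * margin) / px)
  yc <- config$dendrite_width / 2 + margin  # ribbon axis, um from image top
  nt <- length(kin$tp)

  sig <- config$psf_sigma
  amp <- config$photons_per_particle * px^2 / (2 * pi * sig^2)
  hw <- ceiling(4 * sig / px)  # stamp half-width in pixels

  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px

  frames <- array(config$background_level, dim = c(ny, nx, nt))
  for (k in seq_len(nt)) {
    alive <- which(!is.na(kin$traj[, k]))
    for (i in alive) {
      cx <- kin$traj[i, k]
      cy <- yc + kin$y0[i]
      jx <- max(1L, round(cx / px) - hw):min(nx, round(cx / px) + hw)
      jy <- max(1L, round(cy / px) - hw):min(ny, round(cy / px) + hw)
      if (!length(jx) || !length(jy)) next
      gx <- exp(-0.5 * ((xs[jx] - cx) / sig)^2)
      gy <- exp(-0.5 * ((ys[jy] - cy) / sig)^2)
      frames[jy, jx, k] <- frames[jy, jx, k] + amp * outer(gy, gx)
    }
  }
  if (config$noise_on) {
    frames[] <- stats::rpois(length(frames), frames)
  }
  pc_movie(frames, pixel_size = px, frame_interval = config$frame_interval)
}

#' Construct a pulse-chase movie object
#'
#' @param frames numeric array `(y, x, t)` of non-negative intensities, or a
#'   list of equally sized y-by-x matrices.
#' @param pixel_size pixel size, um.
#' @param frame_interval frame interval, s.
#' @param timepoints optional timepoints (s); defaults to a regular grid
#'   starting at 0.
#' @return A `pc_movie` object.
#' @export
pc_movie <- function(frames, pixel_size, frame_interval, timepoints = NULL) {
  if (is.list(frames)) {
    d <- dim(frames[[1L]])
    stopifnot(all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (any(frames < 0)) stop("intensities must be non-negative", call. = FALSE)
  nt <- dim(frames)[3L]
  if (is.null(timepoints)) timepoints <- (seq_len(nt) - 1L) * frame_interval
  stopifnot(length(timepoints) == nt, timepoints[1L] == 0,
            all(diff(timepoints) > 0))
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, timepoints = timepoints),
            class = "pc_movie")
}

#' @export
print.pc_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Pulse-chase movie: %d x %d px, %d frames (0..%g s every %g s), %g um/px\n",
              d[2L], d[1L], d[3L], max(x$timepoints), x$frame_interval,
              x$pixel_size))
  invisible(x)
}

#' Dendrite trace and off-cell background mask for a simulated movie
#'
#' `sim_trace()` returns the [dendrite_trace()] matching the ribbon geometry
#' of a movie simulated with `config`: a straight two-point polyline along the
#' ribbon axis, with a measurement width of `dendrite_width + 6 * psf_sigma`
#' so that laterally blurred signal is captured. `sim_background_mask()`
#' returns a logical pixel mask covering a dark band along the top edge of
#' the field, outside the reach of the PSF, for off-cell background
#' estimation.
#'
#' @param config a [sim_config()].
#' @param band height (um) of the background band.
#' @return A `dendrite_trace`, or a logical matrix (y, x).
#' @export
sim_trace <- function(config) {
  margin <- 2
  yc <- config$dendrite_width / 2 + margin
  dendrite_trace(
    polyline = cbind(x = c(0, config$dendrite_length), y = c(yc, yc)),
    local_width = config$dendrite_width + 6 * config$psf_sigma,
    roi_centre = config$roi_centre,
    roi_halfwidth = config$roi_halfwidth)
}

#' @rdname sim_trace
#' @export
sim_background_mask <- function(config, band = 0.8) {
  px <- config$pixel_size
  nx <- round(config$dendrite_length / px)
  ny <- round((config$dendrite_width + 4) / px)
  rows <- which((seq_len(ny) - 0.5) * px < band)
  m <- matrix(FALSE, ny, nx)
  m[rows, ] <- TRUE
  m
}
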