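#' Dendrite trace with photoconversion ROI
#'
#' A traced dendrite is an ordered polyline in physical image coordinates
#' (um), a local ribbon width, and the position of the photoconversion ROI
#' expressed in arc length along the polyline. The ROI footprint (bin zero)
#' is the arc interval `roi_centre +/- roi_halfwidth`.
#'
#' @param polyline numeric matrix with columns `x`, `y` (um); at least two
#'   points, consecutive points distinct.
#' @param local_width ribbon width in um: a scalar or one value per vertex
#'   (linearly interpolated along the arc).
#' @param roi_centre arc-length position of the ROI centre, um.
#' @param roi_halfwidth ROI half-length along the arc, um.
#' @return A `dendrite_trace` object with precomputed cumulative arc length.
#' @export
dendrite_trace <- function(polyline, local_width, roi_centre, roi_halfwidth) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2L, nrow(polyline) >= 2L)
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen <= 0)) {
    stop("polyline arc length must be strictly increasing (duplicate vertices?)",
         call. = FALSE)
  }
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  if (!(length(local_width) %in% c(1L, nrow(polyline))) || any(local_width <= 0)) {
    stop("local_width must be a positive scalar or one value per vertex",
         call. = FALSE)
  }
  if (roi_halfwidth <= 0) stop("roi_halfwidth must be positive", call. = FALSE)
  if (roi_centre - roi_halfwidth < 0 || roi_centre + roi_halfwidth > total) {
    stop("ROI footprint must lie within the traced extent", call. = FALSE)
  }
  structure(list(polyline = polyline, arc = arc, total_arc = total,
                 local_width = local_width,
                 roi_centre = roi_centre, roi_halfwidth = roi_halfwidth),
            class = "dendrite_trace")
}

#' @export
print.dendrite_trace <- function(x, ...) {
  cat(sprintf("Dendrite trace: %d vertices, %.1f um arc, ROI %.1f +/- %.1f um, width %s um\n",
              nrow(x$polyline), x$total_arc, x$roi_centre, x$roi_halfwidth,
              paste(format(range(x$local_width), digits = 3), collapse = "-")))
  invisible(x)
}

# Project points (px, py) onto the polyline. Returns, per point, the
# arc-length coordinate of the nearest polyline point and the Euclidean
# distance to it.
project_to_trace <- function(trace, px, py) {
  P <- trace$polyline
  nseg <- nrow(P) - 1L
  best_d2 <- rep(Inf, length(px))
  best_s <- rep(NA_real_, length(px))
  for (i in seq_len(nseg)) {
    ax <- P[i, 1L]; ay <- P[i, 2L]
    dx <- P[i + 1L, 1L] - ax; dy <- P[i + 1L, 2L] - ay
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- trace$arc[i] + t[upd] * sqrt(len2)
  }
  list(s = best_s, d = sqrt(best_d2))
}

# Ribbon half-width at arc position s (linear interpolation between vertices).
width_at <- function(trace, s) {
  if (length(trace$local_width) == 1L) {
    rep(trace$local_width, length(s))
  } else {
    stats::approx(trace$arc, trace$local_width, xout = s, rule = 2)$y
  }
}

#' Read or write a dendrite trace as JSON
#'
#' The JSON schema has fields `polyline` (array of `[x, y]` um pairs),
#' `local_width`, `roi_centre` and `roi_halfwidth`.
#'
#' @param path file path.
#' @return `read_trace()` returns a [dendrite_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dendrite_trace(polyline = matrix(unlist(j$polyline), ncol = 2L, byrow = !is.matrix(j$polyline)),
                 local_width = j$local_width,
                 roi_centre = j$roi_centre, roi_halfwidth = j$roi_halfwidth)
}

#' @rdname read_trace
#' @param trace a `dendrite_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dendrite_trace"))
  jsonlite::write_json(list(polyline = unname(trace$polyline),
                            local_width = trace$local_width,
                            roi_centre = trace$roi_centre,
                            roi_halfwidth = trace$roi_halfwidth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
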