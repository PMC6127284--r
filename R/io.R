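#' Read and write movies and volumes as multi-page TIFF
#'
#' Movies are written as one page per frame with intensities scaled to the
#' 32-bit float range accepted by the TIFF writer, plus a JSON sidecar
#' (`<file>.json`) recording `pixel_size`, `frame_interval`, `timepoints` and
#' the intensity scale. Volumes are one page per z-plane with a sidecar
#' holding `voxel_size`.
#'
#' @param movie a [pc_movie()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "pc_movie"))
  scale <- max(movie$frames, 1)
  pages <- lapply(seq_len(dim(movie$frames)[3L]),
                  function(k) movie$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size = movie$pixel_size,
                            frame_interval = movie$frame_interval,
                            timepoints = movie$timepoints,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages))) *
    meta$intensity_scale
  pc_movie(frames, pixel_size = meta$pixel_size,
           frame_interval = meta$frame_interval,
           timepoints = meta$timepoints)
}

#' @rdname write_movie
#' @param volume numeric 3D array `(x, y, z)`.
#' @param voxel_size um per axis.
#' @export
write_volume <- function(volume, path, voxel_size) {
  stopifnot(length(dim(volume)) == 3L)
  scale <- max(volume, 1)
  pages <- lapply(seq_len(dim(volume)[3L]), function(k) volume[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size = rep(voxel_size, length.out = 3L),
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vol <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages))) *
    meta$intensity_scale
  attr(vol, "voxel_size") <- meta$voxel_size
  vol
}
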