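# Independent oracles and small constructors used across the suite.

# Hand-built wave matrix from a list of per-bin time series.
# series: named list "direction_bin" -> numeric vector over `times`.
make_wave <- function(series, times) {
  rows <- lapply(names(series), function(key) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    data.frame(direction = parts[1L], bin = as.numeric(parts[2L]),
               time_s = times, value = series[[key]], truncated = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("wave_matrix", "data.frame"),
            timepoints = times)
}

# Brute-force 26-connected component labelling by BFS flood fill.
flood_fill_labels <- function(binary) {
  d <- dim(binary)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nextlab <- 0L
  fg <- which(binary != 0)
  for (start in fg) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(cur, d)
      nb <- sweep(offs, 2L, as.numeric(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[binary[lin] != 0 & lab[lin] == 0L]
      lab[new] <- nextlab
      queue <- c(queue, new)
    }
  }
  lab
}

# Exhaustive upper-tail hypergeometric probability by enumeration of all
# possible DE-gene draws (N <= 12).
hyper_upper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, K)
  target <- seq_len(n)  # wlog the first n genes form the target set
  hits <- apply(draws, 2L, function(d) sum(d %in% target))
  mean(hits >= k)
}

# A small two-blob 3D volume with known maxima, for split tests.
two_blob_volume <- function(sep_vox = 6L, shape = c(32L, 32L, 16L), sigma = 1.6) {
  axes <- lapply(shape, seq_len)
  c1 <- c(shape[1] / 2 - sep_vox / 2, shape[2] / 2, shape[3] / 2)
  c2 <- c(shape[1] / 2 + sep_vox / 2, shape[2] / 2, shape[3] / 2)
  blob <- function(cen) {
    gx <- exp(-0.5 * ((axes[[1]] - cen[1]) / sigma)^2)
    gy <- exp(-0.5 * ((axes[[2]] - cen[2]) / sigma)^2)
    gz <- exp(-0.5 * ((axes[[3]] - cen[3]) / sigma)^2)
    outer(outer(gx, gy), gz)
  }
  blob(c1) + blob(c2)
}
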