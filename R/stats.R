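#' Group comparisons used for imaging-derived quantities
#'
#' One front-end for the statistical tests used to compare genotype
#' groups: two-tailed t test, one-way ANOVA with pairwise Bonferroni
#' post-tests, Kruskal-Wallis with Dunn's multiple-comparison test, and
#' two-way ANOVA (main effects plus interaction).
#'
#' @param data data frame with columns `value` and `group` (and `factor2` for
#'   the two-way design).
#' @param method one of `"t_test"`, `"anova_bonferroni"`, `"kruskal_dunn"`,
#'   `"two_way_anova"`.
#' @param var_equal for `t_test`: pooled-variance (classical) t test when
#'   `TRUE` (default), Welch when `FALSE`.
#' @return A `group_test` list: `method`, `omnibus` (data frame of statistic,
#'   df and p), and `pairwise` (adjusted post-hoc p values, where the method
#'   defines them).
#' @export
group_compare <- function(data,
                          method = c("t_test", "anova_bonferroni",
                                     "kruskal_dunn", "two_way_anova"),
                          var_equal = TRUE) {
  method <- match.arg(method)
  stopifnot(all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  ng <- nlevels(data$group)
  if (ng < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(data$group)
  if (method %in% c("t_test", "anova_bonferroni", "two_way_anova") &&
      any(sizes < 2L)) {
    stop("variance-based methods need at least two observations per group",
         call. = FALSE)
  }

  out <- switch(method,
    t_test = {
      if (ng != 2L) stop("t_test needs exactly two groups", call. = FALSE)
      tt <- stats::t.test(value ~ group, data = data, var.equal = var_equal)
      list(omnibus = data.frame(term = "group", statistic = unname(tt$statistic),
                                df = unname(tt$parameter), p = tt$p.value),
           pairwise = NULL)
    },
    anova_bonferroni = {
      fit <- stats::aov(value ~ group, data = data)
      s <- summary(fit)[[1L]]
      pw <- stats::pairwise.t.test(data$value, data$group,
                                   p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      list(omnibus = data.frame(term = "group", statistic = s$`F value`[1L],
                                df = s$Df[1L], df_resid = s$Df[2L],
                                p = s$`Pr(>F)`[1L]),
           pairwise = pairwise_long(pw$p.value))
    },
    kruskal_dunn = {
      kw <- stats::kruskal.test(value ~ group, data = data)
      list(omnibus = data.frame(term = "group", statistic = unname(kw$statistic),
                                df = unname(kw$parameter), p = kw$p.value),
           pairwise = dunn_test(data$value, data$group))
    },
    two_way_anova = {
      stopifnot("factor2" %in% names(data))
      data$factor2 <- factor(data$factor2)
      fit <- stats::aov(value ~ group * factor2, data = data)
      s <- summary(fit)[[1L]]
      terms <- trimws(rownames(s))
      keep <- terms != "Residuals"
      list(omnibus = data.frame(term = terms[keep], statistic = s$`F value`[keep],
                                df = s$Df[keep], df_resid = s$Df[!keep],
                                p = s$`Pr(>F)`[keep]),
           pairwise = NULL)
    })
  structure(c(list(method = method), out), class = "group_test")
}

pairwise_long <- function(pm) {
  idx <- which(!is.na(pm), arr.ind = TRUE)
  data.frame(group1 = rownames(pm)[idx[, 1L]],
             group2 = colnames(pm)[idx[, 2L]],
             p_adj = pm[idx])
}

#' @export
print.group_test <- function(x, ...) {
  cat("Group comparison:", x$method, "\n")
  print(x$omnibus, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise (adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Dunn's rank-based multiple-comparison test
#'
#' Pairwise z statistics on mean midranks after a Kruskal-Wallis test, with
#' the tie correction and Bonferroni adjustment across the reported pairs.
#'
#' @param value numeric observations.
#' @param group group labels.
#' @return Data frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(value, group) {
  group <- factor(group)
  N <- length(value)
  r <- rank(value)  # midranks for ties
  rbar <- tapply(r, group, mean)
  n <- table(group)
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(group)
  pairs <- utils::combn(lv, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = res["z", ], p = res["p", ])
  out$p_adj <- pmin(1, out$p * ncol(pairs))
  rownames(out) <- NULL
  out
}

#' Timepoint-paired comparison of two wave-matrix sets
#'
#' For every (direction, bin) the per-timepoint group means are compared by a
#' two-tailed t test paired on the timepoint: the per-timepoint difference of
#' group means is tested against zero across the shared timepoints. This is
#' the bin-wise genotype comparison of pulse-chase waves.
#'
#' @param waves_A,waves_B lists of `wave_matrix` objects (one per neuron per
#'   group) on identical (direction, bin, timepoint) grids.
#' @param exclude_t0 drop t = 0 from the pairing (both groups are normalised
#'   to 1 in bin zero at t = 0); default `TRUE`.
#' @return Data frame: `direction`, `bin`, `t`, `df`, `p`.
#' @export
paired_wave_test <- function(waves_A, waves_B, exclude_t0 = TRUE) {
  stack <- function(waves) {
    do.call(rbind, lapply(seq_along(waves), function(i) {
      w <- as.data.frame(waves[[i]])
      w$neuron <- i
      w
    }))
  }
  A <- stack(waves_A); B <- stack(waves_B)
  key <- function(d) unique(d[order(d$direction, d$bin, d$time_s),
                              c("direction", "bin", "time_s")])
  if (!identical(key(A), key(B))) {
    stop("wave sets are on different (direction, bin, timepoint) grids",
         call. = FALSE)
  }
  agg <- function(d) stats::aggregate(value ~ direction + bin + time_s,
                                      data = d, FUN = mean)
  mA <- agg(A); mB <- agg(B)
  m <- merge(mA, mB, by = c("direction", "bin", "time_s"),
             suffixes = c("_A", "_B"))
  if (exclude_t0) m <- m[m$time_s > 0, ]
  cells <- unique(m[, c("direction", "bin")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    mm <- m[m$direction == cells$direction[i] & m$bin == cells$bin[i], ]
    dif <- mm$value_A - mm$value_B
    tt <- if (stats::sd(dif) > 0) {
      tryCatch(stats::t.test(dif), error = function(e) NULL)
    }
    if (is.null(tt)) {
      # degenerate series: identical groups (p = 1) or an (essentially)
      # constant nonzero shift (as significant as the pairing can make it)
      tval <- if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf
      pval <- if (mean(dif) == 0) 1 else 0
    } else {
      tval <- unname(tt$statistic)
      pval <- tt$p.value
    }
    data.frame(direction = cells$direction[i], bin = cells$bin[i],
               t = tval, df = length(dif) - 1L, p = pval)
  })
  out <- do.call(rbind, res)
  out[order(out$direction, out$bin), ]
}
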