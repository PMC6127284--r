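#' Locus enrichment of a differentially expressed gene list
#'
#' Two complementary statistics for asking whether DE genes are enriched in a
#' collection of disease-associated loci. The gene-level statistic is the
#' upper-tail hypergeometric probability of observing at least `k` DE genes
#' among the `n` genes contained in the loci, drawing `K` DE genes from a
#' universe of `N` expressed genes. The locus-level statistic counts loci
#' containing at least one DE gene and compares it with a permutation null in
#' which `K` genes are drawn uniformly from the universe; this respects
#' unequal locus sizes. Neither is a claim about how any published
#' "hypergeometric probability" over loci was constructed -- both are
#' reported, with the observed and expected counts.
#'
#' @param universe character vector of expressed genes (the universe, size N).
#' @param de_genes character vector of DE genes; intersected with the
#'   universe (size K).
#' @param loci named list of character vectors: the locus gene sets; each is
#'   intersected with the universe.
#' @param target_set optional explicit gene set for the gene-level test;
#'   defaults to the union of all locus genes.
#' @param n_permutations number of permutation draws (default 10000).
#' @param seed integer seed for the permutation null.
#' @return An `enrichment_result`: `gene_level` (N, K, n, k, expected,
#'   p = P(X >= k)) and `locus_level` (n_loci, observed hit loci, expected
#'   under the null, permutation p, n_permutations, seed).
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' res <- locus_enrichment(u, u[1:20], list(L1 = u[1:5], L2 = u[60:64]),
#'                         n_permutations = 1000, seed = 1)
#' res$gene_level$p
#' @export
locus_enrichment <- function(universe, de_genes, loci, target_set = NULL,
                             n_permutations = 10000L, seed = 1L) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  de <- intersect(unique(as.character(de_genes)), universe)
  K <- length(de)
  loci <- lapply(loci, function(g) intersect(unique(as.character(g)), universe))
  if (is.null(target_set)) target_set <- unique(unlist(loci))
  target_set <- intersect(unique(as.character(target_set)), universe)
  n <- length(target_set)
  k <- length(intersect(de, target_set))

  gene_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  gene_level <- list(N = N, K = K, n = n, k = k,
                     expected = n * K / N, p = gene_p)

  # locus-level permutation: draw K genes uniformly, count loci hit
  uni_idx <- seq_len(N)
  loci_idx <- lapply(loci, function(g) match(g, universe))
  observed <- sum(vapply(loci_idx, function(ix) any(ix %in% match(de, universe)),
                         logical(1)))
  set.seed(seed)
  member <- logical(N)
  null_counts <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    draw <- sample.int(N, K)
    member[draw] <- TRUE
    null_counts[p] <- sum(vapply(loci_idx, function(ix) any(member[ix]),
                                 logical(1)))
    member[draw] <- FALSE
  }
  perm_p <- (1 + sum(null_counts >= observed)) / (n_permutations + 1)
  locus_level <- list(n_loci = length(loci), observed = observed,
                      expected = mean(null_counts), p = perm_p,
                      n_permutations = n_permutations, seed = seed)
  structure(list(gene_level = gene_level, locus_level = locus_level),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  g <- x$gene_level; l <- x$locus_level
  cat(sprintf("Gene-level enrichment: %d of %d target genes DE (expected %.1f; universe %d, DE %d)\n",
              g$k, g$n, g$expected, g$N, g$K))
  cat(sprintf("  hypergeometric P(X >= %d) = %.3g\n", g$k, g$p))
  cat(sprintf("Locus-level: %d of %d loci contain a DE gene (null mean %.1f)\n",
              l$observed, l$n_loci, l$expected))
  cat(sprintf("  permutation p = %.3g (%d draws, seed %d)\n",
              l$p, l$n_permutations, l$seed))
  invisible(x)
}

#' Generate a gene universe with planted locus enrichment
#'
#' Builds a synthetic expressed-gene universe, a set of named loci, and a DE
#' list of exactly `n_de` genes drawn without replacement with locus genes
#' weighted `planted_fold_enrichment`-fold relative to background, so the DE
#' rate inside loci is (in expectation) the planted fold times the background
#' rate; fold 1 is the null. Defaults emulate a study-scale universe: 22,753
#' expressed genes, 1,256 DE, 108 loci jointly containing 348 genes.
#'
#' @param universe_size number of genes in the universe.
#' @param n_de number of DE genes (drawn exactly).
#' @param n_loci number of loci.
#' @param locus_genes total genes distributed over the loci (each locus gets
#'   at least one).
#' @param planted_fold_enrichment DE-rate fold for locus genes; clipped with
#'   a warning if `fold * n_de / universe_size` would exceed 1.
#' @param seed integer seed.
#' @return An `enrichment_truth` list: `universe`, `de_genes`, `loci` (named
#'   list), and the planted parameters.
#' @export
make_enrichment_universe <- function(universe_size = 22753L,
                                     n_de = 1256L,
                                     n_loci = 108L,
                                     locus_genes = 348L,
                                     planted_fold_enrichment = 1.7,
                                     seed = 1L) {
  stopifnot(n_de <= universe_size, locus_genes >= n_loci,
            locus_genes <= universe_size, planted_fold_enrichment > 0)
  set.seed(seed)
  universe <- sprintf("gene%05d", seq_len(universe_size))

  # locus sizes: at least one gene each, remainder multinomially distributed
  extra <- stats::rmultinom(1L, locus_genes - n_loci, rep(1, n_loci))[, 1L]
  sizes <- 1L + extra
  locus_members <- split(sample(universe, locus_genes),
                         rep(seq_len(n_loci), sizes))
  names(locus_members) <- sprintf("locus%03d", seq_len(n_loci))

  fold <- planted_fold_enrichment
  if (fold * n_de / universe_size > 1) {
    fold <- universe_size / n_de
    warning("planted fold would push locus DE probability above 1; clipped to ",
            format(fold, digits = 4), call. = FALSE)
  }
  w <- rep(1, universe_size)
  w[universe %in% unlist(locus_members)] <- fold
  de <- sample(universe, n_de, prob = w)

  structure(list(universe = universe, de_genes = de, loci = locus_members,
                 planted_fold_enrichment = fold, n_de = n_de, seed = seed),
            class = "enrichment_truth")
}

#' @export
print.enrichment_truth <- function(x, ...) {
  cat(sprintf("Synthetic enrichment universe: %d genes, %d DE, %d loci (%d genes), planted fold %.3g, seed %d\n",
              length(x$universe), length(x$de_genes), length(x$loci),
              length(unlist(x$loci)), x$planted_fold_enrichment, x$seed))
  invisible(x)
}

#' Read and write GMT gene-set files and plain gene lists
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#' Gene lists: one gene per line (TSV with no header).
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param description description column (recycled).
#' @return `read_gmt()` returns a named list; `read_gene_list()` a character
#'   vector; writers return `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep(description, length.out = length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  trimws(x[nzchar(trimws(x))])
}

#' @rdname read_gmt
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
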