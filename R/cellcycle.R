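#' Fine bins of the cell-cycle distance range
#'
#' The 58 CDP fine bins lying fully inside 50 kb - 8 Mb (left-edge exponents
#' 15.625 to 22.75), the contact-distance range that best captures cell-cycle
#' dynamics in single-cell Hi-C.
#'
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return integer vector of 1-based fine-bin indices.
#' @export
cellcycle_bins <- function(scheme = cdp_bin_edges()) {
  bins_in_range(50e3, 8e6, scheme)
}

#' Per-cell cell-cycle CDPs
#'
#' Non-allelic contact-decay profiles aggregated over all autosomes (chrX
#' excluded; hap1, hap2 and ambiguous pairs all included), restricted to the
#' 58 fine bins fully inside 50 kb - 8 Mb, and normalized to proportions.
#'
#' @param table a [contact_table()] of informative contacts.
#' @param cells cells to profile (default: all in `table`).
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return object of class `cellcycle_profiles`: list with `counts` (cells x
#'   58 proportions), `cell_id`, `n_contacts` (in-range contacts per cell),
#'   `low_coverage` flags.
#' @export
cellcycle_profile <- function(table, cells = NULL,
                              scheme = cdp_bin_edges()) {
  stopifnot(inherits(table, "contact_table"))
  genome <- attr(table, "genome")
  if (is.null(cells)) cells <- unique(table$cell_id)
  auto <- autosomes(genome)
  keep <- table$chrom_a == table$chrom_b & table$chrom_a %in% auto &
    table$cell_id %in% cells
  sub <- table[keep, , drop = FALSE]
  bins <- assign_cdp_bin(abs(sub$pos_a - sub$pos_b), scheme)
  cc_bins <- cellcycle_bins(scheme)
  ok <- !is.na(bins) & bins %in% cc_bins
  counts <- matrix(0, length(cells), length(cc_bins),
                   dimnames = list(cells, NULL))
  if (any(ok)) {
    tab <- table(factor(sub$cell_id[ok], levels = cells),
                 factor(bins[ok], levels = cc_bins))
    counts[] <- as.matrix(tab)
  }
  n <- rowSums(counts)
  structure(list(counts = counts / ifelse(n > 0, n, 1),
                 cell_id = cells, n_contacts = n, low_coverage = n == 0),
            class = "cellcycle_profiles")
}

#' @export
print.cellcycle_profiles <- function(x, ...) {
  cat("cellcycle_profiles:", length(x$cell_id), "cells x",
      ncol(x$counts), "bins;", sum(x$low_coverage), "low-coverage\n")
  invisible(x)
}

#' Short-range and mitotic-band contact fractions
#'
#' Per cell, the proportions of autosomal informative intrachromosomal
#' contacts falling in the short range (1 kb - 2 Mb) and the mitotic band
#' (2 - 12 Mb), the QC scatter used to verify cell-cycle clusters. Mitotic
#' chromosomes show a strong 2-12 Mb enrichment.
#'
#' @param table a [contact_table()] of informative contacts.
#' @param cells cells to evaluate (default: all in `table`).
#' @param short_range,band_range half-open distance ranges in bp.
#' @return data.frame: `cell_id`, `short_range_fraction`,
#'   `mitotic_band_fraction` (`NA` for cells with no autosomal contacts).
#' @export
band_fractions <- function(table, cells = NULL,
                           short_range = c(1e3, 2e6),
                           band_range = c(2e6, 12e6)) {
  stopifnot(inherits(table, "contact_table"))
  genome <- attr(table, "genome")
  if (is.null(cells)) cells <- unique(table$cell_id)
  keep <- table$chrom_a == table$chrom_b &
    table$chrom_a %in% autosomes(genome) & table$cell_id %in% cells
  sub <- table[keep, , drop = FALSE]
  d <- abs(sub$pos_a - sub$pos_b)
  informative <- d > 1000
  f <- factor(sub$cell_id, levels = cells)
  tot <- tabulate(f[informative], nbins = length(cells))
  n_short <- tabulate(f[informative & d >= short_range[1] & d < short_range[2]],
                      nbins = length(cells))
  n_band <- tabulate(f[informative & d >= band_range[1] & d < band_range[2]],
                     nbins = length(cells))
  data.frame(cell_id = cells,
             short_range_fraction = ifelse(tot > 0, n_short / tot, NA_real_),
             mitotic_band_fraction = ifelse(tot > 0, n_band / tot, NA_real_),
             stringsAsFactors = FALSE)
}

# rank-transform rows, center, unit-normalize: squared Euclidean distance on
# these vectors is an affine function of (1 - Spearman rho)
spearman_embed <- function(m) {
  t(apply(m, 1, function(v) {
    r <- rank(v, ties.method = "average")
    r <- r - mean(r)
    nrm <- sqrt(sum(r^2))
    if (nrm == 0) rep(0, length(r)) else r / nrm
  }))
}

#' Stage cells through the cell cycle by k-means on autosomal CDPs
#'
#' Clusters the cell-cycle CDPs into `k` groups with k-means under a Spearman
#' correlation distance, operationalized by rank-transforming each profile,
#' centering and unit-normalizing, then running Euclidean k-means (squared
#' Euclidean distance on the transformed vectors is affine in 1 - Spearman
#' rho). The cluster with the highest mean mitotic-band fraction is labelled
#' mitotic (stage 1); remaining clusters are ordered by decreasing
#' short-range fraction as interphase progression (stages 2..k).
#'
#' Clustering is deterministic given `seed` and invariant to input order:
#' profiles are put in a canonical (lexicographic) order before seeding
#' k-means.
#'
#' @param profiles a `cellcycle_profiles` object (low-coverage cells are
#'   dropped).
#' @param bands data.frame from [band_fractions()] for the same cells.
#' @param k number of clusters (default 4).
#' @param seed integer RNG seed for the k-means initialization.
#' @param nstart random restarts (default 10).
#' @return object of class `cellcycle_assignment`: data.frame `cell_id`,
#'   `cluster`, `stage` (1 = mitotic), `short_range_fraction`,
#'   `mitotic_band_fraction`.
#' @export
cluster_cellcycle <- function(profiles, bands, k = 4, seed = 1,
                              nstart = 10) {
  stopifnot(inherits(profiles, "cellcycle_profiles"))
  keep <- !profiles$low_coverage
  m <- profiles$counts[keep, , drop = FALSE]
  cells <- profiles$cell_id[keep]
  if (nrow(m) < k)
    abort("need at least k = ", k, " cells with coverage; got ", nrow(m))
  emb <- spearman_embed(m)
  if (nrow(unique(emb)) < k)
    abort("cells do not separate: fewer than k distinct profiles")
  ord <- do.call(order, as.data.frame(emb))
  emb_sorted <- emb[ord, , drop = FALSE]
  withr_seed <- function(expr) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(seed)
    expr
  }
  km <- withr_seed(stats::kmeans(emb_sorted, centers = k, nstart = nstart,
                                 iter.max = 100))
  cluster <- integer(nrow(emb))
  cluster[ord] <- km$cluster
  bf <- bands[match(cells, bands$cell_id), ]
  band_mean <- tapply(bf$mitotic_band_fraction, cluster, mean, na.rm = TRUE)
  short_mean <- tapply(bf$short_range_fraction, cluster, mean, na.rm = TRUE)
  mitotic <- as.integer(names(band_mean)[which.max(band_mean)])
  others <- setdiff(as.integer(names(band_mean)), mitotic)
  others <- others[order(short_mean[as.character(others)],
                         decreasing = TRUE)]
  stage_of <- integer(k)
  stage_of[mitotic] <- 1L
  stage_of[others] <- seq_along(others) + 1L
  out <- data.frame(cell_id = cells, cluster = cluster,
                    stage = stage_of[cluster],
                    short_range_fraction = bf$short_range_fraction,
                    mitotic_band_fraction = bf$mitotic_band_fraction,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cellcycle_assignment", "data.frame"))
}

#' @export
print.cellcycle_assignment <- function(x, ...) {
  cat("cellcycle_assignment:", nrow(x), "cells\n")
  print(table(stage = x$stage))
  invisible(x)
}
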