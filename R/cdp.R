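#' Logarithmic contact-distance bin scheme
#'
#' Contact-decay profiles (CDPs) count intrachromosomal contacts within
#' exponentially increasing distance ranges. Bin k (k = 0..142) is the
#' half-open interval `[2^(10 + 0.125 k), 2^(10 + 0.125 (k + 1)))` bp:
#' 143 bins, first left edge 1024 bp, last left edge 2^27.75 bp.
#'
#' @param x0 first exponent (default 10).
#' @param x_end last left-edge exponent (default 27.750).
#' @param step exponent step (default 0.125).
#' @return object of class `cdp_bin_scheme`: list with `exponents` (left-edge
#'   exponents, length `n_bins`), `edges` (length `n_bins + 1`; the last edge
#'   is the exclusive upper bound of the last bin) and `n_bins`.
#' @examples
#' sch <- cdp_bin_edges()
#' sch$n_bins        # 143
#' sch$edges[1]      # 1024
#' @export
cdp_bin_edges <- function(x0 = 10, x_end = 27.750, step = 0.125) {
  exponents <- seq(x0, x_end, by = step)
  edges <- 2^c(exponents, x_end + step)
  structure(list(exponents = exponents, edges = edges,
                 n_bins = length(exponents), x0 = x0, step = step),
            class = "cdp_bin_scheme")
}

#' @export
print.cdp_bin_scheme <- function(x, ...) {
  cat("cdp_bin_scheme:", x$n_bins, "bins, [", x$edges[1], ",",
      format(x$edges[length(x$edges)], big.mark = ","), ") bp, step 2^",
      x$step, "\n")
  invisible(x)
}

#' Assign contact distances to CDP bins
#'
#' Half-open bin membership on the edge grid: distance d falls in bin k iff
#' `edges[k] <= d < edges[k + 1]`. Distances below the first edge or at/above
#' the last edge get `NA`.
#'
#' @param distances numeric vector of contact distances in bp.
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return integer vector of 1-based bin indices in `1..n_bins`, `NA` for
#'   out-of-range distances.
#' @export
assign_cdp_bin <- function(distances, scheme = cdp_bin_edges()) {
  k <- findInterval(distances, scheme$edges)
  k[k < 1L | k > scheme$n_bins | !is.finite(distances)] <- NA_integer_
  as.integer(k)
}

#' Raw contact-decay profile from contact distances
#'
#' Counts distances per CDP bin; distances outside the scheme's range are
#' excluded.
#'
#' @param distances numeric vector of intrachromosomal contact distances (bp).
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return numeric vector of length `scheme$n_bins` of counts.
#' @export
compute_cdp <- function(distances, scheme = cdp_bin_edges()) {
  bins <- assign_cdp_bin(distances, scheme)
  tabulate(bins[!is.na(bins)], nbins = scheme$n_bins)
}

#' Build per-(cell, chromosome, allele) CDPs from a contact table
#'
#' Intrachromosomal contacts are grouped by cell, chromosome and allele and
#' histogrammed on the logarithmic distance grid. The full grid of requested
#' cells x chromosomes x alleles is emitted, so absent combinations appear
#' with zero contacts (needed by [coverage_select()]).
#'
#' @param table a [contact_table()]; apply [informative_contacts()] first.
#' @param chroms chromosomes to profile (default: all in the genome table).
#' @param alleles allele tags to profile separately (default
#'   `c("hap1","hap2")`; ambiguous pairs are excluded from allelic profiles).
#' @param cells cells to profile (default: all cells in `table`).
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return object of class `cdp_set`: list with `counts` (profiles x bins
#'   matrix), `info` (data.frame `cell_id`, `chrom`, `allele`, `n_contacts`,
#'   `low_coverage`), `normalized`, `scheme`.
#' @export
cdp_profiles <- function(table, chroms = NULL, alleles = c("hap1", "hap2"),
                         cells = NULL, scheme = cdp_bin_edges()) {
  stopifnot(inherits(table, "contact_table"))
  genome <- attr(table, "genome")
  if (is.null(chroms)) chroms <- genome$name
  if (is.null(cells)) cells <- unique(table$cell_id)
  keep <- table$chrom_a == table$chrom_b &
    table$chrom_a %in% chroms & table$allele %in% alleles &
    table$cell_id %in% cells
  sub <- table[keep, , drop = FALSE]
  info <- expand.grid(allele = alleles, chrom = chroms, cell_id = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  info <- info[, c("cell_id", "chrom", "allele")]
  key <- function(cell, chrom, allele) paste(cell, chrom, allele, sep = "\r")
  row_of <- match(key(sub$cell_id, sub$chrom_a, sub$allele),
                  key(info$cell_id, info$chrom, info$allele))
  bins <- assign_cdp_bin(abs(sub$pos_a - sub$pos_b), scheme)
  ok <- !is.na(bins)
  counts <- matrix(0, nrow(info), scheme$n_bins)
  if (any(ok)) {
    tab <- table(factor(row_of[ok], levels = seq_len(nrow(info))), bins[ok])
    counts[, as.integer(colnames(tab))] <- as.matrix(tab)
  }
  info$n_contacts <- rowSums(counts)
  info$low_coverage <- info$n_contacts == 0
  rownames(info) <- NULL
  structure(list(counts = counts, info = info, normalized = FALSE,
                 scheme = scheme),
            class = "cdp_set")
}

#' @export
print.cdp_set <- function(x, ...) {
  cat("cdp_set:", nrow(x$counts), "profiles x", ncol(x$counts), "bins",
      if (x$normalized) "(normalized)" else "(raw counts)", "\n")
  cat("cells:", length(unique(x$info$cell_id)),
      " chroms:", paste(unique(x$info$chrom), collapse = ","),
      " alleles:", paste(unique(x$info$allele), collapse = ","), "\n")
  invisible(x)
}

#' Scale-normalize CDPs to proportions
#'
#' Divides each profile by its total contact count so profiles are comparable
#' across cells of different coverage. Zero-coverage profiles stay all-zero
#' and are flagged `low_coverage`.
#'
#' @param x a `cdp_set` of raw counts.
#' @return a normalized `cdp_set`.
#' @export
normalize_cdp <- function(x) {
  stopifnot(inherits(x, "cdp_set"))
  if (x$normalized) return(x)
  n <- x$info$n_contacts
  x$counts <- x$counts / ifelse(n > 0, n, 1)
  x$info$low_coverage <- n == 0
  x$normalized <- TRUE
  x
}

# fine-bin (1-based) indices of the 14 rebin groups; trailing 3 fine bins
# (>= 2^27.5 bp, longer than any mouse chromosome) are dropped
rebin_groups <- function(n_fine = 143, group_size = 10) {
  n_groups <- n_fine %/% group_size
  split(seq_len(n_groups * group_size),
        rep(seq_len(n_groups), each = group_size))
}

#' Rebin 143-bin CDPs into 14 coarse bins
#'
#' Aggregates non-overlapping groups of 10 consecutive logarithmic bins to
#' reduce sparsity noise; the trailing 3 fine bins (distances beyond any
#' mouse chromosome) are dropped.
#'
#' @param x a `cdp_set` with 143-bin profiles (raw or normalized).
#' @return a `cdp_set` whose `counts` has 14 columns; `scheme` is replaced by
#'   a `rebinned` marker list recording the grouping.
#' @export
rebin_cdp <- function(x) {
  stopifnot(inherits(x, "cdp_set"), ncol(x$counts) == 143)
  groups <- rebin_groups(ncol(x$counts))
  coarse <- vapply(groups, function(g) rowSums(x$counts[, g, drop = FALSE]),
                   numeric(nrow(x$counts)))
  if (nrow(x$counts) == 1) coarse <- matrix(coarse, nrow = 1)
  x$counts <- coarse
  x$scheme <- list(rebinned = TRUE, group_size = 10, n_bins = length(groups),
                   parent = x$scheme)
  x
}

#' Z-scale a profile matrix per bin column across cells
#'
#' Standardizes each bin column to mean 0 and (population) standard deviation
#' 1 across cells; constant columns map to 0. Matches the transformation used
#' for CDP heatmap displays.
#'
#' @param profiles numeric matrix, cells in rows, bins in columns (>= 2 rows),
#'   or a `cdp_set` (its `counts` are scaled in place).
#' @return same shape as the input.
#' @export
zscale_profiles <- function(profiles) {
  if (inherits(profiles, "cdp_set")) {
    profiles$counts <- zscale_profiles(profiles$counts)
    return(profiles)
  }
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2)
    abort("z-scaling needs at least 2 cells (sd undefined)")
  mu <- colMeans(profiles)
  sdev <- sqrt(colMeans(sweep(profiles, 2, mu)^2))
  centered <- sweep(profiles, 2, mu)
  out <- sweep(centered, 2, ifelse(sdev > 0, sdev, 1), "/")
  out[, sdev == 0] <- 0
  out
}

#' Select cells meeting per-allele coverage
#'
#' Keeps cells with at least `min_per_allele` intrachromosomal contacts for
#' every requested (chromosome, allele) combination — e.g. at least 100
#' contacts per allele along both chr1 and chrX for Patski fibroblasts, 50
#' for the differentiation time-course lines.
#'
#' @param x a `cdp_set` covering the requested chromosomes and alleles.
#' @param min_per_allele minimum contacts per (chromosome, allele).
#' @param chroms chromosomes whose coverage is required (default
#'   `c("chr1","chrX")`).
#' @param alleles alleles required (default `c("hap1","hap2")`).
#' @return character vector of passing cell ids.
#' @export
coverage_select <- function(x, min_per_allele, chroms = c("chr1", "chrX"),
                            alleles = c("hap1", "hap2")) {
  stopifnot(inherits(x, "cdp_set"))
  info <- x$info[x$info$chrom %in% chroms & x$info$allele %in% alleles, ]
  needed <- length(chroms) * length(alleles)
  if (!nrow(info)) return(character())
  ok <- tapply(info$n_contacts >= min_per_allele, info$cell_id,
               function(v) length(v) == needed && all(v))
  names(ok)[ok]
}
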