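#' Feature x cell x allele UMI count container
#'
#' Holds per-allele UMI count matrices (genes for sci-RNA-seq expression,
#' peak regions for sci-ATAC-seq accessibility) with feature and cell
#' metadata.
#'
#' @param hap1,hap2 numeric matrices (features x cells) of non-negative
#'   integer UMI counts, same dimensions.
#' @param features data.frame with columns `feature`, `chrom` (one row per
#'   matrix row).
#' @param cells data.frame with column `cell_id` (one row per matrix column);
#'   extra columns (`time_point`, `sex`, `line`) are carried along.
#' @return object of class `allelic_counts`.
#' @export
allelic_counts <- function(hap1, hap2, features, cells) {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            all(dim(hap1) == dim(hap2)),
            nrow(features) == nrow(hap1), nrow(cells) == ncol(hap1))
  if (min(hap1, 0) < 0 || min(hap2, 0) < 0)
    abort("UMI counts must be non-negative")
  if (!all(c("feature", "chrom") %in% names(features)))
    abort("features needs 'feature' and 'chrom' columns")
  if (!"cell_id" %in% names(cells)) abort("cells needs a 'cell_id' column")
  dimnames(hap1) <- dimnames(hap2) <- list(features$feature, cells$cell_id)
  structure(list(hap1 = hap1, hap2 = hap2, features = features,
                 cells = cells),
            class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat("allelic_counts:", nrow(x$hap1), "features x", ncol(x$hap1),
      "cells x 2 alleles;",
      sum(x$hap1) + sum(x$hap2), "UMIs\n")
  invisible(x)
}

# subset an allelic_counts by feature / cell index
subset_allelic <- function(x, features = NULL, cells = NULL) {
  if (is.null(features)) features <- seq_len(nrow(x$hap1))
  if (is.null(cells)) cells <- seq_len(ncol(x$hap1))
  allelic_counts(x$hap1[features, cells, drop = FALSE],
                 x$hap2[features, cells, drop = FALSE],
                 x$features[features, , drop = FALSE],
                 x$cells[cells, , drop = FALSE])
}

#' Feature and cell inclusion filters for allelic count matrices
#'
#' Features are kept if they have coverage along one allele in at least
#' `min_cells_per_feature` cells; cells are kept if their chr1 and chrX
#' allelic totals meet `min_umis_per_allele_per_chrom` UMIs — per allele
#' (`allele_rule = "per_allele"`, the default) or summed over both alleles
#' (`"combined"`, used for skew calling so that a fully silenced allele
#' remains callable).
#'
#' @param x an `allelic_counts` object.
#' @param min_cells_per_feature default 10.
#' @param min_umis_per_allele_per_chrom default 10.
#' @param chroms chromosomes whose totals gate cells (default
#'   `c("chr1","chrX")`).
#' @param allele_rule `"per_allele"` or `"combined"`.
#' @return a filtered `allelic_counts` object.
#' @export
feature_cell_filters <- function(x, min_cells_per_feature = 10,
                                 min_umis_per_allele_per_chrom = 10,
                                 chroms = c("chr1", "chrX"),
                                 allele_rule = c("per_allele", "combined")) {
  stopifnot(inherits(x, "allelic_counts"))
  allele_rule <- match.arg(allele_rule)
  feat_keep <- rowSums(x$hap1 > 0) >= min_cells_per_feature |
    rowSums(x$hap2 > 0) >= min_cells_per_feature
  cell_keep <- rep(TRUE, ncol(x$hap1))
  for (ch in chroms) {
    f <- x$features$chrom == ch
    t1 <- colSums(x$hap1[f, , drop = FALSE])
    t2 <- colSums(x$hap2[f, , drop = FALSE])
    cell_keep <- cell_keep & if (allele_rule == "per_allele") {
      t1 >= min_umis_per_allele_per_chrom &
        t2 >= min_umis_per_allele_per_chrom
    } else {
      (t1 + t2) >= min_umis_per_allele_per_chrom
    }
  }
  if (!any(feat_keep) || !any(cell_keep))
    warning("filters removed all features or cells")
  subset_allelic(x, which(feat_keep), which(cell_keep))
}

#' Total allelic UMI counts per cell for one chromosome
#'
#' The TAE (total allelic expression) for sci-RNA-seq or TAA (total allelic
#' accessibility) for sci-ATAC-seq.
#'
#' @param x an `allelic_counts` object.
#' @param chrom chromosome (default `"chrX"`).
#' @return data.frame: `cell_id`, `total_hap1`, `total_hap2`.
#' @export
total_allelic <- function(x, chrom = "chrX") {
  stopifnot(inherits(x, "allelic_counts"))
  f <- x$features$chrom == chrom
  data.frame(cell_id = x$cells$cell_id,
             total_hap1 = colSums(x$hap1[f, , drop = FALSE]),
             total_hap2 = colSums(x$hap2[f, , drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allelic log2 ratio with pseudocount
#'
#' `log2((total_hap1 + pseudocount) / (total_hap2 + pseudocount))`; the
#' pseudocount keeps fully silenced alleles (0 UMIs) at a finite ratio.
#'
#' @param total_hap1,total_hap2 non-negative totals (vectorized).
#' @param pseudocount default 1.
#' @return numeric ratio(s).
#' @export
allelic_log2_ratio <- function(total_hap1, total_hap2, pseudocount = 1) {
  if (any(total_hap1 < 0, na.rm = TRUE) || any(total_hap2 < 0, na.rm = TRUE))
    abort("totals must be non-negative")
  log2((total_hap1 + pseudocount) / (total_hap2 + pseudocount))
}

#' Call per-cell XCI status from allelic log2 ratios
#'
#' A cell is called as having undergone XCI iff its absolute log2 ratio
#' strictly exceeds the threshold. A ratio skewed left (negative: hap1 total
#' lower) means the hap1 homolog is silenced and hap2 is the active X, and
#' symmetrically for a right skew.
#'
#' @param totals data.frame from [total_allelic()].
#' @param spec a `threshold_spec` from [fpr_threshold()] (direction `"abs"`)
#'   derived from the chr1 ratio null.
#' @param pseudocount for the ratio (default 1).
#' @return data.frame: `cell_id`, `total_hap1`, `total_hap2`, `log2_ratio`,
#'   `xci_status` (`biallelic` / `hap1_silenced` / `hap2_silenced` /
#'   `no_call`), `xa_allele` (`hap1`/`hap2`/`none`).
#' @export
call_xci <- function(totals, spec, pseudocount = 1) {
  stopifnot(inherits(spec, "threshold_spec"), spec$direction == "abs")
  r <- allelic_log2_ratio(totals$total_hap1, totals$total_hap2, pseudocount)
  called <- threshold_call(r, spec)
  status <- ifelse(is.na(called), "no_call",
                   ifelse(!called, "biallelic",
                          ifelse(r < 0, "hap1_silenced", "hap2_silenced")))
  xa <- ifelse(status == "hap1_silenced", "hap2",
               ifelse(status == "hap2_silenced", "hap1", "none"))
  cbind(totals,
        data.frame(log2_ratio = r, xci_status = status, xa_allele = xa,
                   stringsAsFactors = FALSE))
}

#' Fit the allelic-skew XCI classifier
#'
#' Mirrors the structure classifier: the per-cell total allelic UMI log2
#' ratio is computed on chr1 (expected biallelic, the null) and chrX; the
#' call threshold is the empirical quantile of |chr1 ratio| at the requested
#' FPR; chrX cells beyond it are called as having undergone XCI, with the
#' higher-total homolog as the Xa. ATAC data follow the same path with peak
#' regions as features, after a per-cell total-UMI prefilter.
#'
#' @param x an `allelic_counts` object (unfiltered; filters applied here).
#' @param modality `"rna"` or `"atac"`.
#' @param fpr nominal false-positive rate (default 0.10).
#' @param null_chrom,target_chrom defaults `"chr1"`, `"chrX"`.
#' @param pseudocount ratio pseudocount (default 1).
#' @param min_cells_per_feature feature filter (default 10).
#' @param min_umis_per_allele_per_chrom cell filter (default 10), applied
#'   with the `"combined"` allele rule so silenced cells stay callable.
#' @param min_total_umis per-cell total-UMI prefilter; default 0 for RNA,
#'   500 for ATAC.
#' @param groups optional named vector (cell id -> group label).
#' @return object of class `skew_fit`: list with `modality`, `threshold`,
#'   `null_ratios`, `calls` (the [call_xci()] table plus optional `group`),
#'   `n_cells_in`, `n_cells_kept`.
#' @export
skew_classifier <- function(x, modality = c("rna", "atac"), fpr = 0.10,
                            null_chrom = "chr1", target_chrom = "chrX",
                            pseudocount = 1, min_cells_per_feature = 10,
                            min_umis_per_allele_per_chrom = 10,
                            min_total_umis = NULL, groups = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(x, "allelic_counts"))
  if (is.null(min_total_umis))
    min_total_umis <- if (modality == "atac") 500 else 0
  n_in <- ncol(x$hap1)
  if (min_total_umis > 0) {
    depth <- colSums(x$hap1) + colSums(x$hap2)
    x <- subset_allelic(x, cells = which(depth >= min_total_umis))
  }
  xf <- feature_cell_filters(x, min_cells_per_feature,
                             min_umis_per_allele_per_chrom,
                             chroms = c(null_chrom, target_chrom),
                             allele_rule = "combined")
  null_tot <- total_allelic(xf, null_chrom)
  null_ratios <- allelic_log2_ratio(null_tot$total_hap1,
                                    null_tot$total_hap2, pseudocount)
  spec <- fpr_threshold(abs(null_ratios), fpr = fpr, direction = "abs",
                        statistic = if (modality == "rna") "tae_log2" else
                          "taa_log2")
  calls <- call_xci(total_allelic(xf, target_chrom), spec, pseudocount)
  if (!is.null(groups)) calls$group <- unname(groups[calls$cell_id])
  structure(list(modality = modality, fpr = fpr, threshold = spec,
                 null_ratios = null_ratios, calls = calls,
                 n_cells_in = n_in, n_cells_kept = nrow(calls)),
            class = "skew_fit")
}

#' @export
print.skew_fit <- function(x, ...) {
  cat("Allelic-skew XCI classifier (", x$modality, ")\n", sep = "")
  cat(sprintf("  cells: %d in, %d callable after filters\n",
              x$n_cells_in, x$n_cells_kept))
  print(x$threshold)
  sil <- x$calls$xci_status %in% c("hap1_silenced", "hap2_silenced")
  cat(sprintf("  calls: %d / %d cells with a silenced chrX (%.1f%%)\n",
              sum(sil), nrow(x$calls),
              if (nrow(x$calls)) 100 * mean(sil) else NA))
  invisible(x)
}

#' Per-cell X:A expression ratio
#'
#' The ratio of mean UMIs over qualifying chrX genes to mean UMIs over
#' qualifying autosomal genes, on allele-summed counts; qualifying genes are
#' expressed in at least `min_cells` cells. Two-active-X female cells show
#' roughly twice the male ratio.
#'
#' @param x an `allelic_counts` object.
#' @param min_cells qualifying-gene floor (default 10).
#' @param x_chrom chrX name (default `"chrX"`).
#' @return data.frame: `cell_id`, `xa_ratio` (`NA` where the autosomal mean
#'   is zero).
#' @export
xa_ratio <- function(x, min_cells = 10, x_chrom = "chrX") {
  stopifnot(inherits(x, "allelic_counts"))
  tot <- x$hap1 + x$hap2
  qual <- rowSums(tot > 0) >= min_cells
  on_x <- x$features$chrom == x_chrom
  mean_x <- colMeans(tot[qual & on_x, , drop = FALSE])
  mean_a <- colMeans(tot[qual & !on_x, , drop = FALSE])
  data.frame(cell_id = x$cells$cell_id,
             xa_ratio = ifelse(mean_a > 0, mean_x / mean_a, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint silencing / bipartite-structure time course table
#'
#' Aligns per-cell calls from several modalities (RNA and ATAC skew calls,
#' Hi-C bipartite calls) on shared groups (time points) and tabulates the
#' percentage of callable cells positive in each — the table used to read
#' off the lag of the Xi structural change behind silencing.
#'
#' @param calls named list of data.frames, each with a grouping column and a
#'   logical `called` column (`NA` = not callable). For convenience,
#'   `xci_fit` and `skew_fit` objects are accepted and converted.
#' @param group grouping column name (default `"group"`).
#' @return data.frame with one row per group and, per modality `m`, columns
#'   `n_<m>` (callable cells) and `pct_<m>` (% called). Groups missing from
#'   a modality get `NA`; empty groups are omitted with a warning.
#' @export
silencing_timecourse <- function(calls, group = "group") {
  as_call_df <- function(obj) {
    if (inherits(obj, "xci_fit")) obj <- obj$calls
    if (inherits(obj, "skew_fit")) obj <- obj$calls
    if (!is.null(obj$is_bipartite) && is.null(obj$called))
      obj$called <- obj$is_bipartite
    if (!is.null(obj$xci_status) && is.null(obj$called))
      obj$called <- ifelse(obj$xci_status == "no_call", NA,
                           obj$xci_status %in%
                             c("hap1_silenced", "hap2_silenced"))
    if (is.null(obj$called)) abort("cannot find calls in input")
    obj
  }
  calls <- lapply(calls, as_call_df)
  if (is.null(names(calls)) || any(names(calls) == ""))
    abort("'calls' must be a named list (one name per modality)")
  all_groups <- sort(unique(unlist(lapply(calls, function(d) d[[group]]))))
  out <- data.frame(group = all_groups, stringsAsFactors = FALSE)
  for (m in names(calls)) {
    d <- calls[[m]]
    d <- d[!is.na(d$called), , drop = FALSE]
    n <- tapply(d$called, factor(d[[group]], levels = all_groups), length)
    pct <- tapply(d$called, factor(d[[group]], levels = all_groups),
                  function(v) 100 * mean(v))
    if (any(is.na(n)))
      warning("modality '", m, "': no callable cells in group(s) ",
              paste(all_groups[is.na(n)], collapse = ", "))
    out[[paste0("n_", m)]] <- as.integer(n)
    out[[paste0("pct_", m)]] <- as.numeric(pct)
  }
  out
}
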