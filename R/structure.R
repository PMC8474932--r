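#' Long-range and mid-range CDP distance ranges
#'
#' The bipartite inactive X is depleted of mid-range (85 kb - 1.1 Mb) and
#' enriched in very long-range (6.5 - 87 Mb) intrachromosomal contacts. Both
#' range endpoints coincide with CDP fine-bin edges (85 kb = 2^16.375,
#' 1.1 Mb ~ 2^20, 6.5 Mb ~ 2^22.625, 87 Mb ~ 2^26.375), so a fine bin either
#' lies fully inside a range or fully outside it.
#'
#' @param mid numeric length-2: mid-range `[lo, hi)` in bp.
#' @param long numeric length-2: long-range `[lo, hi)` in bp.
#' @return object of class `lmd_ranges`.
#' @export
lmd_ranges <- function(mid = c(2^16.375, 2^20), long = c(2^22.625, 2^26.375)) {
  stopifnot(mid[1] < mid[2], long[1] < long[2], mid[2] <= long[1])
  structure(list(mid = mid, long = long), class = "lmd_ranges")
}

# 1-based fine-bin indices fully inside [lo, hi)
bins_in_range <- function(lo, hi, scheme = cdp_bin_edges()) {
  which(scheme$edges[seq_len(scheme$n_bins)] >= lo * (1 - 1e-9) &
          scheme$edges[seq_len(scheme$n_bins) + 1L] <= hi * (1 + 1e-9))
}

#' Long-range to mid-range difference (LMD)
#'
#' For a normalized 143-bin CDP, the sum of the fine bins fully inside the
#' long range minus the sum of those fully inside the mid range. Computed on
#' proportion profiles so the statistic is coverage-invariant.
#'
#' @param profile numeric length-143 normalized CDP (or a matrix of such
#'   profiles in rows).
#' @param ranges an [lmd_ranges()] object.
#' @param scheme a [cdp_bin_edges()] scheme.
#' @return LMD value(s); `NA` for all-zero (zero-coverage) profiles.
#' @export
lmd <- function(profile, ranges = lmd_ranges(), scheme = cdp_bin_edges()) {
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = 1)
  stopifnot(ncol(profile) == scheme$n_bins)
  mid_bins <- bins_in_range(ranges$mid[1], ranges$mid[2], scheme)
  long_bins <- bins_in_range(ranges$long[1], ranges$long[2], scheme)
  out <- rowSums(profile[, long_bins, drop = FALSE]) -
    rowSums(profile[, mid_bins, drop = FALSE])
  out[rowSums(profile) == 0] <- NA_real_
  if (length(out) == 1) out[[1]] else out
}

#' Spearman correlation between two rebinned allelic CDPs
#'
#' Rank correlation with average ranks for ties. Constant vectors give `NA`.
#'
#' @param a,b numeric vectors of equal length (14-bin rebinned CDPs).
#' @return correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
cdp_spearman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Per-cell allelic structure statistics for one chromosome
#'
#' For every cell with both allelic profiles of `chrom` in `x`, computes the
#' per-allele LMDs, their signed difference `delta_lmd = lmd_hap1 - lmd_hap2`,
#' and the Spearman correlation `rho` between the 14-bin rebinned allelic
#' CDPs.
#'
#' @param x a normalized `cdp_set` from [cdp_profiles()] +
#'   [normalize_cdp()]; must contain both alleles of `chrom`.
#' @param chrom chromosome name.
#' @param ranges an [lmd_ranges()] object.
#' @return data.frame: `cell_id`, `rho`, `lmd_hap1`, `lmd_hap2`, `delta_lmd`.
#' @export
xci_stats <- function(x, chrom, ranges = lmd_ranges()) {
  stopifnot(inherits(x, "cdp_set"))
  if (!x$normalized) x <- normalize_cdp(x)
  sel1 <- x$info$chrom == chrom & x$info$allele == "hap1"
  sel2 <- x$info$chrom == chrom & x$info$allele == "hap2"
  cells <- intersect(x$info$cell_id[sel1], x$info$cell_id[sel2])
  p1 <- x$counts[sel1, , drop = FALSE][match(cells, x$info$cell_id[sel1]), ,
                                       drop = FALSE]
  p2 <- x$counts[sel2, , drop = FALSE][match(cells, x$info$cell_id[sel2]), ,
                                       drop = FALSE]
  groups <- rebin_groups(ncol(p1))
  coarse <- function(m) vapply(groups,
                               function(g) rowSums(m[, g, drop = FALSE]),
                               numeric(nrow(m)))
  r1 <- coarse(p1); r2 <- coarse(p2)
  if (length(cells) == 1) { r1 <- matrix(r1, 1); r2 <- matrix(r2, 1) }
  l1 <- lmd(p1, ranges); l2 <- lmd(p2, ranges)
  rho <- vapply(seq_along(cells),
                function(i) cdp_spearman(r1[i, ], r2[i, ]), numeric(1))
  data.frame(cell_id = cells, rho = rho,
             lmd_hap1 = l1, lmd_hap2 = l2, delta_lmd = l1 - l2,
             stringsAsFactors = FALSE)
}

#' Empirical false-positive-rate threshold from a null distribution
#'
#' Threshold chosen so that at most `fpr` of the null statistics would be
#' called positive, by the nearest-rank empirical quantile: for
#' absolute-value statistics (`direction = "abs"`, e.g. |delta-LMD|,
#' |TAE log2 ratio|) the `(1 - fpr)` quantile with a strict `>` call rule;
#' for the Spearman-CDP statistic (`direction = "lower"`) the `fpr` quantile
#' with a strict `<` call rule. The null is taken from chr1, where homologs
#' are structurally and transcriptionally equivalent.
#'
#' @param null_stats numeric vector of null statistics (non-empty; pass
#'   absolute values for `direction = "abs"`).
#' @param fpr nominal false-positive rate in (0, 1), default 0.10.
#' @param direction `"abs"` (call if statistic above threshold) or `"lower"`
#'   (call if below).
#' @param statistic label, e.g. `"delta_lmd"`, `"spearman_cdp"`,
#'   `"tae_log2"`, `"taa_log2"`.
#' @return object of class `threshold_spec`: list with `statistic`,
#'   `threshold`, `fpr`, `direction`, `n_null`.
#' @export
fpr_threshold <- function(null_stats, fpr = 0.10,
                          direction = c("abs", "lower"),
                          statistic = "delta_lmd") {
  direction <- match.arg(direction)
  null_stats <- null_stats[!is.na(null_stats)]
  if (!length(null_stats)) abort("empty null distribution")
  if (fpr <= 0 || fpr >= 1) abort("fpr must lie in (0, 1)")
  thr <- if (direction == "abs")
    nearest_rank_quantile(null_stats, 1 - fpr)
  else nearest_rank_quantile(null_stats, fpr)
  structure(list(statistic = statistic, threshold = thr, fpr = fpr,
                 direction = direction, n_null = length(null_stats)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec: %s %s %.4g (FPR %.0f%%, null n = %d)\n",
              x$statistic, if (x$direction == "abs") ">" else "<",
              x$threshold, 100 * x$fpr, x$n_null))
  invisible(x)
}

# strict-inequality call rule shared by all thresholded statistics
threshold_call <- function(stat, spec) {
  if (spec$direction == "abs") abs(stat) > spec$threshold
  else stat < spec$threshold
}

#' Call bipartite-Xi cells from structure statistics
#'
#' In LMD mode a cell is called bipartite iff `|delta_lmd|` strictly exceeds
#' the threshold, and the homolog with the higher LMD is assigned as the Xi.
#' In Spearman mode a cell is called iff `rho` is strictly below the
#' threshold (the Xi homolog is not identified by this statistic alone).
#' Cells with missing statistics get no call (`is_bipartite = NA`).
#'
#' @param stats data.frame from [xci_stats()].
#' @param spec a [fpr_threshold()] `threshold_spec` (direction `"abs"` for
#'   LMD mode, `"lower"` for Spearman mode).
#' @param mode `"lmd"` or `"spearman"`.
#' @return `stats` with `is_bipartite` (logical) and `xi_allele`
#'   (`"hap1"`/`"hap2"`/`"none"`) columns added.
#' @export
call_bipartite <- function(stats, spec, mode = c("lmd", "spearman")) {
  mode <- match.arg(mode)
  stat <- if (mode == "lmd") stats$delta_lmd else stats$rho
  called <- threshold_call(stat, spec)
  xi <- rep("none", nrow(stats))
  if (mode == "lmd") {
    xi[which(called)] <- ifelse(stats$delta_lmd[which(called)] > 0,
                                "hap1", "hap2")
  }
  xi[is.na(called)] <- "none"
  stats$is_bipartite <- called
  stats$xi_allele <- xi
  stats
}

#' Fit the bipartite-Xi classifier
#'
#' The central estimator: per-cell allelic structure statistics are computed
#' on a null chromosome (chr1, where the two homologs are equivalent) and on
#' chrX; the classification threshold is fitted as the empirical quantile of
#' the null statistic at the requested false-positive rate; chrX cells whose
#' statistic exceeds it (strictly) are called as carrying a bipartite Xi, and
#' in LMD mode the homolog with the higher LMD is assigned as the Xi.
#'
#' Cells must first pass per-allele coverage on both chromosomes
#' ([coverage_select()]); cells failing coverage are "no call" and are never
#' counted in call proportions.
#'
#' @param cdp a `cdp_set` from [cdp_profiles()] covering both alleles of
#'   `null_chrom` and `target_chrom` (raw counts; normalized internally).
#' @param mode `"lmd"` (default) or `"spearman"`.
#' @param fpr nominal false-positive rate (default 0.10).
#' @param null_chrom chromosome providing the null (default `"chr1"`).
#' @param target_chrom chromosome being called (default `"chrX"`).
#' @param min_contacts per-(chromosome, allele) coverage floor (default 50;
#'   use 100 for Patski-like depth).
#' @param groups optional named character vector (names = cell ids) of group
#'   labels (time point / line) carried into `summary()`.
#' @param ranges an [lmd_ranges()] object.
#' @return object of class `xci_fit`: list with `mode`, `fpr`, `threshold`
#'   (a `threshold_spec`), `null_stats`, `target_stats`, `calls` (the target
#'   stats with `is_bipartite`, `xi_allele` and optional `group`),
#'   `cells_pass`, `n_cells_in`, `min_contacts`, chromosome names.
#' @seealso [predict.xci_fit()], [summary.xci_fit()], [classifier_roc()]
#' @export
xci_classifier <- function(cdp, mode = c("lmd", "spearman"), fpr = 0.10,
                           null_chrom = "chr1", target_chrom = "chrX",
                           min_contacts = 50, groups = NULL,
                           ranges = lmd_ranges()) {
  mode <- match.arg(mode)
  stopifnot(inherits(cdp, "cdp_set"))
  n_cells_in <- length(unique(cdp$info$cell_id))
  pass <- coverage_select(cdp, min_contacts,
                          chroms = c(null_chrom, target_chrom))
  norm <- normalize_cdp(cdp)
  null_stats <- xci_stats(norm, null_chrom, ranges)
  target_stats <- xci_stats(norm, target_chrom, ranges)
  null_stats <- null_stats[null_stats$cell_id %in% pass, , drop = FALSE]
  target_stats <- target_stats[target_stats$cell_id %in% pass, , drop = FALSE]
  null_vec <- if (mode == "lmd") abs(null_stats$delta_lmd) else null_stats$rho
  spec <- fpr_threshold(null_vec, fpr = fpr,
                        direction = if (mode == "lmd") "abs" else "lower",
                        statistic = if (mode == "lmd") "delta_lmd" else
                          "spearman_cdp")
  calls <- call_bipartite(target_stats, spec, mode)
  if (!is.null(groups)) calls$group <- unname(groups[calls$cell_id])
  structure(list(mode = mode, fpr = fpr, threshold = spec,
                 null_stats = null_stats, target_stats = target_stats,
                 calls = calls, cells_pass = pass, n_cells_in = n_cells_in,
                 min_contacts = min_contacts, null_chrom = null_chrom,
                 target_chrom = target_chrom, ranges = ranges),
            class = "xci_fit")
}

#' @export
print.xci_fit <- function(x, ...) {
  cat("Bipartite-Xi classifier (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  null: %s, target: %s; coverage >= %d contacts/allele\n",
              x$null_chrom, x$target_chrom, x$min_contacts))
  cat(sprintf("  cells: %d in, %d passing coverage\n",
              x$n_cells_in, length(x$cells_pass)))
  print(x$threshold)
  n_called <- sum(x$calls$is_bipartite, na.rm = TRUE)
  n_call <- sum(!is.na(x$calls$is_bipartite))
  cat(sprintf("  calls: %d / %d cells bipartite (%.1f%%)\n", n_called,
              n_call, if (n_call) 100 * n_called / n_call else NA))
  invisible(x)
}

#' @export
coef.xci_fit <- function(object, ...) {
  c(threshold = object$threshold$threshold)
}

#' Summarize bipartite-Xi calls, optionally per group
#'
#' @param object an `xci_fit`.
#' @param ... unused.
#' @return object of class `summary.xci_fit` wrapping the per-group
#'   proportion table from [proportion_bipartite()].
#' @export
summary.xci_fit <- function(object, ...) {
  calls <- object$calls
  if (is.null(calls$group)) calls$group <- "all"
  tab <- proportion_bipartite(calls, group = "group")
  structure(list(fit = object, proportions = tab),
            class = "summary.xci_fit")
}

#' @export
print.summary.xci_fit <- function(x, ...) {
  print(x$fit)
  cat("\nProportion of cells with a bipartite X, by group:\n")
  print(x$proportions, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Apply a fitted bipartite-Xi classifier to new cells
#'
#' Recomputes the target-chromosome statistics on `newdata` (after the same
#' coverage gate) and applies the fitted threshold; the threshold itself is
#' not re-estimated.
#'
#' @param object an `xci_fit`.
#' @param newdata a `cdp_set` covering both alleles of the fit's null and
#'   target chromosomes.
#' @param ... unused.
#' @return data.frame of calls as in `object$calls`.
#' @export
predict.xci_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cdp_set"))
  pass <- coverage_select(newdata, object$min_contacts,
                          chroms = c(object$null_chrom, object$target_chrom))
  stats <- xci_stats(normalize_cdp(newdata), object$target_chrom,
                     object$ranges)
  stats <- stats[stats$cell_id %in% pass, , drop = FALSE]
  call_bipartite(stats, object$threshold, object$mode)
}

#' Plot the null and target statistic distributions of a fit
#'
#' Histogram of the null-chromosome statistic with the fitted threshold and
#' the target-chromosome statistic overlaid — the standard display for a
#' null-calibrated call threshold.
#'
#' @param x an `xci_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.xci_fit <- function(x, ...) {
  if (x$mode == "lmd") {
    nv <- abs(x$null_stats$delta_lmd); tv <- abs(x$calls$delta_lmd)
    lab <- "|delta LMD|"
  } else {
    nv <- x$null_stats$rho; tv <- x$calls$rho
    lab <- "Spearman rho (rebinned allelic CDPs)"
  }
  brk <- pretty(c(nv, tv), n = 40)
  hn <- graphics::hist(nv, breaks = brk, plot = FALSE)
  ht <- graphics::hist(tv[!is.na(tv)], breaks = brk, plot = FALSE)
  graphics::plot(hn, col = grDevices::grey(0.8, 0.7), border = NA,
                 xlab = lab, main = "Null (grey) vs target (red) statistic",
                 ylim = c(0, max(hn$counts, ht$counts)), ...)
  graphics::plot(ht, col = grDevices::rgb(1, 0, 0, 0.4), border = NA,
                 add = TRUE)
  graphics::abline(v = x$threshold$threshold, lty = 2)
  invisible(x)
}

#' ROC curve of a thresholded statistic against an autosomal null
#'
#' Sweeps all thresholds of the statistic; at each threshold `t` the
#' true-positive rate is the fraction of chrX cells with statistic `> t`
#' (strictly) and the false-positive rate is the same fraction on the chr1
#' null. AUC by trapezoid over the step curve.
#'
#' @param x_stats numeric vector of target-chromosome statistics (e.g.
#'   |delta-LMD| on chrX).
#' @param null_stats numeric vector of null statistics (same statistic on
#'   chr1).
#' @return object of class `roc_curve`: list with `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
classifier_roc <- function(x_stats, null_stats) {
  x_stats <- x_stats[!is.na(x_stats)]
  null_stats <- null_stats[!is.na(null_stats)]
  if (!length(x_stats) || !length(null_stats))
    abort("both statistic vectors must be non-empty")
  thr <- c(Inf, sort(unique(c(x_stats, null_stats)), decreasing = TRUE),
           -Inf)
  tpr <- vapply(thr, function(t) mean(x_stats > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(null_stats > t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d thresholds)\n", x$auc,
              nrow(x$curve)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s", xlab = "FPR",
                 ylab = "TPR",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Mann-Whitney AUC of scores for a binary label, average ranks for ties
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Time-point AUC of an aligned embedding
#'
#' Evaluates how well points sharing a time-point label co-locate in a latent
#' space. For each anchor point, all other points are scored by (negated)
#' Euclidean distance — closer ranks higher — with binary labels marking
#' membership in the anchor's time point; the resulting AUC is averaged over
#' anchors within each time point, and the per-time-point means are averaged.
#'
#' @param embedding numeric matrix, points in rows.
#' @param labels vector of time-point labels, one per row.
#' @return list with `mean_auc`, `per_label` (named vector of per-time-point
#'   mean AUCs) and `n_used`. Labels with fewer than 2 points are excluded
#'   with a warning.
#' @export
embedding_timepoint_auc <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  stopifnot(nrow(embedding) == length(labels))
  sizes <- table(labels)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("excluding label(s) with a single point: ",
            paste(singletons, collapse = ", "))
    keep <- !(labels %in% singletons)
    embedding <- embedding[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2)
    abort("need at least 2 labels with >= 2 points each")
  d <- as.matrix(stats::dist(embedding))
  n <- nrow(d)
  anchor_auc <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    rank_auc(-d[i, others], labels[others] == labels[i])
  }, numeric(1))
  per_label <- tapply(anchor_auc, labels, mean, na.rm = TRUE)
  list(mean_auc = mean(per_label), per_label = c(per_label), n_used = n)
}

#' Proportion of cells with a bipartite X, per group
#'
#' Per group: 100 x called / callable, with the per-allele breakdown (which
#' homolog was assigned as the Xi). Cells with no call (`is_bipartite = NA`,
#' i.e. failing coverage or with undefined statistics) are excluded from the
#' denominator.
#'
#' @param calls data.frame with `is_bipartite`, `xi_allele` and a grouping
#'   column.
#' @param group name of the grouping column (default `"group"`).
#' @return data.frame: `group`, `n_callable`, `n_bipartite`, `pct_bipartite`,
#'   `pct_xi_hap1`, `pct_xi_hap2`.
#' @export
proportion_bipartite <- function(calls, group = "group") {
  if (!group %in% names(calls)) abort("no grouping column '", group, "'")
  calls <- calls[!is.na(calls$is_bipartite), , drop = FALSE]
  if (!nrow(calls)) {
    warning("no callable cells in any group")
    return(data.frame(group = character(), n_callable = integer(),
                      n_bipartite = integer(), pct_bipartite = numeric(),
                      pct_xi_hap1 = numeric(), pct_xi_hap2 = numeric()))
  }
  gs <- split(calls, calls[[group]])
  out <- do.call(rbind, lapply(names(gs), function(g) {
    d <- gs[[g]]
    data.frame(group = g, n_callable = nrow(d),
               n_bipartite = sum(d$is_bipartite),
               pct_bipartite = 100 * mean(d$is_bipartite),
               pct_xi_hap1 = 100 * mean(d$xi_allele == "hap1"),
               pct_xi_hap2 = 100 * mean(d$xi_allele == "hap2"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
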