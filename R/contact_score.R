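#' Raw V-shaped contact score along a contact-map diagonal
#'
#' For each central bin `c` of a square intrachromosomal matrix, the mean
#' interaction count over the V-shaped region of cells `(i, j)` with
#' `i <= c <= j` and `j - i` at most `arm / resolution` bins — i.e. all
#' contacts spanning the central bin out to the arm length. A pseudocount is
#' added to every bin before averaging; truncated windows at the chromosome
#' ends divide by the actual number of cells included.
#'
#' @param matrix a `binned_matrix` from [bin_contacts()], or a square numeric
#'   matrix of counts (upper+lower symmetric or upper-triangular; only the
#'   `i <= j` triangle is read).
#' @param arm arm length of the V in bp (default 20 Mb).
#' @param resolution bin size in bp; taken from a `binned_matrix`
#'   automatically.
#' @param pseudocount added to every bin (default 1).
#' @return numeric vector of raw scores, one per bin.
#' @export
raw_contact_score <- function(matrix, arm = 20e6, resolution = NULL,
                              pseudocount = 1) {
  if (inherits(matrix, "binned_matrix")) {
    resolution <- matrix$resolution
    m <- as.matrix(matrix, symmetric = TRUE)
  } else {
    m <- matrix
    stopifnot(is.matrix(m), nrow(m) == ncol(m))
    if (is.null(resolution)) abort("resolution required for a plain matrix")
  }
  if (arm < resolution) abort("arm must be at least one bin (resolution)")
  n <- nrow(m)
  w <- as.integer(floor(arm / resolution))
  score <- numeric(n)
  for (c_bin in seq_len(n)) {
    total <- 0; cells <- 0L
    i_lo <- max(1L, c_bin - w)
    for (i in i_lo:c_bin) {
      j_hi <- min(n, i + w)
      js <- c_bin:j_hi
      total <- total + sum(m[i, js])
      cells <- cells + length(js)
    }
    score[c_bin] <- total / cells + pseudocount
  }
  score
}

#' Normalize and smooth a raw contact-score track
#'
#' Scores are normalized as `log2(score / chromosomal mean)` (mean over
#' valid, non-edge bins) and smoothed with a Savitzky-Golay filter (window 5,
#' polynomial degree 2). Bins within the first and last 10 Mb of the
#' chromosome are excluded to avoid edge effects; originally-missing bins are
#' spline-interpolated before smoothing and restored to `NA` afterwards.
#'
#' @param raw numeric vector of raw scores from [raw_contact_score()].
#' @param chrom_length chromosome length in bp.
#' @param resolution bin size in bp.
#' @param edge_exclusion excluded margin at each chromosome end (default
#'   10 Mb).
#' @param window Savitzky-Golay window length (odd, default 5).
#' @param polyorder Savitzky-Golay polynomial degree (default 2).
#' @param missing optional logical vector flagging originally-missing bins.
#' @param chrom,allele optional labels carried on the track.
#' @return object of class `contact_score_track`: list with `chrom`,
#'   `allele`, `resolution`, `chrom_length`, `raw_score`, `smoothed_log2`
#'   (`NA` at invalid bins), `valid` mask, `edge_excluded` mask.
#' @export
normalize_smooth_score <- function(raw, chrom_length, resolution,
                                   edge_exclusion = 10e6, window = 5,
                                   polyorder = 2, missing = NULL,
                                   chrom = NA_character_,
                                   allele = "non-allelic") {
  n <- length(raw)
  if (is.null(missing)) missing <- rep(FALSE, n)
  stopifnot(length(missing) == n)
  starts <- (seq_len(n) - 1) * resolution
  ends <- pmin(starts + resolution, chrom_length)
  edge <- starts < edge_exclusion | ends > chrom_length - edge_exclusion
  valid <- !edge & !missing
  log2v <- rep(NA_real_, n)
  if (any(valid)) {
    chrom_mean <- mean(raw[valid])
    inner <- which(!edge)
    v <- log2(raw[inner] / chrom_mean)
    miss_inner <- missing[inner]
    if (any(miss_inner) && sum(!miss_inner) >= 2) {
      anchors <- which(!miss_inner)
      v[miss_inner] <- if (length(anchors) >= 4) {
        stats::spline(anchors, v[anchors], xout = which(miss_inner),
                      method = "natural")$y
      } else {
        stats::approx(anchors, v[anchors], xout = which(miss_inner),
                      rule = 2)$y
      }
    }
    if (sum(is.finite(v)) >= window && length(v) >= window) {
      v <- signal::sgolayfilt(v, p = polyorder, n = window)
    } else {
      warning("fewer than ", window, " valid bins; smoothing skipped")
    }
    v[miss_inner] <- NA_real_
    log2v[inner] <- v
  }
  structure(list(chrom = chrom, allele = allele, resolution = resolution,
                 chrom_length = chrom_length, raw_score = raw,
                 smoothed_log2 = log2v, valid = valid,
                 edge_excluded = edge),
            class = "contact_score_track")
}

#' Contact-score track from a binned allelic contact map
#'
#' Convenience wrapper: [raw_contact_score()] then
#' [normalize_smooth_score()]. Originally-missing bins are those with no
#' contact touching them (zero row/column sum) when
#' `flag_empty_bins = TRUE`.
#'
#' @param matrix a `binned_matrix`.
#' @param genome a [chrom_sizes()] table (for the chromosome length).
#' @param arm V arm length in bp (default 20 Mb).
#' @param pseudocount added to every bin (default 1).
#' @param flag_empty_bins treat bins with no incident contacts as missing.
#' @param ... passed to [normalize_smooth_score()].
#' @return a `contact_score_track`.
#' @export
contact_score <- function(matrix, genome, arm = 20e6, pseudocount = 1,
                          flag_empty_bins = TRUE, ...) {
  stopifnot(inherits(matrix, "binned_matrix"))
  raw <- raw_contact_score(matrix, arm = arm, pseudocount = pseudocount)
  dense <- as.matrix(matrix, symmetric = TRUE)
  missing <- if (flag_empty_bins) rowSums(dense) == 0 else NULL
  normalize_smooth_score(raw, chrom_length = chrom_length(genome, matrix$chrom),
                         resolution = matrix$resolution, missing = missing,
                         chrom = matrix$chrom, allele = matrix$allele, ...)
}

#' @export
print.contact_score_track <- function(x, ...) {
  cat("contact_score_track:", x$chrom, "@",
      format(x$resolution, big.mark = ","), "bp;",
      sum(x$valid), "valid /", length(x$raw_score), "bins\n")
  invisible(x)
}

#' @export
plot.contact_score_track <- function(x, ...) {
  pos <- ((seq_along(x$raw_score)) - 0.5) * x$resolution / 1e6
  graphics::plot(pos, x$smoothed_log2, type = "l", xlab = "position (Mb)",
                 ylab = "smoothed log2(score / mean)",
                 main = paste("Contact score:", x$chrom, x$allele), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Locate the contact-score dip nearest a locus
#'
#' Finds the local minimum of the smoothed track within a window around the
#' locus — e.g. the dip at the *Dxz4* hinge separating the two Xi
#' superdomains — and its depth relative to the flanking local maxima.
#'
#' @param track a `contact_score_track`.
#' @param locus bp position of interest.
#' @param window search half-width in bp (default 10 Mb).
#' @return list with `bin` (1-based index of the dip, `NA` if no local
#'   minimum exists in the window), `position` (bp midpoint), `depth`
#'   (smaller flanking local-max height minus dip value).
#' @export
locate_dip <- function(track, locus, window = 10e6) {
  stopifnot(inherits(track, "contact_score_track"))
  locus_bin <- floor(locus / track$resolution) + 1L
  if (locus_bin < 1 || locus_bin > length(track$raw_score) ||
      track$edge_excluded[locus_bin])
    abort("locus lies inside the excluded chromosome edge")
  v <- track$smoothed_log2
  n <- length(v)
  is_min <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (any(is.na(v[(i - 1):(i + 1)]))) next
    if (v[i] <= v[i - 1] && v[i] <= v[i + 1] &&
        (v[i] < v[i - 1] || v[i] < v[i + 1])) is_min[i] <- TRUE
  }
  half_bins <- ceiling(window / track$resolution)
  in_win <- which(is_min & abs(seq_len(n) - locus_bin) <= half_bins)
  if (!length(in_win))
    return(list(bin = NA_integer_, position = NA_real_, depth = NA_real_))
  bin <- in_win[which.min(abs(in_win - locus_bin))]
  left <- v[seq_len(bin - 1)]
  right <- v[seq(bin + 1, n)]
  local_max <- function(seg) {
    seg <- seg[!is.na(seg)]
    if (!length(seg)) return(NA_real_)
    max(seg)
  }
  depth <- min(local_max(left), local_max(right), na.rm = TRUE) - v[bin]
  list(bin = bin, position = (bin - 0.5) * track$resolution, depth = depth)
}

#' Write a contact-score track as bedGraph
#'
#' Four columns: chrom, start, end, smoothed log2 score; invalid/missing
#' bins are omitted.
#'
#' @param track a `contact_score_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_score <- function(track, path) {
  ok <- !is.na(track$smoothed_log2)
  starts <- (which(ok) - 1) * track$resolution
  df <- data.frame(chrom = track$chrom, start = format(starts, scientific = FALSE, trim = TRUE),
                   end = format(pmin(starts + track$resolution,
                                     track$chrom_length), scientific = FALSE, trim = TRUE),
                   score = track$smoothed_log2[ok])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
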