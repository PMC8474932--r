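#' Per-cell allelically tagged contact table
#'
#' A `contact_table` holds single-cell chromatin contact records together with
#' the genome table they were validated against. Each record is one contact
#' pair with a cell barcode, two genomic positions (0-based) and a per-pair
#' haplotype tag.
#'
#' @param cell_id character vector of cell barcodes.
#' @param chrom_a,chrom_b chromosome names of the two contact ends.
#' @param pos_a,pos_b 0-based base-pair positions (>= 0).
#' @param allele per-pair haplotype tag: `"hap1"`, `"hap2"` or `"ambiguous"`.
#'   Records tagged `conflict` by [segregate_allele()] are discarded upstream
#'   and never stored in a table.
#' @param genome a [chrom_sizes()] table; all chromosome names must be present.
#' @return object of class `contact_table`: a data.frame of records with the
#'   genome table in attribute `"genome"`.
#' @export
contact_table <- function(cell_id, chrom_a, pos_a, chrom_b, pos_b,
                          allele = "ambiguous", genome) {
  stopifnot(inherits(genome, "chrom_sizes"))
  df <- data.frame(cell_id = as.character(cell_id),
                   chrom_a = as.character(chrom_a),
                   pos_a = as.numeric(pos_a),
                   chrom_b = as.character(chrom_b),
                   pos_b = as.numeric(pos_b),
                   allele = as.character(allele),
                   stringsAsFactors = FALSE)
  validate_contact_records(df, genome)
  structure(df, genome = genome, class = c("contact_table", "data.frame"))
}

validate_contact_records <- function(df, genome, line_offset = 0L) {
  bad_chrom <- !(df$chrom_a %in% genome$name) | !(df$chrom_b %in% genome$name)
  if (any(bad_chrom)) {
    offenders <- unique(c(df$chrom_a[!(df$chrom_a %in% genome$name)],
                          df$chrom_b[!(df$chrom_b %in% genome$name)]))
    abort("unknown chromosome(s) not in genome table: ",
          paste(offenders, collapse = ", "),
          " (line ", which(bad_chrom)[1] + line_offset, ")")
  }
  bad_pos <- !is.finite(df$pos_a) | !is.finite(df$pos_b) |
    df$pos_a < 0 | df$pos_b < 0
  if (any(bad_pos)) {
    abort("negative or non-numeric position at line(s): ",
          paste(utils::head(which(bad_pos) + line_offset, 10), collapse = ", "))
  }
  bad_allele <- !(df$allele %in% c("hap1", "hap2", "ambiguous"))
  if (any(bad_allele)) {
    abort("invalid allele tag at line(s): ",
          paste(utils::head(which(bad_allele) + line_offset, 10),
                collapse = ", "))
  }
  invisible(df)
}

#' @export
print.contact_table <- function(x, ...) {
  g <- attr(x, "genome")
  cat("contact_table:", nrow(x), "records,",
      length(unique(x$cell_id)), "cells,",
      nrow(g), "chromosomes\n")
  cat("allele tags:", paste(sprintf("%s=%d", names(table(x$allele)),
                                    table(x$allele)), collapse = " "), "\n")
  invisible(x)
}

#' Read single-cell contact pairs from a pairs-like TSV
#'
#' The dialect is tab-separated with `#`-prefixed header lines. Column names
#' are taken from a `#columns:` header line (whitespace-separated names after
#' the tag); if absent, the first non-`#` line is read as a plain header row.
#' Required columns: `cell_id`, `chrom_a`, `pos_a`, `chrom_b`, `pos_b`;
#' an `allele` column is optional (missing values default to `"ambiguous"`).
#' Extra columns (e.g. `readid`) are ignored. Malformed records are reported
#' with their line numbers; unknown chromosomes are a hard error naming the
#' offender.
#'
#' @param path path to the pairs-like file.
#' @param genome a [chrom_sizes()] table.
#' @return a [contact_table()].
#' @export
read_contacts <- function(path, genome) {
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  ncomment <- if (all(is_header)) length(lines) else which(!is_header)[1] - 1L
  header_lines <- lines[seq_len(ncomment)]
  body <- lines[setdiff(seq_along(lines), seq_len(ncomment))]
  cols_line <- grep("^#columns:", header_lines, value = TRUE)
  if (length(cols_line)) {
    col_names <- strsplit(trimws(sub("^#columns:", "", cols_line[length(cols_line)])),
                          "[ \t]+")[[1]]
    data_lines <- body
    first_data_line <- ncomment + 1L
  } else {
    if (!length(body)) abort("no header line naming columns found in ", path)
    col_names <- strsplit(body[1], "\t")[[1]]
    data_lines <- body[-1]
    first_data_line <- ncomment + 2L
  }
  required <- c("cell_id", "chrom_a", "pos_a", "chrom_b", "pos_b")
  missing_cols <- setdiff(required, col_names)
  if (length(missing_cols))
    abort("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!length(data_lines)) {
    return(contact_table(character(), character(), numeric(),
                         character(), numeric(), character(), genome))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(col_names))) {
    abort("wrong field count at line(s): ",
          paste(utils::head(which(nf != length(col_names)) +
                              first_data_line - 1L, 10), collapse = ", "))
  }
  mat <- matrix(unlist(parts), ncol = length(col_names), byrow = TRUE)
  colnames(mat) <- col_names
  allele <- if ("allele" %in% col_names) mat[, "allele"] else
    rep("ambiguous", nrow(mat))
  allele[is.na(allele) | allele == "" | allele == "."] <- "ambiguous"
  df <- data.frame(cell_id = mat[, "cell_id"],
                   chrom_a = mat[, "chrom_a"],
                   pos_a = suppressWarnings(as.numeric(mat[, "pos_a"])),
                   chrom_b = mat[, "chrom_b"],
                   pos_b = suppressWarnings(as.numeric(mat[, "pos_b"])),
                   allele = allele, stringsAsFactors = FALSE)
  validate_contact_records(df, genome, line_offset = first_data_line - 1L)
  structure(df, genome = genome, class = c("contact_table", "data.frame"))
}

#' Write a contact table in the pairs-like TSV dialect
#'
#' Round-trips exactly through [read_contacts()]: record order is preserved.
#'
#' @param table a [contact_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(table, path) {
  stopifnot(inherits(table, "contact_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs-like contact table", con)
  writeLines("#columns: cell_id chrom_a pos_a chrom_b pos_b allele", con)
  if (nrow(table)) {
    utils::write.table(
      data.frame(table$cell_id, table$chrom_a, format(table$pos_a, scientific = FALSE, trim = TRUE),
                 table$chrom_b, format(table$pos_b, scientific = FALSE, trim = TRUE), table$allele),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Segregate a read pair to its parental haplotype
#'
#' A pair is assigned to a haplotype if either end carries at least one SNP
#' particular to one parental strain and no SNP of the other strain. Pairs
#' with no SNP evidence on either end are `"ambiguous"` (retained for
#' non-allelic analysis only); pairs with evidence for both haplotypes are
#' `"conflict"` and are discarded from both allelic and non-allelic analyses.
#'
#' @param hap1_a,hap2_a counts of hap1/hap2-diagnostic SNP hits on end a.
#' @param hap1_b,hap2_b same for end b.
#' @return one of `"hap1"`, `"hap2"`, `"ambiguous"`, `"conflict"`
#'   (vectorized).
#' @export
segregate_allele <- function(hap1_a, hap2_a, hap1_b = 0, hap2_b = 0) {
  ev <- cbind(hap1_a, hap2_a, hap1_b, hap2_b)
  if (any(!is.finite(ev)) || any(ev < 0))
    abort("SNP evidence counts must be non-negative")
  h1 <- ev[, 1] + ev[, 3]
  h2 <- ev[, 2] + ev[, 4]
  out <- rep("ambiguous", length(h1))
  out[h1 > 0 & h2 == 0] <- "hap1"
  out[h2 > 0 & h1 == 0] <- "hap2"
  out[h1 > 0 & h2 > 0] <- "conflict"
  out
}

#' Per-cell sci-Hi-C quality-control filter
#'
#' A cell passes if it has at least `min_pairs` uniquely mapped contact
#' pairs, a cis:trans ratio of at least `min_cis_trans` (a cell with zero
#' trans contacts and positive cis contacts passes the ratio test), and a
#' species purity (fraction of reads mapping to the majority species in the
#' barnyard mix) of at least `min_purity`.
#'
#' @param qc data.frame with columns `cell_id`, `n_valid_pairs`, `cis_count`,
#'   `trans_count`, `species_purity`.
#' @param min_pairs minimum valid pairs (default 1000).
#' @param min_cis_trans minimum cis:trans ratio (default 1).
#' @param min_purity minimum species purity (default 0.95).
#' @return the `qc` data.frame with a logical `pass` column added.
#' @export
filter_cells_qc <- function(qc, min_pairs = 1000, min_cis_trans = 1.0,
                            min_purity = 0.95) {
  needed <- c("cell_id", "n_valid_pairs", "cis_count", "trans_count",
              "species_purity")
  missing_cols <- setdiff(needed, names(qc))
  if (length(missing_cols))
    abort("qc table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(qc$species_purity < 0 | qc$species_purity > 1, na.rm = TRUE))
    abort("species_purity must lie in [0, 1]")
  ratio <- ifelse(qc$trans_count == 0,
                  ifelse(qc$cis_count > 0, Inf, NaN),
                  qc$cis_count / qc$trans_count)
  qc$pass <- qc$n_valid_pairs >= min_pairs &
    !is.nan(ratio) & ratio >= min_cis_trans &
    qc$species_purity >= min_purity
  qc$pass[is.na(qc$pass)] <- FALSE
  qc
}

#' Keep informative contacts
#'
#' Informative contacts are interchromosomal contacts plus intrachromosomal
#' contacts spanning more than 1 kb. The operation is idempotent.
#'
#' @param table a [contact_table()].
#' @param min_distance intrachromosomal distance cutoff in bp (default 1000;
#'   strictly greater-than).
#' @return filtered [contact_table()].
#' @export
informative_contacts <- function(table, min_distance = 1000) {
  stopifnot(inherits(table, "contact_table"))
  keep <- table$chrom_a != table$chrom_b |
    abs(table$pos_a - table$pos_b) > min_distance
  out <- table[keep, , drop = FALSE]
  structure(as.data.frame(out), genome = attr(table, "genome"),
            class = c("contact_table", "data.frame"))
}

#' Bin intrachromosomal contacts into a sparse upper-triangular matrix
#'
#' Counts are summed within fixed-size genomic bins; entries are stored as
#' triplets with `i <= j` (symmetric semantics). The sum of entries always
#' equals the number of selected records, and summing the matrices of two
#' disjoint cell sets equals the matrix of their union (pseudobulk).
#'
#' @param table a [contact_table()].
#' @param chrom chromosome to bin (intrachromosomal records only).
#' @param resolution bin size in bp (> 0), e.g. `500000`.
#' @param cells optional character vector restricting to a cell set.
#' @param allele optional allele filter: subset of
#'   `c("hap1","hap2","ambiguous")`; `NULL` (default) keeps all records
#'   (non-allelic).
#' @return object of class `binned_matrix`: list with `chrom`, `resolution`,
#'   `n_bins`, `allele`, `n_cells`, and a `counts` data.frame (`i`, `j`,
#'   `count`; 0-based bin indices, `i <= j`).
#' @export
bin_contacts <- function(table, chrom, resolution, cells = NULL,
                         allele = NULL) {
  stopifnot(inherits(table, "contact_table"))
  if (!is.numeric(resolution) || resolution <= 0)
    abort("resolution must be > 0")
  genome <- attr(table, "genome")
  if (!chrom %in% genome$name) abort("unknown chromosome: ", chrom)
  n_bins <- as.integer(ceiling(chrom_length(genome, chrom) / resolution))
  keep <- table$chrom_a == chrom & table$chrom_b == chrom
  if (!is.null(cells)) keep <- keep & table$cell_id %in% cells
  if (!is.null(allele)) keep <- keep & table$allele %in% allele
  sub <- table[keep, , drop = FALSE]
  if (!nrow(sub)) {
    counts <- data.frame(i = integer(), j = integer(), count = numeric())
  } else {
    bi <- floor(sub$pos_a / resolution)
    bj <- floor(sub$pos_b / resolution)
    i <- pmin(bi, bj)
    j <- pmax(bi, bj)
    key <- i * n_bins + j
    agg <- table(key)
    keyv <- as.numeric(names(agg))
    counts <- data.frame(i = as.integer(keyv %/% n_bins),
                         j = as.integer(keyv %% n_bins),
                         count = as.numeric(agg))
    counts <- counts[order(counts$i, counts$j), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(chrom = chrom, resolution = resolution, n_bins = n_bins,
                 allele = if (is.null(allele)) "non-allelic" else
                   paste(allele, collapse = "+"),
                 n_cells = if (is.null(cells))
                   length(unique(sub$cell_id)) else length(unique(cells)),
                 counts = counts),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("binned_matrix:", x$chrom, "@", format(x$resolution, big.mark = ","),
      "bp,", x$n_bins, "bins,", sum(x$counts$count), "contacts (",
      x$allele, ")\n")
  invisible(x)
}

#' Densify a binned matrix
#'
#' @param x a `binned_matrix`.
#' @param symmetric fill both triangles (default `TRUE`).
#' @param ... unused.
#' @return a square numeric matrix.
#' @export
as.matrix.binned_matrix <- function(x, symmetric = TRUE, ...) {
  m <- matrix(0, x$n_bins, x$n_bins)
  if (nrow(x$counts)) {
    m[cbind(x$counts$i + 1L, x$counts$j + 1L)] <- x$counts$count
    if (symmetric) {
      lower <- x$counts$i != x$counts$j
      m[cbind(x$counts$j[lower] + 1L, x$counts$i[lower] + 1L)] <-
        x$counts$count[lower]
    }
  }
  m
}

#' Write a binned matrix as triplet text
#'
#' Tab-separated `bin_i`, `bin_j`, `count` (0-based, `i <= j`), with a
#' `#`-prefixed header describing chromosome and resolution.
#'
#' @param x a `binned_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("## binned_matrix chrom=%s resolution=%d allele=%s",
                     x$chrom, as.integer(x$resolution), x$allele), con)
  writeLines("#columns: bin_i bin_j count", con)
  if (nrow(x$counts))
    utils::write.table(x$counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
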