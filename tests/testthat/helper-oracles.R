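# independent oracles and tiny fixtures used across test files

# linear scan over bin edges: bin k iff edges[k] <= d < edges[k+1]
scan_bin_oracle <- function(d, edges) {
  n_bins <- length(edges) - 1L
  vapply(d, function(x) {
    for (k in seq_len(n_bins)) {
      if (x >= edges[k] && x < edges[k + 1]) return(k)
    }
    NA_integer_
  }, integer(1))
}

# brute-force V-window enumeration: mean over all (i, j) with i <= c <= j
# and j - i <= w, pseudocount added to every cell
brute_v_score <- function(m, w, pseudocount = 1) {
  n <- nrow(m)
  vapply(seq_len(n), function(c_bin) {
    vals <- c()
    for (i in seq_len(n)) for (j in i:n) {
      if (i <= c_bin && c_bin <= j && (j - i) <= w)
        vals <- c(vals, m[i, j] + pseudocount)
    }
    mean(vals)
  }, numeric(1))
}

# rank-then-Pearson Spearman oracle (average ranks)
spearman_oracle <- function(a, b) {
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"), method = "pearson")
}

mouse_genome <- function() chrom_sizes(c("chr1", "chrX"), c(195e6, 171e6))

# contact table from a compact record data.frame
make_table <- function(df, genome = mouse_genome()) {
  contact_table(df$cell_id, df$chrom_a, df$pos_a, df$chrom_b, df$pos_b,
                if (is.null(df$allele)) "ambiguous" else df$allele, genome)
}

# single-cell intrachromosomal records at given distances from position 0
distance_records <- function(distances, cell = "c1", chrom = "chr1",
                             allele = "hap1") {
  data.frame(cell_id = cell, chrom_a = chrom, pos_a = 0,
             chrom_b = chrom, pos_b = distances, allele = allele,
             stringsAsFactors = FALSE)
}
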