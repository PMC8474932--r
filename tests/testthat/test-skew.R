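# tiny deterministic count fixture: 6 genes (3 chr1, 3 chrX) x 4 cells
fixture_counts <- function() {
  features <- data.frame(feature = paste0("g", 1:6),
                         chrom = rep(c("chr1", "chrX"), each = 3))
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      time_point = c("d0", "d0", "d7", "d7"))
  hap1 <- matrix(10, 6, 4)
  hap2 <- matrix(10, 6, 4)
  allelic_counts(hap1, hap2, features, cells)
}

test_that("feature and cell filters apply the 10-cell / 10-UMI rules", {
  set.seed(16)
  n_cells <- 30
  features <- data.frame(feature = paste0("g", 1:4),
                         chrom = c("chr1", "chr1", "chrX", "chrX"))
  cells <- data.frame(cell_id = paste0("c", seq_len(n_cells)))
  hap1 <- matrix(10, 4, n_cells)
  hap2 <- matrix(10, 4, n_cells)
  hap1[2, ] <- 0; hap1[2, 1:9] <- 1       # gene 2: hap1 in 9 cells only
  hap2[2, ] <- 0                          # ...and nothing on hap2
  x <- allelic_counts(hap1, hap2, features, cells)
  f <- feature_cell_filters(x)
  expect_false("g2" %in% f$features$feature)   # 9 < 10 cells
  expect_true(all(paste0("g", c(1, 3, 4)) %in% f$features$feature))

  # a cell with chrX hap2 total 9 is dropped under the per-allele rule
  hap2[3:4, 1] <- c(4, 5)                # chrX hap2 total = 9 for cell 1
  hap1[2, ] <- 10; hap2[2, ] <- 10       # make gene 2 pass
  x2 <- allelic_counts(hap1, hap2, features, cells)
  f2 <- feature_cell_filters(x2, allele_rule = "per_allele")
  expect_false("c1" %in% f2$cells$cell_id)
  # ...but kept under the combined rule (20 + 9 >= 10)
  f3 <- feature_cell_filters(x2, allele_rule = "combined")
  expect_true("c1" %in% f3$cells$cell_id)
  # idempotence under the same rule
  f4 <- feature_cell_filters(f3, allele_rule = "combined")
  expect_equal(dim(f4$hap1), dim(f3$hap1))
})

test_that("allelic log2 ratios use the documented pseudocount", {
  expect_equal(allelic_log2_ratio(50, 50), 0)
  expect_equal(allelic_log2_ratio(80, 20), log2(81 / 21))
  expect_equal(allelic_log2_ratio(0, 40), log2(1 / 41))
  expect_equal(allelic_log2_ratio(10, 20), -allelic_log2_ratio(20, 10))
  expect_error(allelic_log2_ratio(-1, 5), "non-negative")
})

test_that("XCI calls follow the skew sign convention with strict threshold", {
  spec <- fpr_threshold(rep(1.2, 10), fpr = 0.10, direction = "abs",
                        statistic = "tae_log2")
  totals <- data.frame(cell_id = c("bi", "left", "edge"),
                       total_hap1 = c(50, 3, 100),
                       total_hap2 = c(50, 40, 100 * 2^1.2 + 0.2))
  out <- call_xci(totals, spec)
  expect_equal(out$xci_status[1], "biallelic")
  expect_equal(out$xci_status[2], "hap1_silenced")   # skewed left
  expect_equal(out$xa_allele[2], "hap2")
  # ratio -3 with threshold 1.2 -> hap1 silenced
  r <- allelic_log2_ratio(out$total_hap1[2], out$total_hap2[2])
  expect_lt(r, -1.2)
  # antisymmetry: swapping alleles swaps the silenced call
  swapped <- totals
  names(swapped)[2:3] <- c("total_hap2", "total_hap1")
  out2 <- call_xci(swapped, spec)
  expect_equal(out2$log2_ratio, -out$log2_ratio)
  expect_equal(out2$xci_status[2], "hap2_silenced")
})

test_that("a ratio exactly at the threshold stays biallelic", {
  spec <- fpr_threshold(rep(2, 5), direction = "abs")
  totals <- data.frame(cell_id = "t", total_hap1 = 4 * 10 - 1,
                       total_hap2 = 10 - 1)   # ratio = log2(4) = 2
  out <- call_xci(totals, spec)
  expect_equal(out$log2_ratio, 2)
  expect_equal(out$xci_status, "biallelic")
})

test_that("X:A ratios track dosage linearly", {
  x <- fixture_counts()
  xa <- xa_ratio(x, min_cells = 2)
  expect_equal(xa$xa_ratio, rep(1, 4))       # identical per-gene means
  x2 <- x
  x2$hap1[x$features$chrom == "chrX", ] <-
    x$hap1[x$features$chrom == "chrX", ] / 2
  x2$hap2[x$features$chrom == "chrX", ] <-
    x$hap2[x$features$chrom == "chrX", ] / 2
  expect_equal(xa_ratio(x2, min_cells = 2)$xa_ratio, rep(0.5, 4))
})

test_that("simulated two-active-X females show ~2x the male X:A ratio", {
  f <- simulate_allelic_counts(count_sim_spec(sex = "female"), 150,
                               silencing_fraction = 0, seed = 17)
  m <- simulate_allelic_counts(count_sim_spec(sex = "male"), 150,
                               silencing_fraction = 0, seed = 18)
  rf <- mean(xa_ratio(f$counts)$xa_ratio, na.rm = TRUE)
  rm_ <- mean(xa_ratio(m$counts)$xa_ratio, na.rm = TRUE)
  expect_equal(rf / rm_, 2, tolerance = 0.15)
})

test_that("chr1-derived skew threshold calibrates on an independent biallelic chromosome", {
  spec <- count_sim_spec(n_genes = c(chr1 = 200, chr7 = 200, chrX = 200))
  sim <- simulate_allelic_counts(spec, 600, silencing_fraction = 0,
                                 seed = 19)
  x <- sim$counts
  null_tot <- total_allelic(x, "chr1")
  thr <- fpr_threshold(abs(allelic_log2_ratio(null_tot$total_hap1,
                                              null_tot$total_hap2)),
                       fpr = 0.10, direction = "abs")
  other <- total_allelic(x, "chr7")
  fp <- mean(abs(allelic_log2_ratio(other$total_hap1,
                                    other$total_hap2)) > thr$threshold)
  ci <- stats::binom.test(round(fp * 600), 600, 0.10)$conf.int
  expect_true(0.10 >= ci[1] && 0.10 <= ci[2])
})

test_that("the joint time course aligns modalities and shows a structural lag", {
  rna <- data.frame(group = rep(c("d0", "d3", "d7"), each = 10),
                    xci_status = c(rep("biallelic", 10),
                                   rep(c("hap1_silenced", "biallelic"),
                                       c(6, 4)),
                                   rep(c("hap2_silenced", "no_call"),
                                       c(9, 1))))
  hic <- data.frame(group = rep(c("d0", "d3", "d7"), each = 10),
                    is_bipartite = c(rep(FALSE, 10),
                                     rep(c(TRUE, FALSE), c(2, 8)),
                                     rep(c(TRUE, NA), c(7, 3))))
  tab <- silencing_timecourse(list(rna = rna, hic = hic))
  expect_equal(tab$pct_rna, c(0, 60, 100))   # 9/9 callable at d7
  expect_equal(tab$n_rna, c(10, 10, 9))
  expect_equal(tab$pct_hic, c(0, 20, 100))
  expect_equal(tab$n_hic, c(10, 10, 7))
  # intermediate time point: structure lags expression
  expect_lt(tab$pct_hic[2], tab$pct_rna[2])
})
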