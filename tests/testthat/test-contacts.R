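test_that("pairs-like files round-trip exactly, including an empty table", {
  g <- mouse_genome()
  tab <- make_table(data.frame(
    cell_id = c("a", "a", "b"),
    chrom_a = c("chr1", "chrX", "chr1"), pos_a = c(100, 5000, 2e6),
    chrom_b = c("chr1", "chrX", "chrX"), pos_b = c(600000, 9000, 3e6),
    allele = c("hap1", "hap2", "ambiguous")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(tab, path)
  back <- read_contacts(path, g)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # empty file with a valid header
  writeLines("#columns: cell_id chrom_a pos_a chrom_b pos_b allele", path)
  empty <- read_contacts(path, g)
  expect_s3_class(empty, "contact_table")
  expect_equal(nrow(empty), 0)

  # plain-header dialect, no allele column -> ambiguous
  writeLines(c("cell_id\tchrom_a\tpos_a\tchrom_b\tpos_b",
               "a\tchr1\t10\tchr1\t5000"), path)
  plain <- read_contacts(path, g)
  expect_equal(plain$allele, "ambiguous")
})

test_that("malformed input is rejected with located errors", {
  g <- mouse_genome()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#columns: cell_id chrom_a pos_a chrom_b pos_b",
               "a\tchr1\t10\tchr1\t500",
               "a\tchr1\t-5\tchr1\t500"), path)
  expect_error(read_contacts(path, g), "line.*3")
  writeLines(c("#columns: cell_id chrom_a pos_a chrom_b pos_b",
               "a\tchr9\t10\tchr9\t500"), path)
  expect_error(read_contacts(path, g), "chr9")
  writeLines(c("#columns: cell_id chrom_a pos_a", "a\tchr1\t10"), path)
  expect_error(read_contacts(path, g), "missing required column")
})

test_that("allelic segregation follows the SNP-evidence rule", {
  expect_equal(segregate_allele(2, 0, 0, 0), "hap1")
  expect_equal(segregate_allele(0, 0, 0, 3), "hap2")
  expect_equal(segregate_allele(0, 0, 0, 0), "ambiguous")
  expect_equal(segregate_allele(1, 0, 0, 1), "conflict")
  # vectorized
  expect_equal(segregate_allele(c(1, 0), c(0, 0), c(0, 0), c(0, 2)),
               c("hap1", "hap2"))
  expect_error(segregate_allele(-1, 0), "non-negative")
})

test_that("cell QC applies the pair-count, cis:trans and purity gates", {
  qc <- data.frame(
    cell_id = c("under", "ratio1", "impure", "notrans", "allcis0"),
    n_valid_pairs = c(999, 1000, 5000, 2000, 1000),
    cis_count = c(600, 500, 4000, 2000, 0),
    trans_count = c(399, 500, 1000, 0, 1000),
    species_purity = c(0.99, 0.96, 0.94, 0.99, 0.99))
  out <- filter_cells_qc(qc)
  expect_equal(out$pass,
               c(FALSE,  # 999 < 1000 pairs
                 TRUE,   # ratio exactly 1 passes
                 FALSE,  # purity 0.94 < 0.95
                 TRUE,   # trans = 0 treated as infinite ratio
                 FALSE)) # all-trans fails the ratio
  expect_equal(nrow(filter_cells_qc(qc[0, ])), 0)
})

test_that("informative-contact filter keeps inter and >1 kb intra, idempotently", {
  tab <- make_table(data.frame(
    cell_id = "c", chrom_a = c("chr1", "chr1", "chr1"),
    pos_a = c(0, 0, 100),
    chrom_b = c("chr1", "chr1", "chrX"),
    pos_b = c(999, 1500, 50)))
  out <- informative_contacts(tab)
  expect_equal(nrow(out), 2)         # 999 bp dropped, 1500 bp + inter kept
  expect_true(all(out$pos_b %in% c(1500, 50)))
  expect_equal(as.data.frame(informative_contacts(out)),
               as.data.frame(out))   # idempotent
  # boundary: exactly 1000 bp is not informative (strict >)
  tab2 <- make_table(distance_records(1000))
  expect_equal(nrow(informative_contacts(tab2)), 0)
})

test_that("binning conserves counts and is additive over disjoint cell sets", {
  g <- mouse_genome()
  tab <- make_table(data.frame(
    cell_id = "c", chrom_a = "chr1", pos_a = 100,
    chrom_b = "chr1", pos_b = 600000))
  bm <- bin_contacts(tab, "chr1", 500e3)
  expect_equal(bm$counts, data.frame(i = 0L, j = 1L, count = 1))

  dup <- make_table(rbind(as.data.frame(tab), as.data.frame(tab)))
  expect_equal(bin_contacts(dup, "chr1", 500e3)$counts$count, 2)

  # 10-record fixture: aggregate equals elementwise sum of two cell sets
  set.seed(4)
  recs <- data.frame(cell_id = rep(c("a", "b"), each = 5),
                     chrom_a = "chr1",
                     pos_a = floor(runif(10) * 5e6),
                     chrom_b = "chr1",
                     pos_b = floor(runif(10) * 5e6))
  tab10 <- make_table(recs)
  m_all <- as.matrix(bin_contacts(tab10, "chr1", 1e6, cells = c("a", "b")),
                     symmetric = FALSE)
  m_a <- as.matrix(bin_contacts(tab10, "chr1", 1e6, cells = "a"),
                   symmetric = FALSE)
  m_b <- as.matrix(bin_contacts(tab10, "chr1", 1e6, cells = "b"),
                   symmetric = FALSE)
  expect_equal(m_all, m_a + m_b)
  expect_equal(sum(m_all), 10)   # conservation

  empty <- bin_contacts(tab10, "chr1", 1e6, cells = character())
  expect_equal(nrow(empty$counts), 0)
  expect_equal(empty$n_bins, ceiling(195e6 / 1e6))
})

test_that("allelic tags partition retained records", {
  ev <- data.frame(h1a = c(2, 0, 0, 1, 0), h2a = c(0, 0, 1, 1, 0),
                   h1b = c(0, 0, 0, 0, 0), h2b = c(0, 3, 0, 0, 0))
  tags <- segregate_allele(ev$h1a, ev$h2a, ev$h1b, ev$h2b)
  retained <- tags[tags != "conflict"]
  expect_equal(sum(retained == "hap1") + sum(retained == "hap2") +
                 sum(retained == "ambiguous"), length(retained))
  expect_equal(sum(tags == "conflict"), 1)
})
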