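test_that("generation is reproducible given the seed", {
  spec <- contact_sim_spec(n_min = 100, n_max = 400)
  a <- simulate_population(spec, 10, bipartite_fraction = 0.5, seed = 30)
  b <- simulate_population(spec, 10, bipartite_fraction = 0.5, seed = 30)
  expect_identical(a, b)
  c1 <- simulate_cell_contacts(spec, seed = 31)
  c2 <- simulate_cell_contacts(spec, seed = 31)
  expect_identical(c1, c2)
  k <- count_sim_spec()
  expect_identical(simulate_allelic_counts(k, 20, 0.5, seed = 32),
                   simulate_allelic_counts(k, 20, 0.5, seed = 32))
})

test_that("population composition follows the deterministic allocation rule", {
  spec <- contact_sim_spec(n_min = 50, n_max = 60, mitotic_fraction = 0.03)
  fr <- c(0.1, 0.3, 0.6, 0.7, 0.8)
  pop <- simulate_population(spec, 100, bipartite_fraction = fr, seed = 33)
  got <- tapply(pop$truth$bipartite, pop$truth$time_point, mean)
  expect_equal(as.numeric(got[paste0("tp", 1:5)]), fr)
  expect_equal(sum(pop$truth$state == "mitotic"), round(0.03 * 500))
  # 3:1 hap1 skew among bipartite cells, per the allocation rule
  bip <- pop$truth[pop$truth$bipartite, ]
  expect_equal(mean(bip$xi_allele == "hap1"), 0.75, tolerance = 0.02)
})

test_that("decay masses are proper distributions and modifications stay in range", {
  spec <- contact_sim_spec()
  for (v in c("null", "mitotic", "bipartite")) {
    mass <- decay_bin_mass(spec, 171e6, v)
    expect_equal(sum(mass), 1, tolerance = 1e-12)
    expect_true(all(mass >= 0))
  }
  m0 <- decay_bin_mass(spec, 171e6, "null")
  mb <- decay_bin_mass(spec, 171e6, "bipartite")
  sch <- cdp_bin_edges()
  mid <- bins_in <- which(sch$edges[1:143] >= spec$ranges$mid[1] - 1 &
                            sch$edges[2:144] <= spec$ranges$mid[2] + 1)
  long <- which(sch$edges[1:143] >= spec$ranges$long[1] - 1 &
                  sch$edges[2:144] <= spec$ranges$long[2] + 1)
  outside <- setdiff(seq_len(143), c(mid, long))
  # outside the named ranges only the normalization constant acts
  ratio <- mb[outside] / m0[outside]
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-12)
  # inside: depletion and boost act on top of that constant
  expect_equal(mean(mb[mid] / m0[mid]) / ratio[1], spec$mid_depletion,
               tolerance = 1e-9)
  expect_equal(mean(mb[long] / m0[long]) / ratio[1], spec$long_boost,
               tolerance = 1e-9)
})

test_that("sampled distances follow the discretized decay law (chi-square GOF)", {
  spec <- contact_sim_spec()
  mass <- decay_bin_mass(spec, 195e6, "null")
  set.seed(34)
  d <- xcistruct:::sample_distances(1e5, mass, spec, 195e6)
  obs <- compute_cdp(d)
  expect_true(all(obs[mass == 0] == 0))   # no mass beyond the chromosome
  keep <- mass * 1e5 >= 5                 # chi-square validity
  pool <- !keep & mass > 0                # pool sparse positive-mass bins
  x_obs <- obs[keep]; p_exp <- mass[keep]
  if (any(pool)) {
    x_obs <- c(x_obs, sum(obs[pool]))
    p_exp <- c(p_exp, sum(mass[pool]))
  }
  p <- suppressWarnings(stats::chisq.test(x_obs, p = p_exp,
                                          rescale.p = TRUE)$p.value)
  expect_gt(p, 0.01)
})

test_that("null cells are symmetric and bipartite cells shift LMD as designed", {
  spec <- contact_sim_spec(n_min = 300, n_max = 1000, mitotic_fraction = 0)
  null_pop <- simulate_population(spec, 200, bipartite_fraction = 0,
                                  seed = 35)
  cdp <- normalize_cdp(cdp_profiles(informative_contacts(null_pop$contacts)))
  st <- xci_stats(cdp, "chrX")
  expect_equal(mean(st$delta_lmd), 0, tolerance = 0.01)
  bip_pop <- simulate_population(spec, 200, bipartite_fraction = 1,
                                 seed = 36)
  cdp_b <- normalize_cdp(cdp_profiles(informative_contacts(bip_pop$contacts)))
  st_b <- xci_stats(cdp_b, "chrX")
  signed <- ifelse(bip_pop$truth$xi_allele[
    match(st_b$cell_id, bip_pop$truth$cell_id)] == "hap1",
    st_b$delta_lmd, -st_b$delta_lmd)
  expect_gt(mean(signed), 0.2)        # E[LMD(xi)] > E[LMD(xa)]
})

test_that("allelic count truth matches construction in degenerate limits", {
  # male cells never express hap2 chrX
  male <- simulate_allelic_counts(count_sim_spec(sex = "male"), 30, 0,
                                  seed = 37)
  on_x <- male$counts$features$chrom == "chrX"
  expect_true(all(male$counts$hap2[on_x, ] == 0))
  expect_true(any(male$counts$hap1[on_x, ] > 0))
  # completeness 0 + full silencing -> every Xi total is exactly 0
  k0 <- count_sim_spec(completeness = 0)
  sim <- simulate_allelic_counts(k0, 40, silencing_fraction = 1, seed = 38)
  tot <- total_allelic(sim$counts, "chrX")
  xi <- sim$truth$xi_allele[match(tot$cell_id, sim$truth$cell_id)]
  xi_total <- ifelse(xi == "hap1", tot$total_hap1, tot$total_hap2)
  expect_true(all(xi_total == 0))
  spec <- fpr_threshold(rep(0.5, 20), direction = "abs")
  calls <- call_xci(tot, spec)
  expect_true(all(calls$xci_status %in% c("hap1_silenced",
                                          "hap2_silenced")))
})

test_that("without silencing, chrX and chr1 ratio distributions are indistinguishable", {
  sim <- simulate_allelic_counts(count_sim_spec(), 500,
                                 silencing_fraction = 0, seed = 39)
  r1 <- with(total_allelic(sim$counts, "chr1"),
             allelic_log2_ratio(total_hap1, total_hap2))
  rx <- with(total_allelic(sim$counts, "chrX"),
             allelic_log2_ratio(total_hap1, total_hap2))
  p <- suppressWarnings(stats::ks.test(r1, rx)$p.value)
  expect_gt(p, 0.01)
})

test_that("trans contacts appear only when requested, for QC testing", {
  spec0 <- contact_sim_spec(n_min = 100, n_max = 200)
  pop0 <- simulate_population(spec0, 5, 0, seed = 40)
  expect_true(all(pop0$contacts$chrom_a == pop0$contacts$chrom_b))
  spec_t <- contact_sim_spec(n_min = 100, n_max = 200,
                             trans_fraction = 0.2)
  pop_t <- simulate_population(spec_t, 5, 0, seed = 40)
  frac <- mean(pop_t$contacts$chrom_a != pop_t$contacts$chrom_b)
  expect_equal(frac, 0.2, tolerance = 0.02)
})
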