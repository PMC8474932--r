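sch <- cdp_bin_edges()
rng <- lmd_ranges()
mid_bins <- which(sch$edges[1:143] >= rng$mid[1] - 1e-6 &
                    sch$edges[2:144] <= rng$mid[2] + 1e-6)
long_bins <- which(sch$edges[1:143] >= rng$long[1] - 1e-6 &
                     sch$edges[2:144] <= rng$long[2] + 1e-6)

test_that("LMD is the long-range minus mid-range proportion difference", {
  p <- rep(0, 143)
  p[long_bins[1]] <- 1
  expect_equal(lmd(p), 1)                  # all mass long-range
  p <- rep(0, 143); p[mid_bins[1]] <- 1
  expect_equal(lmd(p), -1)                 # all mass mid-range
  # 0.6 long, 0.3 mid, 0.1 elsewhere -> 0.3
  p <- rep(0, 143)
  p[long_bins] <- 0.6 / length(long_bins)
  p[mid_bins] <- 0.3 / length(mid_bins)
  p[1] <- 0.1
  expect_equal(lmd(p), 0.3, tolerance = 1e-12)
  expect_true(is.na(lmd(rep(0, 143))))     # zero coverage undefined
})

test_that("delta-LMD is antisymmetric under allele swap", {
  set.seed(5)
  tab <- make_table(rbind(
    distance_records(round(10^runif(300, 3.2, 7.9)), "c", "chrX", "hap1"),
    distance_records(round(10^runif(300, 5.0, 7.9)), "c", "chrX", "hap2")))
  st <- xci_stats(normalize_cdp(cdp_profiles(tab, chroms = "chrX")), "chrX")
  expect_equal(st$delta_lmd, st$lmd_hap1 - st$lmd_hap2)
  swapped <- tab
  swapped$allele <- ifelse(tab$allele == "hap1", "hap2", "hap1")
  st2 <- xci_stats(normalize_cdp(cdp_profiles(swapped, chroms = "chrX")),
                   "chrX")
  expect_equal(st2$delta_lmd, -st$delta_lmd)
  expect_equal(st2$rho, st$rho)
  # identical allelic profiles -> exactly 0
  same <- make_table(rbind(
    distance_records(c(2000, 5e4, 2e6), "c", "chrX", "hap1"),
    distance_records(c(2000, 5e4, 2e6), "c", "chrX", "hap2")))
  st3 <- xci_stats(normalize_cdp(cdp_profiles(same, chroms = "chrX")),
                   "chrX")
  expect_equal(st3$delta_lmd, 0)
})

test_that("CDP Spearman correlation matches a rank-then-Pearson oracle", {
  a <- 1:14
  expect_equal(cdp_spearman(a, a), 1)
  expect_equal(cdp_spearman(a, rev(a)), -1)
  b <- c(1:13, 0)
  expect_equal(cdp_spearman(a, b), spearman_oracle(a, b))
  set.seed(6)
  for (i in 1:20) {
    x <- rpois(14, 4); y <- rpois(14, 4)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(cdp_spearman(x, y), spearman_oracle(x, y))
  }
  expect_true(is.na(cdp_spearman(rep(1, 14), a)))
})

test_that("FPR thresholds are nearest-rank quantiles with strict calls", {
  spec <- fpr_threshold(1:10, fpr = 0.10, direction = "abs")
  expect_equal(spec$threshold, 9)
  expect_equal(sum(1:10 > spec$threshold), 1)      # 10% of the null
  spec0 <- fpr_threshold(rep(0, 50), direction = "abs")
  expect_equal(spec0$threshold, 0)
  expect_true(xcistruct:::threshold_call(0.01, spec0))
  specm <- fpr_threshold(1:11, fpr = 0.5, direction = "abs")
  expect_equal(specm$threshold, 6)                 # median of symmetric null
  expect_error(fpr_threshold(numeric()), "empty null")
  # lower-tail direction for the Spearman statistic
  spl <- fpr_threshold(seq(0.1, 1, by = 0.1), fpr = 0.2,
                       direction = "lower", statistic = "spearman_cdp")
  expect_equal(spl$threshold, 0.2)
  expect_true(sum(seq(0.1, 1, 0.1) < spl$threshold) <= 2)
})

test_that("bipartite calls use strict inequality and assign the higher-LMD homolog", {
  st <- data.frame(cell_id = c("eq", "pos", "neg"),
                   rho = c(0.9, 0.1, 0.95),
                   lmd_hap1 = c(0.3, 0.6, 0.0), lmd_hap2 = c(0.1, 0.1, 0.5),
                   delta_lmd = c(0.2, 0.5, -0.5))
  spec <- structure(list(statistic = "delta_lmd", threshold = 0.2,
                         fpr = 0.1, direction = "abs", n_null = 10),
                    class = "threshold_spec")
  out <- call_bipartite(st, spec, mode = "lmd")
  expect_equal(out$is_bipartite, c(FALSE, TRUE, TRUE))  # |0.2| not > 0.2
  expect_equal(out$xi_allele, c("none", "hap1", "hap2"))
  spec_rho <- structure(list(statistic = "spearman_cdp", threshold = 0.5,
                             fpr = 0.1, direction = "lower", n_null = 10),
                        class = "threshold_spec")
  outr <- call_bipartite(st, spec_rho, mode = "spearman")
  expect_equal(outr$is_bipartite, c(FALSE, TRUE, FALSE))
  expect_equal(outr$xi_allele, rep("none", 3))
})

test_that("ROC sweeps reproduce perfect, chance and pROC-checked AUCs", {
  expect_equal(classifier_roc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_equal(classifier_roc(2, 1)$auc, 1)
  set.seed(7)
  same <- classifier_roc(runif(4000), runif(4000))
  expect_equal(same$auc, 0.5, tolerance = 0.03)    # identical distributions
  x <- abs(rnorm(200, 1)); y <- abs(rnorm(300))
  r <- classifier_roc(x, y)
  expect_true(all(r$curve$tpr >= 0 & r$curve$tpr <= 1))
  ref <- suppressMessages(pROC::roc(
    response = c(rep(1, 200), rep(0, 300)), predictor = c(x, y),
    direction = "<"))
  expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-10)
})

test_that("embedding time-point AUC behaves on separated, random and hand-ranked cases", {
  # two collapsed clusters -> 1
  emb <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) +
    matrix(rnorm(20, sd = 1e-3), 10, 2)
  expect_equal(embedding_timepoint_auc(emb, rep(c("a", "b"), each = 5))$mean_auc,
               1)
  # hand-ranked line example: A at 0,1; B at 10,11
  line <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(embedding_timepoint_auc(line, c("A", "A", "B", "B"))$mean_auc,
               1)
  # random labels on one isotropic cloud -> ~0.5
  set.seed(8)
  cloud <- matrix(rnorm(600), ncol = 2)
  ra <- embedding_timepoint_auc(cloud, sample(rep(c("a", "b", "c"), 100)))
  expect_equal(ra$mean_auc, 0.5, tolerance = 0.05)
  # rigid rotation leaves the AUC unchanged
  theta <- 0.7
  rot <- cloud %*% matrix(c(cos(theta), sin(theta),
                            -sin(theta), cos(theta)), 2)
  labs <- rep(c("a", "b", "c"), 100)
  expect_equal(embedding_timepoint_auc(rot, labs)$mean_auc,
               embedding_timepoint_auc(cloud, labs)$mean_auc)
  # singleton labels are excluded with a warning
  expect_warning(embedding_timepoint_auc(rbind(cloud, c(99, 99)),
                                         c(labs, "solo")),
                 "single point")
})

test_that("bipartite proportions are per-group percentages of callable cells", {
  calls <- data.frame(
    cell_id = paste0("c", 1:12),
    is_bipartite = c(rep(TRUE, 8), FALSE, FALSE, NA, NA),
    xi_allele = c(rep("hap1", 6), "hap2", "hap2", rep("none", 4)),
    group = c(rep("d7", 10), "d7", "d0"))
  tab <- proportion_bipartite(calls)
  d7 <- tab[tab$group == "d7", ]
  expect_equal(d7$n_callable, 10)          # the NA cell is excluded
  expect_equal(d7$pct_bipartite, 80)
  expect_equal(d7$pct_xi_hap1, 60)
  expect_equal(d7$pct_xi_hap2, 20)
  expect_false("d0" %in% tab$group)        # only no-call cells in d0
  expect_warning(proportion_bipartite(calls[11:12, ]), "no callable")
})

test_that("relabeling haplotypes flips the call sign but not the call set", {
  spec <- contact_sim_spec(n_min = 300, n_max = 1000)
  pop <- simulate_population(spec, 60, bipartite_fraction = 0.5, seed = 21)
  cdp <- cdp_profiles(informative_contacts(pop$contacts))
  fit <- xci_classifier(cdp)
  swapped <- pop$contacts
  swapped$allele <- ifelse(swapped$allele == "hap1", "hap2",
                           ifelse(swapped$allele == "hap2", "hap1",
                                  swapped$allele))
  fit2 <- xci_classifier(cdp_profiles(informative_contacts(swapped)))
  m <- merge(fit$calls, fit2$calls, by = "cell_id")
  expect_equal(m$delta_lmd.y, -m$delta_lmd.x)
  expect_equal(m$is_bipartite.y, m$is_bipartite.x)
  called <- which(m$is_bipartite.x)
  expect_equal(m$xi_allele.y[called],
               ifelse(m$xi_allele.x[called] == "hap1", "hap2", "hap1"))
})

test_that("Spearman-mode and LMD-mode calls agree beyond chance on strong effects", {
  # a sloped decay (alpha > 1) gives CDPs a rank-informative shape; under
  # alpha = 1 every log bin has equal mass and rank correlations carry no
  # signal, which only the LMD statistic survives
  spec <- contact_sim_spec(n_min = 300, n_max = 1500, alpha = 1.3)
  pop <- simulate_population(spec, 150, bipartite_fraction = 0.5, seed = 22)
  cdp <- cdp_profiles(informative_contacts(pop$contacts))
  fit_l <- xci_classifier(cdp, mode = "lmd")
  fit_s <- xci_classifier(cdp, mode = "spearman")
  m <- merge(fit_l$calls[, c("cell_id", "is_bipartite")],
             fit_s$calls[, c("cell_id", "is_bipartite")], by = "cell_id")
  agreement <- mean(m$is_bipartite.x == m$is_bipartite.y, na.rm = TRUE)
  p_l <- mean(m$is_bipartite.x, na.rm = TRUE)
  p_s <- mean(m$is_bipartite.y, na.rm = TRUE)
  chance <- p_l * p_s + (1 - p_l) * (1 - p_s)
  expect_gt(agreement, chance)
  expect_gt(agreement, 0.75)
})
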