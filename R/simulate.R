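#' Specification for the synthetic contact generator
#'
#' Defines the study-like conditions under which per-cell allelic contact
#' lists are generated: power-law distance decay on each chromosome, a
#' log-uniform per-cell coverage distribution, an optional mitotic band
#' enrichment, and an optional bipartite superdomain modification applied to
#' the designated Xi homolog of chrX (mid-range depletion, within-superdomain
#' long-range boost, hinge boundary at a fraction of the chromosome length
#' mimicking the *Dxz4* position).
#'
#' @param genome a [chrom_sizes()] table; default chr1 = 195 Mb,
#'   chrX = 171 Mb (mouse-like).
#' @param n_min,n_max per-cell, per-allele, per-chromosome contact count
#'   range; counts are drawn log-uniformly (defaults 50 and 5000).
#' @param alpha decay exponent: P(distance d) proportional to d^-alpha on
#'   [1 kb, chromosome length] (default 1).
#' @param mitotic_boost multiplicative mass enrichment of the 2-12 Mb band in
#'   mitotic cells (default 8).
#' @param mitotic_band the band range in bp (default `c(2e6, 12e6)`).
#' @param boundary_frac superdomain hinge position as a fraction of chrX
#'   length (default 0.44).
#' @param mid_depletion multiplier on mid-range (85 kb - 1.1 Mb) mass of the
#'   bipartite homolog (default 0.5).
#' @param long_boost multiplier on long-range (6.5 - 87 Mb) mass of the
#'   bipartite homolog, restricted to within-superdomain pairs (default 4).
#' @param mitotic_fraction fraction of mitotic cells in a population
#'   (default 0.03).
#' @param xi_skew probability that a bipartite cell's Xi is hap1 (default
#'   0.75, a 3:1 skew).
#' @param trans_fraction fraction of interchromosomal contacts per cell
#'   (default 0; available for QC-filter testing).
#' @param ranges an [lmd_ranges()] object naming the mid/long ranges.
#' @return object of class `contact_sim_spec`.
#' @export
contact_sim_spec <- function(genome = chrom_sizes(c("chr1", "chrX"),
                                                  c(195e6, 171e6)),
                             n_min = 50, n_max = 5000, alpha = 1,
                             mitotic_boost = 8,
                             mitotic_band = c(2e6, 12e6),
                             boundary_frac = 0.44, mid_depletion = 0.5,
                             long_boost = 4, mitotic_fraction = 0.03,
                             xi_skew = 0.75, trans_fraction = 0,
                             ranges = lmd_ranges()) {
  stopifnot(inherits(genome, "chrom_sizes"), n_min >= 1, n_max >= n_min,
            mitotic_boost > 0, mid_depletion > 0, long_boost > 0,
            boundary_frac > 0, boundary_frac < 1,
            mitotic_fraction >= 0, mitotic_fraction <= 1,
            xi_skew >= 0, xi_skew <= 1,
            trans_fraction >= 0, trans_fraction < 1)
  structure(list(genome = genome, n_min = n_min, n_max = n_max,
                 alpha = alpha, mitotic_boost = mitotic_boost,
                 mitotic_band = mitotic_band,
                 boundary_frac = boundary_frac,
                 mid_depletion = mid_depletion, long_boost = long_boost,
                 mitotic_fraction = mitotic_fraction, xi_skew = xi_skew,
                 trans_fraction = trans_fraction, ranges = ranges,
                 scheme = cdp_bin_edges()),
            class = "contact_sim_spec")
}

#' Discretized decay-law bin masses
#'
#' Probability mass of each CDP fine bin under the power-law decay truncated
#' to [1 kb, chromosome length], optionally modified for a mitotic cell
#' (band boost) or the bipartite homolog (mid depletion + long boost), then
#' renormalized. Sampling distances on the analysis grid keeps generator
#' effect sizes interpretable in CDP bins.
#'
#' @param spec a [contact_sim_spec()].
#' @param chrom_len chromosome length in bp.
#' @param variant `"null"`, `"mitotic"` or `"bipartite"`.
#' @return numeric vector of length 143 summing to 1.
#' @export
decay_bin_mass <- function(spec, chrom_len,
                           variant = c("null", "mitotic", "bipartite")) {
  variant <- match.arg(variant)
  sch <- spec$scheme
  lo <- pmax(sch$edges[seq_len(sch$n_bins)], 1e3)
  hi <- pmin(sch$edges[seq_len(sch$n_bins) + 1L], chrom_len)
  a <- spec$alpha
  mass <- ifelse(hi > lo,
                 if (abs(a - 1) < 1e-12) log(hi / lo)
                 else (hi^(1 - a) - lo^(1 - a)) / (1 - a),
                 0)
  if (variant == "mitotic") {
    band <- bins_in_range(spec$mitotic_band[1], spec$mitotic_band[2],
                          sch)
    mass[band] <- mass[band] * spec$mitotic_boost
  } else if (variant == "bipartite") {
    mid <- bins_in_range(spec$ranges$mid[1], spec$ranges$mid[2], sch)
    long <- bins_in_range(spec$ranges$long[1], spec$ranges$long[2], sch)
    mass[mid] <- mass[mid] * spec$mid_depletion
    mass[long] <- mass[long] * spec$long_boost
  }
  mass / sum(mass)
}

# sample n distances from the discretized law: bin by mass, then inverse-CDF
# of d^-alpha within the (truncated) bin
sample_distances <- function(n, mass, spec, chrom_len) {
  if (n == 0) return(numeric())
  sch <- spec$scheme
  k <- sample.int(sch$n_bins, n, replace = TRUE, prob = mass)
  lo <- pmax(sch$edges[k], 1e3)
  hi <- pmin(sch$edges[k + 1L], chrom_len)
  u <- stats::runif(n)
  a <- spec$alpha
  d <- if (abs(a - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    (lo^(1 - a) + u * (hi^(1 - a) - lo^(1 - a)))^(1 / (1 - a))
  }
  pmin(floor(d), chrom_len - 1)
}

# place distances on a chromosome; long-range pairs of a bipartite homolog
# are kept within one superdomain where feasible
place_contacts <- function(d, chrom_len, bipartite = FALSE,
                           boundary = NULL, long_range = NULL) {
  n <- length(d)
  pos_a <- numeric(n)
  unconstrained <- rep(TRUE, n)
  if (bipartite && n > 0) {
    is_long <- d >= long_range[1] & d < long_range[2]
    sides <- c(boundary, chrom_len - boundary)
    fit1 <- pmax(sides[1] - d, 0)
    fit2 <- pmax(sides[2] - d, 0)
    can <- is_long & (fit1 + fit2 > 0)
    pick2 <- stats::runif(n) < fit2 / pmax(fit1 + fit2, 1)
    off <- ifelse(pick2, boundary, 0)
    room <- ifelse(pick2, fit2, fit1)
    idx <- which(can)
    pos_a[idx] <- off[idx] + floor(stats::runif(length(idx)) * room[idx])
    unconstrained[idx] <- FALSE
  }
  idx <- which(unconstrained)
  pos_a[idx] <- floor(stats::runif(length(idx)) *
                        pmax(chrom_len - d[idx], 1))
  data.frame(pos_a = pos_a, pos_b = pos_a + d)
}

#' Simulate the allelic contact list of one cell
#'
#' Draws, for each chromosome and allele, a log-uniform contact count and
#' samples contact distances from the (state-modified) decay law; the
#' bipartite modification applies only to the designated Xi homolog of chrX
#' in non-mitotic cells, with its long-range contacts placed within a single
#' superdomain.
#'
#' @param spec a [contact_sim_spec()].
#' @param cell_id barcode for the records.
#' @param state `"interphase"` or `"mitotic"`.
#' @param bipartite does this cell carry a bipartite Xi?
#' @param xi_allele which homolog is the Xi (`"hap1"`/`"hap2"`).
#' @param n_per_allele optional fixed per-(chromosome, allele) contact count
#'   (default: drawn log-uniformly between `n_min` and `n_max`).
#' @param seed optional integer seed (set only if given).
#' @return a [contact_table()] of this cell's records.
#' @export
simulate_cell_contacts <- function(spec, cell_id = "cell_1",
                                   state = c("interphase", "mitotic"),
                                   bipartite = FALSE, xi_allele = "hap1",
                                   n_per_allele = NULL, seed = NULL) {
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  truth <- data.frame(cell_id = cell_id, time_point = "t0", state = state,
                      bipartite = bipartite, xi_allele =
                        if (bipartite) xi_allele else "none",
                      stringsAsFactors = FALSE)
  sim_records(spec, truth, n_per_allele = n_per_allele)
}

# core generator: one vectorized sampling pass per (chromosome, law variant)
sim_records <- function(spec, truth, n_per_allele = NULL) {
  genome <- spec$genome
  xc <- x_chrom(genome)
  out <- vector("list", 2 * nrow(genome))
  li <- 0
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$name[ci]
    L <- genome$length[ci]
    masses <- list(null = decay_bin_mass(spec, L, "null"),
                   mitotic = decay_bin_mass(spec, L, "mitotic"),
                   bipartite = decay_bin_mass(spec, L, "bipartite"))
    for (allele in c("hap1", "hap2")) {
      variant <- ifelse(truth$state == "mitotic", "mitotic",
                        ifelse(chrom == xc & truth$bipartite &
                                 truth$xi_allele == allele,
                               "bipartite", "null"))
      n <- if (is.null(n_per_allele)) {
        round(exp(stats::runif(nrow(truth), log(spec$n_min),
                               log(spec$n_max))))
      } else rep(n_per_allele, nrow(truth))
      recs <- lapply(c("null", "mitotic", "bipartite"), function(v) {
        rows <- which(variant == v)
        if (!length(rows)) return(NULL)
        total <- sum(n[rows])
        d <- sample_distances(total, masses[[v]], spec, L)
        pos <- place_contacts(d, L, bipartite = (v == "bipartite"),
                              boundary = round(spec$boundary_frac * L),
                              long_range = spec$ranges$long)
        data.frame(cell_id = rep(truth$cell_id[rows], n[rows]),
                   chrom_a = chrom, pos_a = pos$pos_a,
                   chrom_b = chrom, pos_b = pos$pos_b,
                   allele = allele, stringsAsFactors = FALSE)
      })
      li <- li + 1
      out[[li]] <- do.call(rbind, recs)
    }
  }
  df <- do.call(rbind, out)
  if (spec$trans_fraction > 0 && nrow(genome) >= 2 && nrow(df) > 0) {
    n_trans <- round(spec$trans_fraction / (1 - spec$trans_fraction) *
                       nrow(df))
    ci <- t(vapply(seq_len(n_trans), function(i)
      sample.int(nrow(genome), 2), integer(2)))
    if (n_trans > 0) {
      df <- rbind(df, data.frame(
        cell_id = sample(truth$cell_id, n_trans, replace = TRUE),
        chrom_a = genome$name[ci[, 1]],
        pos_a = floor(stats::runif(n_trans) * genome$length[ci[, 1]]),
        chrom_b = genome$name[ci[, 2]],
        pos_b = floor(stats::runif(n_trans) * genome$length[ci[, 2]]),
        allele = "ambiguous", stringsAsFactors = FALSE))
    }
  }
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("contact_table", "data.frame"))
}

# deterministic allocation: round(fraction * n) positives, positions shuffled
allocate_binary <- function(n, fraction) {
  k <- round(fraction * n)
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

#' Simulate a ground-truth-labelled cell population
#'
#' Generates per-cell allelic contact lists for a (possibly multi-time-point)
#' population. Per time point, the fraction of bipartite cells is allocated
#' deterministically by rounding (positions randomized under the seed); the
#' Xi homolog of each bipartite cell is hap1 with probability `xi_skew`;
#' `mitotic_fraction` of cells are mitotic (and display no bipartite
#' structure while condensed).
#'
#' @param spec a [contact_sim_spec()].
#' @param n_cells cells per time point.
#' @param bipartite_fraction numeric vector, one fraction per time point.
#' @param time_points labels (default `tp1..tpk`).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return list with `contacts` (a [contact_table()]) and `truth`
#'   (data.frame `cell_id`, `time_point`, `state`, `bipartite`,
#'   `xi_allele`).
#' @export
simulate_population <- function(spec, n_cells, bipartite_fraction = 0,
                                time_points = NULL, seed = 1) {
  set.seed(seed)
  k <- length(bipartite_fraction)
  if (is.null(time_points))
    time_points <- paste0("tp", seq_len(k))
  stopifnot(length(time_points) == k)
  truths <- lapply(seq_len(k), function(i) {
    bip <- allocate_binary(n_cells, bipartite_fraction[i])
    mit <- allocate_binary(n_cells, spec$mitotic_fraction)
    n_bip <- sum(bip)
    xi <- rep("none", n_cells)
    xi[bip] <- ifelse(allocate_binary(n_bip, spec$xi_skew), "hap1", "hap2")
    data.frame(cell_id = sprintf("%s_c%04d", time_points[i],
                                 seq_len(n_cells)),
               time_point = time_points[i],
               state = ifelse(mit, "mitotic", "interphase"),
               bipartite = bip, xi_allele = xi, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truths)
  list(contacts = sim_records(spec, truth), truth = truth)
}

#' Specification for the synthetic allelic UMI count generator
#'
#' @param n_genes named integer vector of features per chromosome (default
#'   `c(chr1 = 200, chrX = 200)`); one name must be `"chrX"`. Equal expected
#'   expressed mass on the null and target chromosomes mirrors the premise
#'   that the chr1 allelic-ratio null transfers to chrX.
#' @param rate_meanlog,rate_sdlog log-normal parameters of per-gene baseline
#'   rates (defaults 0 and 1).
#' @param depth_size,depth_mu negative-binomial parameters of per-cell total
#'   UMI depth over both alleles (defaults size 10, mean 2000).
#' @param completeness residual Xi expression fraction after silencing
#'   (default 0.02: near-complete silencing with escape).
#' @param xi_skew probability the silenced homolog is hap1 (default 0.75).
#' @param sex `"female"` or `"male"` (male cells carry no hap2 chrX).
#' @return object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = c(chr1 = 200, chrX = 200),
                           rate_meanlog = 0, rate_sdlog = 1,
                           depth_size = 10, depth_mu = 2000,
                           completeness = 0.02, xi_skew = 0.75,
                           sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot("chrX" %in% names(n_genes), all(n_genes > 0),
            completeness >= 0, completeness <= 1,
            xi_skew >= 0, xi_skew <= 1)
  structure(list(n_genes = n_genes, rate_meanlog = rate_meanlog,
                 rate_sdlog = rate_sdlog, depth_size = depth_size,
                 depth_mu = depth_mu, completeness = completeness,
                 xi_skew = xi_skew, sex = sex),
            class = "count_sim_spec")
}

#' Simulate allelic UMI count matrices with progressive X silencing
#'
#' Per-gene baseline rates are log-normal and shared across cells; per-cell
#' depth is negative-binomial; counts are Poisson at
#' `depth x rate / 2` per allele. In silenced female cells the Xi-allele
#' chrX gene rates are multiplied by `completeness`; autosomes stay
#' biallelic; male cells have zero hap2 chrX counts throughout.
#'
#' @param spec a [count_sim_spec()].
#' @param n_cells cells per time point.
#' @param silencing_fraction numeric vector, one fraction per time point.
#' @param time_points labels (default `tp1..tpk`).
#' @param seed integer seed.
#' @return list with `counts` (an [allelic_counts()]) and `truth`
#'   (data.frame `cell_id`, `time_point`, `silenced`, `xi_allele`).
#' @export
simulate_allelic_counts <- function(spec, n_cells, silencing_fraction = 0,
                                    time_points = NULL, seed = 1) {
  set.seed(seed)
  k <- length(silencing_fraction)
  if (is.null(time_points)) time_points <- paste0("tp", seq_len(k))
  stopifnot(length(time_points) == k)
  n_total_genes <- sum(spec$n_genes)
  chroms <- rep(names(spec$n_genes), spec$n_genes)
  features <- data.frame(feature = sprintf("f%04d", seq_len(n_total_genes)),
                         chrom = chroms, stringsAsFactors = FALSE)
  rates <- stats::rlnorm(n_total_genes, spec$rate_meanlog, spec$rate_sdlog)
  rates <- rates / sum(rates)
  truths <- lapply(seq_len(k), function(i) {
    sil <- if (spec$sex == "female")
      allocate_binary(n_cells, silencing_fraction[i]) else
        rep(FALSE, n_cells)
    xi <- rep("none", n_cells)
    xi[sil] <- ifelse(allocate_binary(sum(sil), spec$xi_skew),
                      "hap1", "hap2")
    data.frame(cell_id = sprintf("%s_r%04d", time_points[i],
                                 seq_len(n_cells)),
               time_point = time_points[i], silenced = sil,
               xi_allele = xi, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truths)
  n <- nrow(truth)
  depth <- pmax(stats::rnbinom(n, size = spec$depth_size,
                               mu = spec$depth_mu), 2)
  on_x <- features$chrom == "chrX"
  lam_base <- outer(rates, depth / 2)   # genes x cells, per allele
  mod1 <- matrix(1, n_total_genes, n)
  mod2 <- matrix(1, n_total_genes, n)
  mod1[on_x, truth$xi_allele == "hap1"] <- spec$completeness
  mod2[on_x, truth$xi_allele == "hap2"] <- spec$completeness
  if (spec$sex == "male") mod2[on_x, ] <- 0
  hap1 <- matrix(stats::rpois(n_total_genes * n, lam_base * mod1),
                 n_total_genes, n)
  hap2 <- matrix(stats::rpois(n_total_genes * n, lam_base * mod2),
                 n_total_genes, n)
  cells <- data.frame(cell_id = truth$cell_id,
                      time_point = truth$time_point,
                      sex = spec$sex, stringsAsFactors = FALSE)
  list(counts = allelic_counts(hap1, hap2, features, cells), truth = truth)
}
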