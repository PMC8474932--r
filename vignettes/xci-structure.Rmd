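---
title: "Calling the bipartite inactive X from allele-resolved single-cell Hi-C"
author: "xcistruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling the bipartite inactive X from allele-resolved single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcistruct)
```

## The problem

During X-chromosome inactivation (XCI) in female mammalian cells, the
inactive X (Xi) folds into a distinctive bipartite conformation: two large
superdomains of dense long-range contacts separated at the *Dxz4* hinge
locus. Bulk Hi-C sees this structure as a population average; single-cell
Hi-C with haplotype-resolved (allelic) contacts can ask the sharper
question of *which individual cells*, and *which homolog within each
cell*, have acquired it — and how that timing relates to allelic gene
silencing and chromatin-accessibility loss during differentiation.

The obstacle is sparsity: a single cell yields only tens to a few thousand
allelically assignable intrachromosomal contacts per chromosome, far too
few to call superdomains from a per-cell contact map. This package instead
works with **contact decay profiles** (CDPs): per-cell, per-chromosome,
per-allele histograms of contact counts over exponentially growing
distance ranges. The bipartite Xi leaves a robust signature in the CDP — a
deficit of mid-range (85 kb–1.1 Mb) and an excess of very long-range
(6.5–87 Mb) contacts — that survives sparsity because it pools all
contacts on the chromosome.

## Contact decay profiles

Distances are binned on a logarithmic grid: bin $k$ ($k = 0,\dots,142$)
covers $[\,2^{10+0.125k},\ 2^{10+0.125(k+1)}\,)$ bp — 143 half-open bins
of width $2^{0.125}$, from 1024 bp to $2^{27.875}$ bp. Per cell,
chromosome and allele, profiles are **scale-normalized** to proportions
(divided by their total count) so that cells of very different sequencing
depth are comparable; normalization is per chromosome–allele rather than
per whole cell, so a chromosome's profile is a self-contained distance
distribution. For rank-based statistics the 143 bins are aggregated into
14 coarse bins of 10 consecutive fine bins each; the trailing 3 fine bins
cover distances beyond any mouse chromosome ($\ge 2^{27.5} \approx
1.9\times10^8$ bp) and are dropped.

Two details are deliberate decisions rather than forced choices:

* **Bin width.** The operative definition is width $0.125$ in the
  exponent, which is the only reading consistent with 143 bins spanning
  exponents 10–27.875.
* **Heatmap z-scaling** (`zscale_profiles()`) standardizes each *bin
  column* across cells, with the population standard deviation and
  constant columns mapped to 0.

## The bipartite-Xi classifier

Two per-cell statistics compare the chrX homologs:

* **LMD** (long-range minus mid-range difference): on the normalized
  profile, $\mathrm{LMD} = \sum_{\text{6.5–87 Mb}} p_k -
  \sum_{\text{85 kb–1.1 Mb}} p_k$. Both range endpoints coincide with bin
  edges ($85\,\mathrm{kb} = 2^{16.375}$, $1.1\,\mathrm{Mb} \approx 2^{20}$,
  $6.5\,\mathrm{Mb} \approx 2^{22.625}$, $87\,\mathrm{Mb} \approx
  2^{26.375}$), so no partial bins arise. The classifier statistic is
  $\Delta\mathrm{LMD} = \mathrm{LMD}_{hap1} - \mathrm{LMD}_{hap2}$.
  Computing LMD on proportions (not raw counts) makes the statistic
  coverage-invariant, which matters when cells differing 25-fold in depth
  are thresholded together.
* **Spearman-CDP**: the rank correlation $\rho$ between the two homologs'
  14-bin rebinned profiles, with average ranks for ties. A low $\rho$
  flags a cell whose homologs have diverged in shape, without identifying
  which one is the Xi.

**Threshold fitting.** Neither statistic has a usable parametric null, but
chr1 provides an empirical one: its homologs are structurally equivalent,
so the chr1 distribution of the same statistic is the distribution under
"no bipartite homolog". `xci_classifier()` fits the call threshold as the
nearest-rank (ceiling) empirical quantile of the chr1 statistic at a 10%
false-positive rate — the $(1-\mathrm{FPR})$ quantile of
$|\Delta\mathrm{LMD}|$, or the $\mathrm{FPR}$ quantile of $\rho$ — and
calls chrX with a strict inequality. Nearest-rank quantiles and strict
calls remove interpolation ambiguity and make at most
$\lfloor \mathrm{FPR}\cdot n\rfloor$ of the null exceed the threshold by
construction. In LMD mode the homolog with the higher LMD is assigned as
the Xi.

Cells must first pass per-allele coverage on both chromosomes (50
intrachromosomal contacts per chromosome–allele by default; 100 for
deeply sequenced fibroblast-like data). Cells failing coverage are "no
call" and are excluded from every denominator — call proportions are
always fractions of *callable* cells.

ROC evaluation (`classifier_roc()`) sweeps all thresholds of
$|\Delta\mathrm{LMD}|$ pooled across cells, with chrX supplying the
true-positive rate and chr1 the false-positive rate at each threshold, and
trapezoid AUC over the step curve. `embedding_timepoint_auc()` implements
the companion evaluation for multimodal embeddings: for each anchor cell,
other cells are ranked by Euclidean distance and scored against
same-time-point membership; per-anchor AUCs are averaged within time
points and then across them.

## Cell-cycle staging

Mitotic chromosomes lose compartment structure and gain a characteristic
contact enrichment at 2–12 Mb separations (the "mitotic band"); the Xi
bipartite signature disappears at mitosis and re-forms in interphase, so
cell-cycle staging is a necessary companion analysis. Per cell,
`cellcycle_profile()` builds a non-allelic CDP aggregated over all
autosomes, restricted to the 58 fine bins fully inside 50 kb–8 Mb — the
range that best captures cell-cycle dynamics — and normalized.

`cluster_cellcycle()` groups these profiles into $k = 4$ clusters by
k-means under a Spearman correlation distance. Since k-means is defined
for Euclidean geometry, each profile is rank-transformed, centered and
unit-normalized first: on such vectors, squared Euclidean distance is an
affine function of $1 - \rho$, so Euclidean k-means optimizes the intended
criterion. Determinism and input-order invariance are obtained by putting
profiles in a canonical lexicographic order before the seeded
initialization. The cluster with the highest mean mitotic-band fraction is
labelled mitotic (stage 1); the rest are ordered by decreasing short-range
fraction as interphase progression. The band definitions for the QC
scatter — short range $[1\,\mathrm{kb}, 2\,\mathrm{Mb})$, mitotic band
$[2, 12)$ Mb — follow the single-cell Hi-C cell-cycle literature and are
exposed as arguments; the analysis itself fixes no numeric band.

## The V-shaped contact score

On a binned pseudobulk allelic map (500 kb default), the contact score of
a central bin is the mean count over all matrix cells $(i, j)$ with
$i \le c \le j$ and $j - i$ within a 20 Mb arm — every contact spanning
the locus out to the arm length; sliding this V-shaped region along the
diagonal gives a per-locus track. A pseudocount of 1 is added to every
bin; windows truncated at the chromosome ends divide by the number of
cells actually included. Scores are normalized as
$\log_2(\text{score}/\text{chromosomal mean})$ (mean over valid bins),
bins in the first and last 10 Mb are excluded against edge effects, and
the track is smoothed with a five-window, degree-2 Savitzky–Golay filter.
Originally-missing bins are cubic-spline interpolated before smoothing
(linear if fewer than 4 anchors) and restored to `NA` afterwards.
`locate_dip()` then finds the local minimum nearest a locus — on the Xi,
the dip at the *Dxz4* hinge between the two superdomains — and reports its
depth against the flanking local maxima. The score uses cis contacts
only.

## Allelic expression and accessibility skew

XCI status is called from UMI counts with the same null-threshold logic.
Per cell, the total allelic expression (TAE) of each chrX homolog is
summed; the statistic is $\log_2((T_{hap1}+1)/(T_{hap2}+1))$, with the
pseudocount keeping fully silenced alleles at finite ratios. The threshold
is the 10% FPR quantile of the chr1 ratio null — recomputed from the data
at hand, never hard-coded (1.2 is retained only as a regression-test
default) — and a strict exceedance calls the cell, with the lower-total
homolog silenced and the higher-total homolog as the active X. Chromatin
accessibility (TAA) follows the identical path with peak regions as
features and a 500-UMI per-cell prefilter.

Inclusion filters: features with coverage along one allele in at least 10
cells; cells with at least 10 UMIs per chr1 and chrX allele. The cell
filter has two documented readings — per allele, or combined over both
alleles of a chromosome — because a fully silenced allele (0 UMIs) must
remain callable in the skew analysis; `feature_cell_filters()` exposes
both and the skew path uses the combined rule.

`silencing_timecourse()` aligns RNA, ATAC and Hi-C calls per time point
into one table of percentages of callable cells, which is where the lag
of the Xi structural change behind silencing becomes visible.

## The synthetic-data generator

The generator produces the inputs the analysis assumes, with truth labels,
so every stage can be verified without external data.

**Contacts.** Distances follow $P(d) \propto d^{-\alpha}$ on
$[1\,\mathrm{kb}, L]$, discretized on the 143-bin analysis grid
(inverse-CDF per bin, then exact power-law sampling within the bin) —
aligning generator and analysis resolution makes effect sizes directly
interpretable in CDP bins. Defaults: two chromosomes (chr1 195 Mb, chrX
171 Mb), $\alpha = 1$, log-uniform coverage of 50–5000 contacts per
allele per chromosome, 3% mitotic cells. A mitotic cell multiplies the
2–12 Mb band mass by 8. A bipartite Xi multiplies mid-range mass by 0.5
and long-range mass by 4 (renormalized), with the superdomain hinge at
44% of chrX and long-range contacts placed within one superdomain where
they fit. Per time point, the bipartite fraction is allocated
deterministically by rounding; among bipartite cells the Xi is hap1 with
probability 0.75 (a 3:1 skew).

**Counts.** Per-gene rates are log-normal and shared across cells;
per-cell depth is negative-binomial (mean 2000 UMIs, size 10); counts are
Poisson at depth × rate / 2 per allele. Silenced cells express the Xi
allele of chrX genes at 2% of baseline (near-complete silencing with
escape); male cells carry no hap2 chrX. The default gene allocation gives
chr1 and chrX **equal expressed mass** (200 genes each): the threshold
transfer from chr1 to chrX assumes the null statistic has the same
sampling distribution on both chromosomes, and since the log-ratio's
spread scales as $1/\sqrt{\text{total UMIs}}$, a generator with strongly
unequal chromosome masses would break the very premise the method rests
on. Pre-XCI female cells, with two active X chromosomes, make comparable
allelic output realistic.

**What the generator does not emulate.** No TAD/loop or compartment
structure, no polymer physics, no trans-contact structure (a uniform trans
fraction exists only for QC testing), no overdispersed or
zero-inflated expression beyond the NB-Poisson hierarchy, no doublets or
barcode errors. Passing tests therefore demonstrate correctness of the
statistics and calibration of the thresholds under the stated sampling
model — not robustness to every artefact of real sci-experiments. One
consequence worth knowing: at $\alpha = 1$ every logarithmic bin carries
equal mass, so profiles are flat in log-distance and the Spearman-CDP
statistic has no rank signal to work with; concordance between the
Spearman and LMD routes is meaningful only under a sloped decay
($\alpha > 1$), which is also the realistic regime.

## Calibration checks and expected call rates

A classifier operating at a nominal 10% FPR calls approximately
$f + 0.1(1-f)$ of cells when the true positive fraction is $f$ (with
near-unit sensitivity, which strong effects and 2% silencing completeness
give). Recovery tests therefore compare observed call counts with the
exact binomial interval around this *expected call rate* — propagating
generator truth through the classifier's operating characteristics —
rather than around $f$ itself, which a correctly calibrated classifier
would systematically exceed at small $f$. Mitotic truly-bipartite cells
display no structure while condensed and sit on the null side of this
calculation.

The FPR calibration experiment is fully held out: 2000 null cells, a
threshold fitted on 1000 training cells' chr1 statistics, and the call
rate measured on the other 1000 cells' chrX statistics, accepted within
the exact binomial 99% interval of the nominal rate.

## Problem sizes and numerical choices

The shipped tests run at desk scale: 2000 cells for calibration, 200
cells per time point for recovery, 100 cells per archetype for
cell-cycle staging, 100-bin matrices for contact-score oracles, 150
cells per time point for skew — sizes at which the binomial intervals are
tight enough to be informative while the whole suite runs in minutes.
Other numerical choices: nearest-rank quantiles everywhere a threshold is
fitted; strict inequalities for all calls; ties in ranks by averaging;
cis:trans ratio with zero trans treated as passing (the test is a lower
bound); population standard deviation in z-scaling with constant columns
to 0; pseudocount 1 in the contact score and allelic ratios (set the
contact-score pseudocount to 0 to make the track exactly scale-invariant).

## Limitations

The package calls *whether* a cell has a bipartite chrX homolog and
*which* homolog it is; it does not estimate superdomain boundaries from
single-cell maps, call TADs or compartments, or test dip depths
statistically. Upstream processing — alignment to an N-masked genome, SNP
assignment, barcode demultiplexing, duplicate removal — is assumed done.
Real-data headline figures from deeply sequenced datasets (e.g. overall
bipartite percentages in specific cell lines) depend on those datasets and
are not reproduced by the synthetic suite; what the suite establishes is
that each statistic computes what it claims and that every fitted
threshold holds its nominal error rate under the generator's sampling
model.
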