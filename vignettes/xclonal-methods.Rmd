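---
title: "Models and methods behind xclonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xclonal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xclonal)
```

# The biological setting

Random X-chromosome inactivation (XCI) silences one of the two X chromosomes
in every cell of an early XX embryo, and the choice is inherited clonally.
A heterozygous XX individual is therefore a mosaic of two clonal
compartments that express mutually exclusive X-linked alleles. Two questions
follow naturally:

1. **How much coding diversity does XCI expose?** Any two X haplotypes
   differ at some number of missense sites; within one individual, XCI
   partitions exactly that diversity into two cell populations.
2. **Are the two compartments equally represented?** Departures from the
   50% expectation can arise from selection or competition between clones —
   or from nothing but sampling noise among a finite number of embryonic
   founder cells.

xclonal implements the four quantitative pieces needed to work on these
questions: a pairwise haplotype-difference statistic over phased cohorts, an
allele-specific qPCR/read-count quantification of clone fractions with a
skew test, a cluster-proportion permutation analysis with gene-set scoring
for single-cell data, and a stochastic founder-sampling null model. A
synthetic-data layer generates every input with known ground truth, so the
whole pipeline is testable end to end without external downloads.

# Pairwise haplotype diversity

`read_phased_haplotypes()` expands a phased chrX VCF into a 0/1
haplotype-by-site matrix: two rows per female (her phased haplotypes), one
per male. `pairwise_differences()` then computes Hamming distances either
over **all unordered pairs** of cohort haplotypes — the population-level
reading of "any two X chromosomes", H(H−1)/2 pairs — or **within
individuals**, one pair per female, which is the diversity XCI actually
partitions inside one body. Both modes are exposed because cohort-scale pair
counts (millions of pairs for thousands of haplotypes) indicate the
all-pairs convention, while the biological framing is intra-individual.

The canonical filter (`filter_sites()`) keeps missense sites and masks genes
that escape XCI, since escape genes are expressed from both X chromosomes
and do not differentiate the two compartments. Escape status is a per-gene
property supplied as a gene list or BED file — annotation is an input, never
predicted in-package.

Two independent routes to the mean guard the implementation. A site where
$c_s$ of $H$ haplotypes carry the alternate allele contributes
$c_s(H-c_s)$ discordant pairs, so

$$\bar d \;=\; \frac{\sum_s c_s\,(H-c_s)}{\binom{H}{2}},$$

which `mean_pairwise_closed_form()` evaluates directly from allele counts.
The test suite holds the enumerated mean equal to this closed form to
1e-9 on simulated cohorts (up to ~200 haplotypes and 2,000 sites), and the
`dist()`-based fast path equal to a naive per-site loop.

Quantiles in `summarize_diversity()` use the inverse-empirical-CDF rule (the
smallest difference count whose cumulative pair fraction reaches the
probability) so a statement like "90% of pairs carry at least the 10th
percentile" is exactly decidable rather than interpolation-dependent.

**Missing genotypes** are dropped site-wide by default. This keeps $H$
constant at every retained site, which keeps the closed form exact; the
alternative (per-pair exclusion) would make the pair denominator
site-dependent.

# Allele-specific qPCR quantification

Allele-specific TaqMan probes read out the variant:wild-type mRNA ratio as a
threshold-cycle difference. The package uses the minimal kinetics-consistent
logit model

$$\Delta C_T \;=\; C_{T,\mathrm{var}} - C_{T,\mathrm{wt}}
  \;=\; \delta \;-\; \log_E \frac{f}{1-f},$$

with $f$ the variant-clone fraction, $E$ the amplification efficiency (fold
per cycle, default 2 — near-ideal TaqMan doubling) and $\delta$ a fitted
offset: the $\Delta C_T$ of a 50:50 mixture, absorbing probe-specific
normalisation. Calibration mixtures of known $f$ identify $\delta$ exactly
(mean residual intercept with $E$ fixed) or $(E, \delta)$ jointly by linear
regression on $\ln(f/(1-f))$ when at least three distinct fractions are
available. Quantification inverts the model,
$f = 1/(1 + E^{\Delta C_T - \delta})$, and the 95% interval transforms
$\Delta C_T \pm 1.96\,s$ (calibration residual SD $s$) through the same map,
so it respects $[0,1]$ by construction. Fractions are averaged per
biological replicate *after* inversion, and `test_skew()` applies a
two-sided one-sample t test of the replicate fractions against the 50%
expectation; zero-variance inputs take explicit degenerate branches (p = 1
at the null mean, p = 0 otherwise, both flagged).

Boundary mixtures ($f \in \{0, 1\}$) have infinite $\Delta C_T$ under the
model and are rejected by the simulator and the calibration fitter with an
explicit message. Count-based readouts (cDNA sequencing) use
`quantify_counts()`: $f = \mathrm{alt}/(\mathrm{alt}+\mathrm{ref})$ with a
Wilson score interval, which unlike the Wald form stays inside $[0,1]$ at
the boundaries.

The simulator adds i.i.d. Gaussian per-well noise in cycles (default SD 0.2,
a typical qPCR technical spread; configurable). The round trip
simulate → calibrate → quantify recovers fractions to 1e-9 with zero noise,
and with 0.25-cycle noise and 8 calibration mixtures the mean absolute
recovery error over 200 samples of 3 replicates stays below 0.05.

# Cluster proportions, permutation and gene-set scoring

For two genotype conditions profiled by scRNA-seq, per-cluster
representation is compared as

$$\log_2\mathrm{FC}_k \;=\; \log_2
  \frac{n_{k,\mathrm{var}} / T_{\mathrm{var}}}
       {n_{k,\mathrm{wt}} / T_{\mathrm{wt}}},$$

where the denominators $T$ are the QC-passing totals, not the sum of
annotated clusters (cells assigned to no cluster form an explicit
"unassigned" stratum during resampling). A pseudocount of 0.5 is added to
*both* counts of a cluster only when either is zero, keeping empty clusters
finite without perturbing the rest.

`permutation_test()` pools all cells with their cluster labels and
repeatedly reassigns condition labels preserving the two totals; the
two-sided p-value uses the add-one form
$p = (1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\})/(1 + n_{iter})$, which
is never exactly zero and finite-sample valid. Internally the reassignment
is drawn as a multivariate hypergeometric allocation — distribution-identical
to shuffling individual labels but vectorisable across iterations — and the
allocation is drawn for the condition with the smaller total, making the
test exactly symmetric under exchanging the two conditions at a fixed seed.
The default 1,000 iterations mirror common practice; the suite checks the
Monte-Carlo p against exhaustive enumeration on a 6-cell instance and the
type-I error rate (0.05 ± 0.02 over 500 null datasets). Two-sidedness on
$|\log_2\mathrm{FC}|$ is the conservative choice where sidedness is not
dictated by the question. `bootstrap_ci()` resamples cells with replacement
within each condition for a percentile interval, and `fdr_adjust()` applies
Benjamini–Hochberg step-up via `stats::p.adjust`.

`gene_set_auc()` scores each cell by the area under the recovery curve of a
gene set within the top-ranked fraction of genes (default 5%, the customary
rank cutoff for this score family), normalised to the maximum achievable
area; ties are broken by stable gene index for cross-platform determinism.
The score depends only on within-cell ranks and is therefore invariant under
any strictly monotone transform of the expression values — normalisation
choices upstream cannot move it. Classification uses an inclusive threshold
(default 0.2), so a score exactly at the threshold is positive.

# The founder-sampling null

Under random XCI with no selection, each of an individual's $N$ founder
cells independently keeps one X active (probability $p = 1/2$ under the fair
null; a bias parameter is exposed for carrier backgrounds with skewed
choice). The fraction of clones with the focal X active is $K/N$,
$K \sim \mathrm{Binomial}(N, p)$, with mean $p$ and variance $p(1-p)/N$ —
so sampling alone produces skew, and more of it the fewer the founders. An
optional second layer subsamples $M \le N$ founders hypergeometrically into
a tissue (allocation to germ layers or tissue anlagen), which can only add
variance. Selection and competition are deliberately *not* parameterised:
the model is the null against which observed skew is judged.

`estimate_founders()` inverts the variance by method of moments,
$\hat N = 1/(4\widehat{\mathrm{Var}})$, with a percentile bootstrap over
individuals; zero observed variance carries no information about $N$ beyond
a lower bound and is flagged as an unbounded (infinite) estimate rather than
silently capped. Simulation recovery holds $\hat N$ within [14, 18] for
$N = 16$ at 10,000 individuals in ≥95% of repetitions.

# The synthetic-data layer

`simulate_cohort()` draws per-site allele frequencies from a Beta
distribution and then draws each haplotype's allele independently per site.
Defaults emulate a large reference cohort: 1,271 XX and 1,233 XY donors
(3,775 haplotypes), 13,796 coding sites, a rare-allele-heavy Beta(0.2, 2)
spectrum, a 2:1 missense:synonymous split (the typical coding ratio), and
20% of genes escaping XCI (the literature range is roughly 15–23%). The
empirical spectrum of any particular cohort is not claimed — the Beta shape
is a configurable placeholder. Genes are contiguous, non-overlapping site
blocks with per-gene escape status; females are written phased (`a|b`),
males haploid (`0`/`1`), and the loader accepts both male dialects while
rejecting haploid females.

What the generator deliberately does **not** emulate: linkage
disequilibrium (sites are independent), recombination, demography, and
read-level noise. The pairwise-difference statistic is site-marginal, so LD
affects only the variance of pair counts, never the mean — tests of the
mean and of the closed-form equivalence are unaffected, but the simulated
*spread* of the distribution is narrower than real cohorts would show.
Passing tests demonstrate correctness of the computations, not realism of
any particular spectrum.

`simulate_cluster_counts()` defaults its condition totals to 6,274 and
6,073 cells — realistic QC-passing totals for a sorted bone-marrow
progenitor experiment — and records the renormalised expected fold changes
as truth. `simulate_ranked_expression()` plants an additive gene-set boost
in a labelled subset of cells over a log-normal background; only ranks
matter downstream.

# Numerical and design choices

* **Seeds.** Every stochastic function takes `seed = NULL`; a supplied seed
  is applied via an isolated RNG scope so callers' RNG state is never
  disturbed, and identical seeds give byte-identical simulator output.
* **Quantiles** are inverse-empirical-CDF (type 1), computed directly on the
  difference histogram.
* **Pair distances** use `stats::dist(method = "manhattan")` on the 0/1
  matrix (equal to Hamming), verified against a naive loop.
* **Degenerate inputs** take explicit branches: zero-variance skew tests,
  zero-variance founder estimates, empty clusters (pseudocount), empty
  post-filter site sets (allowed; downstream errors only where a statistic
  is undefined).
* **Problem sizes in the checks.** The shipped verification uses cohorts up
  to ~200 haplotypes × 2,000 sites, 500 null datasets × 1,000 permutation
  iterations, 1e5 individuals for the variance law and 1e4 for founder
  recovery — sizes at which every Monte-Carlo tolerance asserted is several
  standard errors wide.

# Limitations

* Consequence annotation and escape-gene lists are inputs; the package
  neither predicts consequences nor ships a definitive escape list.
* The qPCR model assumes a single shared efficiency for both probes;
  probe-specific efficiencies are absorbed into $\delta$ only to first
  order.
* The founder estimator assumes the fair-choice null when inverting
  1/(4N); under biased choice the variance formula generalises but the
  default inversion does not.
* Cohort simulation is site-independent; do not use it to study the
  variance or tails of the pairwise-difference distribution of real
  populations.
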