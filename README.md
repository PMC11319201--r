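# xclonal

Tools for quantifying the genetic diversity that random X-chromosome
inactivation (XCI) exposes inside XX individuals, and for testing whether
the two resulting clonal compartments are equally represented.

Random XCI silences one X per cell early in development and the choice is
clonally inherited, so a heterozygous XX individual is a mosaic of two cell
populations expressing mutually exclusive X-linked alleles. xclonal
implements the four quantitative pieces needed to study this mosaic:

* **Pairwise haplotype diversity** — from a phased chrX VCF, the
  distribution of Hamming distances between X haplotypes, with missense
  filtering and escape-gene masking. The all-pairs mean has an exact
  allele-frequency closed form, \(\bar d = \sum_s c_s (H - c_s) / \binom{H}{2}\),
  used as an internal cross-check.
* **Allelic skew** — allele-specific qPCR CT pairs are inverted through the
  calibrated logit model \(\Delta C_T = \delta - \log_E \frac{f}{1-f}\) to
  variant-clone fractions \(f\) (read counts use a Wilson interval instead),
  and a one-sample t test compares replicate fractions to the 50% XCI
  expectation.
* **Clonal proportions** — per-cluster log2 fold changes of cell
  proportions between genotypes, tested by label-permutation
  (add-one p-values), with percentile bootstrap intervals,
  Benjamini–Hochberg FDR, and an AUCell-style gene-set recovery-curve score
  for classifying primed cells (inclusive threshold, default 0.2).
* **Founder-sampling null** — each of \(N\) founder cells picks an active X
  at random, so clone fractions are \(K/N\), \(K \sim \mathrm{Bin}(N, 1/2)\),
  with variance \(1/(4N)\); `estimate_founders()` inverts this by method of
  moments with a bootstrap interval.

A synthetic-data layer (`simulate_cohort()`, `simulate_qpcr_panel()`,
`simulate_cluster_counts()`, `simulate_ranked_expression()`,
`simulate_xci_cohort()`) generates every input with known ground truth, so
the full pipeline runs and is tested without any external download.

All user-facing functions take data frames (or file paths) and return
tibbles; fitted objects have `tidy()`/`glance()` methods and result types
have `autoplot()` methods.

## Worked example

Simulate a phased cohort, load it, filter to missense sites outside escape
genes, and summarise the pairwise difference distribution:

```r
library(xclonal)

cfg <- cohort_sim_config(n_females = 50, n_males = 40, n_sites = 2000,
                         n_genes = 100, seed = 42)
cohort <- simulate_cohort(cfg, out_dir = tempdir())
hm <- read_phased_haplotypes(cohort$vcf, cohort$panel,
                             annotation = cohort$annotation)
hm_missense <- filter_sites(hm, keep_consequences = "missense",
                            escape = cohort$escape_bed)
hm_missense
#> <haplotype_matrix> 140 haplotypes (50 females, 40 males) x 1000 sites
#>   consequences: missense=1000

dist_all <- pairwise_differences(hm_missense, mode = "all_pairs")
summarize_diversity(dist_all, threshold = 100)
#> # A tibble: 1 × 9
#>   n_pairs  mean   min   max   q10   q50   q90 frac_ge_threshold threshold
#>     <int> <dbl> <int> <int> <dbl> <dbl> <dbl>             <dbl>     <dbl>
#> 1    9730  115.    84   147   104   115   126             0.962       100

mean_pairwise_closed_form(hm_missense)
#> [1] 114.9009
```

So the 140 simulated haplotypes form 9,730 pairs differing at 115 missense
sites on average (range 84–147), 96% of pairs differ at 100 or more sites,
and the allele-frequency closed form reproduces the enumerated mean exactly.

Quantify clone fractions from a simulated qPCR panel and test for skew in
blood:

```r
panel <- simulate_qpcr_panel(c(blood = 0.07, brain = 0.48, muscle = 0.35),
                             n_replicates = 6, delta = 1.2, noise_sd = 0.2,
                             seed = 7)
calmix <- simulate_qpcr_panel(
  setNames(seq(0.1, 0.9, length.out = 8), paste0("mix", 1:8)),
  n_replicates = 1, delta = 1.2, noise_sd = 0.1, seed = 8)
cal <- fit_calibration(
  data.frame(fraction = attr(calmix, "truth")$true_fraction,
             delta_ct = calmix$ct_var - calmix$ct_wt))
fr <- quantify_qpcr(panel, cal)
test_skew(fr$fraction[fr$sample == "blood"], expected = 0.5)
#> <skew_test> mean fraction 0.0626 vs expected 0.50: t = -68.705, df = 5, p = 1.237e-08
```

The variant compartment contributes only ~6% of blood transcripts (true
simulated value 7%), decisively below the 50% null.

Estimate the founder number from simulated clone fractions:

```r
sim <- simulate_xci_cohort(n_founders = 8, n_individuals = 10000, seed = 1)
estimate_founders(sim, seed = 2)
#> <founder_fit> N-hat = 7.83 (~8 founders), 95% CI [7.6, 8.0], n = 10000
```

Test per-cluster proportion shifts between genotypes:

```r
cc <- simulate_cluster_counts(
  c(HSC = 0.12, Lymphoid = 0.28, GM = 0.35, Ery = 0.18, Mega = 0.07),
  log2fc = c(0.6, -1.1, 0.25, 0.3, 0.3),
  n_wt = 6274, n_variant = 6073, seed = 5)
test_cluster_proportions(cc, n_iter = 1000, seed = 6)
#> # A tibble: 5 × 8
#>   cluster  prop_wt prop_variant log2fc conf.low conf.high  p.value      fdr
#>   <chr>      <dbl>        <dbl>  <dbl>    <dbl>     <dbl>    <dbl>    <dbl>
#> 1 HSC       0.117        0.160   0.458    0.330     0.588 0.000999 0.000999
#> 2 Lymphoid  0.289        0.127  -1.18    -1.29     -1.07  0.000999 0.000999
#> 3 GM        0.352        0.411   0.222    0.161     0.286 0.000999 0.000999
#> 4 Ery       0.175        0.216   0.305    0.204     0.415 0.000999 0.000999
#> 5 Mega      0.0674       0.0855  0.342    0.163     0.535 0.000999 0.000999
```

All planted shifts are recovered with tight intervals; the smallest
attainable p at 1,000 iterations is 1/1001 ≈ 0.000999.

Every stage is also invocable from the shell through the thin wrapper in
`inst/cli/xclonal.R`, e.g.

```sh
Rscript inst/cli/xclonal.R simulate_cohort --seed 3 --out cohort_out n_females=6 n_males=4 n_sites=60 n_genes=6
Rscript inst/cli/xclonal.R diversity --out div_out vcf=cohort_out/cohort.vcf panel=cohort_out/panel.tsv annotation=cohort_out/sites.tsv escape_bed=cohort_out/escape.bed
```

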