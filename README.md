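# msatpop

Population-genetics analysis of co-dominant microsatellite (SSR) genotype
panels, written for fishery and conservation studies that ask the classic
questions of a riverine sample: how diverse is the population, is it
inbreeding, has it been through a bottleneck, how large is its effective
size and how fast will it lose heterozygosity, and is the catch one stock
or several?

The package covers, end to end:

* **Data model and I/O** — a `genotype_panel` stores diploid allele calls as
  fragment sizes (bp) with per-individual metadata (section, season, year,
  stock); readers/writers for a tabular CSV dialect, GenePop 4.x (rank-coded
  with a sidecar so true sizes survive a round trip) and STRUCTURE files.
* **Diversity** — Na, Ho, Nei's unbiased He, PIC, Weir–Cockerham Fis with a
  within-population permutation test, and the Chakraborty null-allele index
  `r = (He − Ho)/(He + Ho)`.
* **Exact tests** — Guo–Thompson-style Hardy–Weinberg exact test (complete
  enumeration for small tables, a Markov chain over genotype tables
  otherwise), genotypic linkage-disequilibrium G tests, Holm sequential
  Bonferroni, Fisher's combination.
* **Bottlenecks** — heterozygosity-excess tests under IAM, SMM and TPM via
  coalescent simulation of the equilibrium heterozygosity conditional on the
  observed allele count (one-tailed Wilcoxon signed-rank across loci), and
  the modified Garza–Williamson `M = k/(r+1)` with the 0.68 criterion.
* **Effective size and outlook** — the linkage-disequilibrium Ne estimator
  (Burrows composite r², sample-size bias correction, jackknife 95% CI over
  locus pairs), drift decay `Ht/H0 = (1 − 1/(2Ne))^t`, and a threat
  classification from the 25%-loss rule at t = 10/50/100 generations.
* **Differentiation** — Weir–Cockerham θ, standardized F′ST (maximum-FST
  recoding), Jost's D, allele-level AMOVA with permutation tests, exact
  G tests of allele-frequency heterogeneity.
* **Stock structure** — an admixture-model Gibbs sampler (Q matrices,
  replicate alignment, Evanno ΔK and Puechmaille-style K selectors), a
  compact DAPC, and seasonal stock-composition tables.
* **Synthetic data** — a two-stock Balding–Nichols panel generator
  emulating the study design the package validates against (324 fish,
  14 loci, 5 river sections, seasonal stock mixing, inbreeding, null
  alleles), plus a forward Wright–Fisher simulator for calibrating the Ne
  and bottleneck methods.

## Worked example

```r
library(msatpop)

panel <- simulate_panel(sim_config(seed = 11))   # 324 fish, 14 loci, 2 stocks
panel
#> genotype_panel: 324 individuals x 14 loci
#>   alleles/locus: 7 - 30 | missing calls: 0
#>   sections: S4 S5 S6 S7 S8

ml <- multilocus_summary(panel, "S4", n_perm = 1000, seed = 1)
round(c(na = ml$mean_na, ho = ml$mean_ho, he = ml$mean_he, fis = ml$fis), 3)
#>     na     ho     he    fis
#> 16.500  0.809  0.873  0.074

est <- estimate_ne_ld(panel, "S4", maf_cutoff = 0.02)
est
#> LD Ne [S4]: Inf (2975.78-Inf), S = 64, pairs = 91

proj <- project_heterozygosity(select_ne_for_projection(est))
round(proj$ht_reduction_pct, 3)
#> [1] 0.168 0.837 1.666
classify_threat(proj)
#> [1] "non-threatened"
```

The Fis of ~0.07 recovers the generator's inbreeding setting.  With no real
linkage-disequilibrium signal in this panel the point estimate is infinite,
so the projection falls back to the lower confidence bound (2976), exactly
the convention used when a point estimate cannot be resolved; the projected
losses (0.17% of He after 10 generations, 1.7% after 100) stay far below
the 25% threshold of every threat class and the section is classified
non-threatened.

`run_full_analysis()` chains every module (diversity → Hardy–Weinberg →
bottleneck/Ne → clustering → differentiation) and writes the familiar
table shapes as CSV plus a results JSON.

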