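---
title: "Methods and design notes for msatpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for msatpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`msatpop` implements the statistical toolkit of a microsatellite
population-genetics study: diversity and inbreeding statistics, exact
Hardy–Weinberg and linkage tests, heterozygosity-excess bottleneck tests,
linkage-disequilibrium effective population size with a drift-decay
outlook, differentiation statistics, and admixture-model stock inference.
This vignette explains each model, its assumptions and tunable parameters,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The data model

A `genotype_panel` is an individuals × loci matrix of unordered diploid
allele pairs, stored as integer fragment sizes in base pairs (the scale on
which microsatellite alleles are scored, here 100–450 bp) and
canonicalized smaller-first.  A cell is either fully called or fully
missing; half-calls are rejected at parse time because no downstream
statistic can use them coherently.  Each locus carries a `motif_length`
(repeat-unit size, 3–5 bp for the tri-/tetranucleotide loci this package
targets), which is the divisor of the Garza–Williamson M-ratio.  GenePop
export rank-encodes alleles as 3-digit codes and writes a sidecar mapping
(code → bp, motif) because GenePop's numeric codes would otherwise destroy
the size information the M-ratio needs.  When a file carries no motif
information, motif length is inferred as the greatest common divisor of
allele-size differences — correct whenever at least two alleles on the
ladder differ by a single repeat unit, and overridable via
`motif_lengths`.

Grouping is late-bound: `section` (the sampling unit) is the default
population variable, with `stock`, `season` and `season × year` available
at analysis time, because all three axes are legitimate analysis frames
for a seasonally mixed fishery sample.

## Diversity statistics

Allele frequencies are computed over the `2n` allele copies of the
non-missing genotypes of a population (pairwise deletion; listwise
deletion would discard most individuals in a 14-locus panel for no
inferential gain).  Expected heterozygosity uses Nei's unbiased
small-sample form `He = (2n/(2n−1)) (1 − Σ p_i²)` — needed for per-locus
values at section-level sample sizes (n ≈ 40–90) to be comparable with
standard software output; `unbiased = FALSE` disables it.  PIC is
`1 − Σ p_i² − Σ_{i<j} 2 p_i² p_j²`.

The inbreeding coefficient is the Weir–Cockerham within-population
estimator from variance components: per locus,
`b = n/(n−1) [(1 − Σp²) − (2n−1)/(2n) · Ho]` and `c = Ho`, with
`Fis = Σb / Σ(b+c)` summed over loci (and over alleles within a locus).
This form is zero exactly when Ho equals the unbiased He, and the
multilocus value reduces to the single-locus value when only one locus is
informative — which is why the same estimator is used at both levels
rather than the cruder `1 − Ho/He`.  Significance of Fis > 0 is a
one-tailed permutation test that shuffles allele copies among individuals
within the population: frequencies are invariant under this permutation,
so only the heterozygote deficit is tested (10,000 permutations by
default).

Null alleles are screened with the Chakraborty homozygote-excess index
`r = (He − Ho)/(He + Ho)`, clipped to [0, 1], with loci flagged suspect
above 0.2 (a deliberately blunt screen: its role is to justify excluding
loci from downstream analysis, mirroring how null-allele-carrying loci are
conventionally dropped).  `filter_panel()` implements both that exclusion
(`drop_loci`, removed everywhere) and the minimum-allele-frequency screen
(`min_maf`, default 0.02) whose result only masks alleles for the Ne
estimator — diversity statistics keep every allele.

## Exact tests

The Hardy–Weinberg test conditions on allele counts.  For ≤ 3 alleles and
≤ 30 individuals the genotype-table space is enumerated completely and the
p-value is the exact probability of tables no more probable than the one
observed (ties resolved on table probability, the Guo–Thompson
convention).  Larger problems run a Markov chain whose state is the
assignment of the 2n allele copies to n ordered genotype slots; a random
transposition of two slot contents is always accepted, because the uniform
distribution over labelled arrangements induces exactly the conditional
law `P(f) ∝ 2^h / Π f_ij!`.  This avoids any Metropolis ratio and mixes by
construction.  Chain defaults are 100,000 recorded steps after 10,000
dememorization steps; the chain agrees with the enumeration branch to
±0.015 in the test suite.  Monomorphic loci return p = 1 by convention.

The genotypic linkage test is a log-likelihood-ratio G on the two-locus
genotype contingency table with a permutation null (one locus's genotypes
shuffled among individuals), `p = (1 + #{G* ≥ G}) / (1 + B)`.  Pairs
sharing fewer than 10 genotyped individuals are flagged rather than
tested.

Multiple testing uses Holm's sequential Bonferroni (step-down, stop at the
first failure).  Cross-locus combination uses Fisher's method
(`X² = −2 Σ log p`, df = 2m) and is labelled as such, since a global
permutation alternative would be equally defensible; zero p-values are
clamped to the smallest positive double and flagged.

## Bottleneck detection

The heterozygosity-excess test rests on the observation that after a crash
allele number erodes faster than heterozygosity, so observed He exceeds
the equilibrium heterozygosity expected for the observed allele count.
For each polymorphic locus the package simulates that equilibrium
distribution conditional on the allele count k: θ is matched to k by
bisection on the expected allele number (closed form under the
infinite-alleles model via `E[K] = Σ θ/(θ+i)`; Monte-Carlo under the
stepwise and two-phase models), genealogies are simulated (a
Chinese-restaurant-process draw for IAM, which is the coalescent's allele
configuration law; a Kingman tree with Poisson mutations stepping ±1
repeat unit, or a geometric multi-step with probability `1 − p_ss`, for
SMM/TPM), and only replicates realizing exactly k alleles are kept.  The
standardized deviation `DH = (He_obs − mean Heq)/sd Heq` feeds a
one-tailed Wilcoxon signed-rank test of median DH > 0, exact (via the
signed-rank null) up to 25 loci and normal-approximated above.

Conditioning on k makes the IAM configuration law θ-free, which is what
the exhaustive Ewens-sampling-formula oracle in the test suite exploits
(n ≤ 8 genes, k ≤ 4: enumeration of all partitions with weights
`n!/Π j^{a_j} a_j!`).  A point worth stating explicitly: for fixed (n, k),
equilibrium heterozygosity is *highest* under SMM and lowest under IAM,
because stepwise mutation regenerates existing allele sizes and needs a
larger θ — hence more even frequencies — to hold k alleles.  That ordering
(asserted in the tests) is what makes microsatellite panels from
constant-size populations test "significant" under the IAM reference while
the SMM reference stays null — the familiar pattern of IAM-everywhere-
significant bottleneck tables — and is why the package's power experiment
contrasts crashed and constant-size Wright–Fisher populations under the
SMM reference.

TPM parameters default to 70% single-step mutations with multi-step
variance 30 (the convention of the standard bottleneck-testing program);
both are exposed because the TPM column of any bottleneck table depends on
them.  Coalescent replicates default to 10,000 per locus, reduced in tests
for speed.

The modified Garza–Williamson index is `M = k/(r+1)` with `r` the allele
size range in repeat units (rounded; floor division with a logged note for
off-ladder ranges), averaged over loci, with the published 0.68 criterion
for recent severe reductions.  `M = 1` on a fully occupied ladder and
falls as interior rungs empty.  Monomorphic loci return `M = 1` (r = 0),
a documented convention.  The per-population "overall" row pools all
individuals (the alternative, averaging populations, is available by
calling per population).

## Effective population size and outlook

`estimate_ne_ld()` implements the linkage-disequilibrium method: for every
locus pair, Burrows' composite disequilibrium Δ̂ (with the n/(n−1)
correction) across all allele pairs passing the frequency screen, squared
and normalized by the composite denominators `p(1−p) + D_A` which absorb
within-locus Hardy–Weinberg departure — appropriate because the method is
applied to samples that may carry heterozygote deficits.  Allele-pair r²
values are averaged with weights proportional to sample size, the
sampling-bias expectation `E[r²|S] = 1/S + 3.19/S²` (S ≥ 30; the
small-sample polynomial below) is subtracted, and the random-mating
estimator `Ne = (1/3 + √(1/9 − 2.76 r²'))/(2 r²')` applied.  A
non-positive r²' or negative discriminant yields ∞ — the honest answer
when drift leaves no detectable signal.  The 95% CI is a delete-one
jackknife over locus pairs on the weighted mean r², converted to an
effective chi-square df (`n' = 2 r̂²²/var_jack`) and mapped through the
same formula; in the Wright–Fisher calibration (true Ne = 100, S = 50,
20 loci) the interval covers the truth in ≥ 17 of 20 replicates.  Because
the estimator is unbiased, a no-signal panel returns ∞ in only about half
of replicates and a very large finite value otherwise; the test suite
asserts "∞ or ≥ 5× sample size" rather than an ∞-count no unbiased
estimator could deliver.

The outlook uses the drift-decay law `Ht/H0 = (1 − 1/(2Ne))^t`.  When the
point estimate is infinite the projection uses the lower confidence bound
(`select_ne_for_projection()`), the standard fallback when a point cannot
be resolved.  Threat classes apply a 25% He-loss rule with inclusive
comparisons: ≥ 25% by t = 10 → critically endangered, by 50 → endangered,
by 100 → vulnerable, else non-threatened.

## Differentiation

Weir–Cockerham variance components (a, b, c per allele per locus; `θ = Σa
/ Σ(a+b+c)`) are the FST workhorse.  The standardized F′ST divides θ by
its maximum, obtained by recoding each population's alleles to be private
while keeping the genotype structure — the recoding flavour of
standardization, chosen and labelled because published standardizations
differ.  Jost's D uses the sample-size-corrected estimator
(`Hs' = (2ñ/(2ñ−1)) Hs`, `Ht' = Ht + Hs'/(2ñk)`, ñ the harmonic mean
sample size) with `D = (k/(k−1))(Ht'−Hs')/(1−Hs')`; the multilocus value
is the harmonic mean of positive per-locus values (documented because
tools differ; with the small-sample corrections, identical sample
profiles give values near but not exactly zero).  AMOVA is allele-level
(two gene copies per individual), with sums of squares from
allele-identity distances, moment-equation components summed across loci,
Φ_ST = σ²_among/σ²_total, and significance by permuting individuals among
groups (999 by default, matching the granularity of a P = 0.001 report).
Negative components are reported as computed, with a floored Φ in the
summary view only.  The degrees-of-freedom line prints (groups − 1,
2N − 1): among and total, the pair a 5-section, 324-fish panel renders as
(4, 647).  The exact G test of allele-frequency heterogeneity samples the
conditional null by randomly reallocating allele copies among populations
— i.i.d. draws from the margin-fixed table distribution, equivalent in
law to the usual Markov-chain samplers but independent by construction —
and combines loci with Fisher's method.

## Stock inference

`admixture_mcmc()` is a Gibbs sampler for the admixture model with
independent allele-frequency priors: Dirichlet(λ) frequency updates per
cluster and locus, categorical cluster assignment per allele copy, and
Dirichlet(α + counts) membership updates per individual.  Missing cells
contribute nothing.  The sampler reports the posterior-mean Q and the mean
post-burn-in data log-likelihood L(K); a large split-half difference in
L flags non-convergence without failing the run.

α is sampled by default (Metropolis on a uniform (0, 10) prior with a
log-scale random walk), as the reference implementation of this model
does.  This was a deliberate reversal of an initial fixed-α design: with
α fixed at 1 the membership prior keeps all K clusters materially
occupied when K exceeds the true number, posterior-mean memberships smear,
and cluster-counting K selectors degenerate to 1.  With sampled α the
two-stock recovery concentrates (≥ 99% of individuals above 0.8
membership at divergence 0.05 with 300 fish × 14 loci).  `sample_alpha =
FALSE` restores the fixed prior.  The independent-frequency prior (rather
than the correlated one) is the remaining fidelity gap versus the original
program at weak divergence, and is documented as such.

K selection offers the Evanno statistic `ΔK = mean_r |L_r(K+1) − 2L_r(K) +
L_r(K−1)| / sd_r L(K)` (replicates paired, interior K only, undefined when
the sd is zero) and four Puechmaille-style counts: per replicate at the
largest K, a cluster is "real" when its mean (or median) membership in at
least one predefined group passes 0.5, with MEDMEANK/MAXMEANK/MEDMEDK/
MAXMEDK the median/max over replicates and a floor of one.  River sections
are the default predefined groups; for a seasonally mixed design where
both stocks co-occur in every section, the seasons are the informative
grouping and are what the package's own two-stock validation passes to
`select_k()`.  The final `chosen_k` is the modal value over the five
selectors with ties to the smaller K.  Replicate label switching is undone
by greedy column matching against the first replicate (correlation-based);
chain lengths default to 50,000/10,000 (desk scale — the ensembles in the
test suite use 2,500/800, which the recovery experiments show is ample at
this signal strength), with the million-step configuration available via
arguments.

`dapc_lite()` is a compact discriminant-analysis-of-principal-components:
one-hot allele-count encoding, centering (missing cells at the column
mean), PCA truncation (fixed n_pcs or grouped cross-validation), linear
discriminant analysis, and leave-one-out accuracy.  `season_composition()`
assigns each fish to its argmax cluster when that membership reaches 0.5
(ties and sub-threshold rows are "admixed" — the assignment threshold is
this package's convention) and tabulates percentages per season × year.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure the analysis
assumes, with defaults set to the study design the package validates
against: 324 individuals at 14 tetranucleotide loci across five sections
(S4–S8), 9–35 alleles per locus from a symmetric Dirichlet (concentration
0.6, which reproduces the high-He, rare-allele-rich frequency profiles of
real microsatellite panels), two stocks at target FST 0.006 via a
Balding–Nichols construction (stock frequencies ~ Dirichlet(p·(1−F)/F),
chosen for its closed-form expected FST; the calibration is verified by
simulation at F = 0.05), inbreeding Fis = 0.07 implemented exactly as
`P(hom_i) = p_i² + p_i(1−p_i)f`, seasonal mixing with Stock2 at 92% of
rainy-season and Stock1 at 65% of dry-season catches (capture percentages
treated as sampling proportions, since true stock sizes are not part of
the design), and optional null alleles (a hidden allele whose
heterozygous carriers appear homozygous and whose homozygotes go missing)
and missing data.  Allele ladders are contiguous (every rung occupied at
simulation start), so simulated M-ratios sit near 1 rather than at the
fragmented values of real historical panels — one of several features of
real data the generator does not emulate, along with genotyping error,
stutter, allele-size homoplasy and family structure.  Passing tests
therefore certify the estimators against the model's assumptions, not
against laboratory artefacts.

`simulate_wright_fisher()` is the calibration harness: a diploid
random-mating population of configurable size (with a size-change schedule
for crash scenarios), unlinked loci, per-copy mutation under IAM, SMM or
TPM, sampled at the final generation.  It generates genuine
drift-generated linkage disequilibrium (offspring draw two parents; one
allele per locus per parent), which is exactly the signal the LD-Ne method
consumes.

## Problem sizes and reproducibility

Every stochastic routine takes a seed and is deterministic given it; the
pipeline derives per-stage seeds from one global seed and records them in
its results.  The test suite runs at reduced problem sizes chosen to keep
the full suite under a few minutes while leaving the assertions
well-powered: coalescent references at 150–10,000 replicates per locus,
type-I-error experiments at 400–500 replicates, Wright–Fisher calibrations
at 10–20 paired runs, and clustering ensembles at 2,500 sweeps × 3
replicates over K = 1–4.  `run_full_analysis()` defaults sit between
these test scales and full desk scale.

## Known limitations

* No rarefaction of allelic richness and no stepwise-weighted RST.
* The admixture sampler uses independent frequency priors and single-chain
  posterior means; within-chain label switching at very weak divergence is
  not corrected (only across replicates).
* Jost's D multilocus aggregation is undefined when every locus is
  non-positive except as the documented zero convention.
* The LD-Ne bias correction uses the published random-mating polynomial;
  no monogamy variant, temporal method or sibship estimator is provided.
* The tabular motif-inference heuristic (gcd of size differences) can
  overestimate motif length for loci observed with only compound-repeat
  spacing; supply `motif_lengths` when it matters.
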