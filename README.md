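# dartsex

Discovery of sex-linked markers from reduced-representation genotyping
(DArTseq-style SNP and SilicoDArT presence/absence reports), with a qPCR
gene-dosage module for molecular sexing.

## The problem

In many reptiles (and other non-model vertebrates) the sex chromosomes are
homomorphic: males and females cannot be told apart by karyotype, and it
may not even be known whether the species is male-heterogametic (XX/XY) or
female-heterogametic (ZZ/ZW). Genome complexity reduction genotyping
scores tens of thousands of short sequence tags per individual as either
codominant SNP genotypes or dominant presence/absence (PA) fragments.
Given a cohort of phenotypically sexed individuals, loci whose genotype
tracks sex reveal both the heterogamety system and candidate
sex-chromosome sequence.

`dartsex` implements that screen for population geneticists working with
DArT-style one-row reports:

* **Filtering.** Under the XY hypothesis, a SNP locus is retained at
  stringency *s* when, over called individuals, female reference-allele
  homozygosity ≥ *s*, female SNP-allele homozygosity and heterozygosity
  are each ≤ 0.30, male heterozygosity ≥ *s* and male reference
  homozygosity ≤ 1 − *s* (male SNP-allele homozygosity is unconstrained,
  because X–Y recombination can fix the SNP allele on some X copies). A PA
  locus is retained when the fragment is present in ≥ *s* of males and
  absent in ≥ *s* of females. The ZW rules are the exact sex mirror. The
  grid *s* ∈ {0.70, 0.80, 0.90, 1.00} separates *perfectly* (*s* = 1,
  non-recombining region) from *moderately* (*s* < 1, recombining margin)
  sex-linked loci.
* **Statistics.** Pairwise proportional Hamming distances
  (pairwise-complete denominator) with within-/between-sex summaries; the
  Cochran–Armitage trend test χ² = N·r² with allele-dose scores (0, 1, 2);
  polymorphism information content PIC = 2p(1 − p); the probability that a
  locus is sex-concordant by chance, *P* = 0.5ⁿ, and the expected number
  of spurious hits *L*·0.5ⁿ; criterion comparisons via chi-square,
  Kruskal–Wallis and a Nemenyi post hoc.
* **qPCR dosage sexing.** Relative dosage R = 2^(C̄p_ref − C̄p_target),
  male:female ratio r = R̄_m/R̄_f (≈ 0.5 for X-linked genes degenerate on
  the Y, ≈ 1 for autosomal genes) with an exact rank-sum test,
  standard-curve efficiency E = −1 + 10^(−1/slope), and 10 % / 15 %
  intra-/inter-assay CV gates.
* **Simulation.** A generator plants autosomal, perfectly sex-linked and
  partially sex-linked (recombined) loci with configurable missingness
  and error, plus qPCR plates with known copy ratios, so every statistic
  can be validated against ground truth.

## Worked example

Simulate a cohort of 14 males and 15 females at 10,000 SNP loci (clean
calls), filter at the strictest 100:0 XY criterion, and inspect the
retained loci:

```r
library(dartsex)
sim <- simulate_population(sim_config(missing_rate = 0, error_rate = 0,
                                      seed = 1))
res <- run_filter(sim$snp, sim$sexes, list(filter_criterion("XY", 1)))
res$XY_100
#> XY_100 filter (SNP markers): 23/10000 loci retained (perfectly sex-linked)
head(res$XY_100$table[c("locus_id", "het_m", "ref_hom_f",
                        "catt_chi2", "catt_p", "pic", "class")], 3)
#>    locus_id het_m ref_hom_f catt_chi2      catt_p       pic   class
#> 1 SNP_09801    14        15        29 7.23783e-08 0.3662307 perfect
#> 2 SNP_09802    14        15        29 7.23783e-08 0.3662307 perfect
#> 3 SNP_09803    14        15        29 7.23783e-08 0.3662307 perfect
```

Every retained locus is heterozygous in all 14 males and
reference-homozygous in all 15 females, so the trend test reaches its
complete-separation value χ² = N = 29 (p ≈ 7×10⁻⁸). 23 loci are retained:
the 5 planted perfect loci plus 18 planted *partial* loci that happened to
realise no recombinant male — at ρ = 0.15 a partial locus escapes
recombination in all 14 males about 10 % of the time, which is exactly why
the screen's "perfect" class is an observational, not mechanistic, label.

How worried should we be that these are flukes? With 29 individuals:

```r
random_linkage(29, 20000)
#> P(sex-linked by chance | n = 29) = 1.86e-09; expected among 20,000 loci = 3.73e-05
```

The qPCR route, on a noise-free simulated plate with an X-linked target:

```r
q <- simulate_qpcr_plate(noise_sd = 0, seed = 1)
plate_dosages(q$plate)$ratios$SEXL1
#> relative gene dosage ratio r = 0.500 (W = 0, p = 0.007937; 5 males vs 5 females)
```

Males carry one X copy against two in females, so r = 0.5 and the exact
5-vs-5 rank-sum test gives p = 2/252.

The full pipeline (`run_pipeline(run_config(...))`) evaluates both
heterogamety hypotheses across the whole stringency grid and writes the
retained-locus table, distance summaries, FASTA of retained tags and a
criteria-by-marker summary table to an output directory.

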