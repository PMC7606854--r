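---
title: "Discovering sex-linked markers from DArT-style genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked markers from DArT-style genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartsex)
```

## The screen and its assumptions

`dartsex` screens reduced-representation genotyping data — DArT-style
one-row SNP reports and SilicoDArT presence/absence (PA) reports — for
loci whose calls track phenotypic sex, in species where the heterogamety
system (XX/XY vs ZZ/ZW) is itself unknown. The underlying genetic model
is simple:

* Under male heterogamety, a locus in the non-recombining region of the
  sex pair has its reference allele on the X and a diverged (SNP) allele
  on the Y. Every male is then heterozygous and every female is
  homozygous for the reference allele. A Y-specific restriction fragment
  is present in every male and absent from every female.
* Where X and Y still recombine, the SNP allele leaks onto X haplotypes:
  some males become reference-homozygous (their Y carries an X-type
  state), and the sex signal weakens in proportion to the recombination
  fraction.
* An autosomal locus shows the same genotype distribution in both sexes.

The screen therefore evaluates each locus against both hypotheses at a
grid of stringencies $s \in \{0.70, 0.80, 0.90, 1.00\}$. For XY and SNP
markers, a locus is retained at stringency $s$ iff, with frequencies over
**called** individuals of each sex,

$$f^{\mathrm{ref/ref}}_{F} \ge s, \quad f^{\mathrm{snp/snp}}_{F} \le d,
\quad f^{\mathrm{het}}_{F} \le d, \quad f^{\mathrm{het}}_{M} \ge s,
\quad f^{\mathrm{ref/ref}}_{M} \le 1 - s,$$

with the discard bound $d = 0.30$. Male SNP-allele homozygosity is left
unconstrained: if recombination has placed SNP alleles on X copies, a
genuinely sex-linked locus can show SNP-homozygous males, and rejecting
those would bias the screen against the recombining margin. PA markers
are retained iff the fragment is present in $\ge s$ of called males and
absent in $\ge s$ of called females. ZW rules are the exact sex mirror.
Retention at $s = 1$ defines *perfectly* sex-linked loci (the candidate
non-recombining region); retention only at $s < 1$ defines *moderately*
sex-linked loci (candidate recombining margin).

Design choices in the rule, made once and kept:

* **Denominator.** Frequencies use called individuals of a sex, not the
  cohort size: reduced-representation call rates below 1 would otherwise
  make "100 % of males" unattainable for loci with a single missing call.
  `denominator = "cohort"` restores the stricter convention.
* **Inclusive thresholds.** "At least 70 %" is read inclusively
  ($\ge s$, with a $10^{-9}$ guard against float noise in ratios such as
  $10/14$ vs $0.7142\ldots$).
* **The female discard rule** requires *both* SNP-allele homozygosity and
  heterozygosity to be $\le d$; retaining a locus when either exceeds
  0.30 would admit loci polymorphic in females, contradicting the aim of
  minimising SNP-allele carriage in the homogametic sex.
* **The discard bound stays at 0.30 at every stringency.** An alternative
  would tighten it to $1 - s$; we keep it fixed so that moving along the
  stringency grid changes only the concordance requirement, making the
  nesting $R(1.00) \subseteq R(0.90) \subseteq R(0.80) \subseteq R(0.70)$
  a structural property (verified after every run, and by property tests).
* **Uncallable vs rejected.** A locus with fewer called individuals than
  `min_called` (default 1) in either sex is flagged `uncallable`, a
  distinct outcome from failing the thresholds.
* **Missing-call spelling.** Real exports write missing calls as "-", the
  Unicode minus, "NA" or an empty cell; all are normalised to `NA`. For
  PA markers some pipelines gloss "-" as putative heterozygosity; we
  deliberately treat it as a plain non-call, since nothing downstream can
  use a half-dose interpretation of a dominant marker.

## Supporting statistics

**Hamming distances.** $d(i,j)$ is the fraction of *jointly called* loci
at which samples $i$ and $j$ differ; pairs with no jointly called locus
are flagged undefined and excluded (with a count) from group means. Group
summaries report mean, standard error (headline) and standard deviation
over the within-male, within-female and between-sex pair sets: on loci
passing the 100:0 XY filter with complete data these are forced to
$1.000 \pm 0.000$ between sexes and $0.000 \pm 0.000$ within males, which
is the package's acceptance check of the distance geometry.

**Trend test.** The Cochran–Armitage trend test with allele-dose scores
$(0, 1, 2)$ for (reference homozygote, heterozygote, SNP homozygote) —
the file coding's "2 = heterozygote" is *not* the dose order — and
$(0, 1)$ for (absent, present). Computed as $\chi^2 = N r^2$ with $r$ the
score–sex correlation over called individuals, referred to
$\chi^2_1$; this equals the classical variance-formula statistic, and the
tests verify it against `stats::prop.trend.test` and the collapsed-2×2
Pearson statistic. Under complete separation $\chi^2 = N$ exactly, e.g.
29 for 14 heterozygous males vs 15 reference-homozygous females. Raw
p-values are reported (the screen's significance filter is raw
$p < 0.001$ by convention); a Bonferroni column is emitted alongside for
users who want familywise control, but no correction is applied by the
package itself.

**PIC.** For biallelic markers, $2p(1-p)$ with $p$ from allele counting
over called genotypes (presence frequency for PA markers): 0 at fixation,
0.5 at $p = 0.5$.

**Random sex-linkage.** With $n$ individuals genotyped, a locus is
sex-concordant by chance with probability $P = 0.5^{\,n}$; over $L$
screened loci $L \cdot 0.5^{\,n}$ spurious hits are expected. At
$n = 29$, $L = 173{,}144$: $P \approx 1.86 \times 10^{-9}$, expected
$\approx 3.2 \times 10^{-4}$.

**Criterion comparison.** `compare_criteria()` runs a chi-square over the
retained-count table and a Kruskal–Wallis test over per-locus
heterozygosity by criterion group, with a Nemenyi all-pairs post hoc
(Tukey-type over mean midranks, studentized-range reference). The Nemenyi
step is implemented in-package because no installed package provides it;
it reduces at $k = 2$ to the normal-theory two-group comparison.

## The qPCR dosage module

Females (XX) carry two copies of X-specific genes against one in males,
so the dosage of a target gene relative to a same-sample reference gene,
$R = 2^{\bar{C}p_{\mathrm{ref}} - \bar{C}p_{\mathrm{target}}}$
(replicate means first; only the Cp difference matters), has male:female
ratio $r = \bar R_M / \bar R_F \approx 0.5$ for X-linked,
Y-degenerate genes and $\approx 1$ for autosomal or pseudoautosomal
genes. The male/female comparison uses an exact Mann–Whitney rank-sum
test — full enumeration of all $\binom{n_M + n_F}{n_M}$ rank subsets up
to 20 samples, midranks under ties, tie-corrected normal approximation
beyond — implemented in-package and cross-checked against
`stats::wilcox.test`. (The field often reports this comparison under the
signed-rank name; the sampling design is unpaired, so the rank-sum test
is the defensible choice and is labelled as such.)

Standard curves are least-squares fits of mean Cp against
$\log_{10}$ concentration over a serial dilution; efficiency
$E = -1 + 10^{-1/\mathrm{slope}}$, so perfect doubling ($E = 1$) has
slope $-1/\log_{10} 2 \approx -3.32$, and a non-negative slope flags the
curve invalid. Replicate quality uses the intra-assay CV (sample SD of a
replicate group over its mean, ×100; gate 10 %) and inter-assay CV
(over per-plate means; gate 15 %). The $n-1$ SD is used; with triplicates
the distinction is immaterial relative to the gates.

## What the simulator emulates — and what it does not

`simulate_population()` generates the statistical structure the screen
assumes, with known ground truth:

* *Perfect* loci: heterogametic sex heterozygous (PA: present),
  homogametic sex reference-homozygous (PA: absent), no exceptions.
* *Partial* loci: each heterogametic individual's Y (W) haplotype carries
  the X-type (Z-type) state independently with probability $\rho$ — such
  males become reference-homozygous (PA: absent). The homogametic sex is
  unaffected; the construction models recombination pressure on the
  heterogametic haplotype only.
* *Autosomal* loci: Hardy–Weinberg draws at a per-locus reference-allele
  frequency $p \sim U(a, b)$, identical in both sexes; PA loci use a
  dominant model (present iff at least one presence allele,
  $1 - (1-q)^2$).
* Missingness first (probability $\mu$ per call, independent), then
  error (probability $\varepsilon$ per non-missing call, replaced by a
  uniform draw over the other valid states). Missing PA calls are a
  state distinct from "absent", mirroring the report files. A single
  seeded generator stream drives everything, so identical config + seed
  gives bit-identical output.

Defaults describe the study regime the package is validated in: 14 males
and 15 females; 20,000 loci (10,000 SNP + 10,000 PA — inside the
$10^4$–$10^5$ band typical of these assays, sized so the full pipeline
runs in seconds); planted classes of 5 / 30 perfect and 195 / 200 partial
SNP / PA loci, keeping perfect loci rare and rarer among SNPs than PA
markers, as observed in real screens; $\rho = 0.15$; $\mu = 0.05$
(call rates around 95 % are typical); $\varepsilon = 0.01$ (genotyping
error rates are rarely published for these platforms — the default is
exposed, not asserted); allele frequencies $U(0.3, 0.7)$, mimicking the
high-informativeness (PIC near 0.5) marker panels these platforms
deliver.

The simulator does **not** model linkage between loci, multi-chromosome
genome structure, read-level noise (depth-dependent dropout, allelic
imbalance), reproducibility scores, or sex-biased missingness. Passing
tests therefore demonstrate that the screen's arithmetic and its
recovery properties are correct under the assumed generative model — not
that any particular real dataset is free of the batch effects those
mechanisms produce.

One recovery subtlety is intrinsic, not a simulator artifact: a partial
locus with $\rho > 0$ realises zero recombinant males with probability
$(1-\rho)^{n_M}$ (about 10 % at $\rho = 0.15$, $n_M = 14$) and is then
*observationally identical* to a perfect locus. The tests assert exact
recovery of planted perfect loci in simulations without partial classes,
and, with partial classes present, that a partial locus is retained at
100:0 exactly when no recombinant male was realised.

`simulate_qpcr_plate()` generates crossing points as
$Cp = \mathrm{intercept} - \log_2(\mathrm{copy} \times \mathrm{conc}) /
\log_2(1+E) + N(0, \sigma)$, X-linked genes at one male copy vs two
female copies, with optional serial dilutions whose expected slope is
$-1/\log_{10}(1+E)$ — so the module's estimators can be checked against
the generating truth in closed form.

## Numerical choices and degenerate inputs

* Frequency/threshold comparisons carry a $10^{-9}$ tolerance; all other
  arithmetic is exact to double precision.
* A monomorphic locus (zero score variance) has trend statistic 0 by
  definition rather than an indeterminate $0/0$; a sex with zero called
  individuals makes the test undefined (flagged), not zero.
* All-tied Kruskal–Wallis input collapses to statistic 0, p = 1.
* Sample pairs with no jointly called locus get `NA` distances, excluded
  and counted in summaries; a sex with fewer than two members yields an
  undefined within-sex summary rather than a silent `NaN`.
* Exact rank-sum enumeration is used up to 20 combined samples
  ($\binom{20}{10} = 184{,}756$ subsets, milliseconds); beyond that the
  tie-corrected normal approximation with continuity correction.
* The pipeline removes partial outputs on failure and contains no
  timestamps in its artifacts, so fixed seed + config reproduces outputs
  byte-for-byte.

## Scale of the shipped validation

The test suite simulates cohorts of 14♂/15♀ (the validated study design)
at 60–500 loci per matrix for module tests, 100 randomised 8♂/9♀
matrices for the nesting property, and a 500-individual cohort for the
Hardy–Weinberg check; the acceptance script simulates the full 20,000
locus default once. These sizes were chosen as the smallest at which each
property is sharply testable; all statistics scale linearly in loci and
quadratically in samples (distance matrices), and the full default
pipeline runs in a few seconds.

## Known limitations

* The screen is a marginal, per-locus filter: it does not model linkage
  disequilibrium among candidate loci, nor correct for relatedness in
  the cohort (the validated design uses siblings from several clutches;
  relatedness inflates the effective false-positive rate relative to
  $0.5^n$).
* PA markers are dominant, so heterozygous fragment carriers are
  indistinguishable from homozygous ones; the PIC proxy for PA loci uses
  presence frequency, not allele frequency.
* The ZW path is validated only against the mirrored simulator; no
  female-heterogametic empirical dataset ships with the package.
* qPCR dosage assumes equal amplification efficiency between target and
  reference within the measured range; the standard-curve module
  quantifies but does not correct efficiency differences.
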