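Package: dartsex
Title: Sex-Linked Marker Discovery from Reduced-Representation Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sex-linked SNP and presence/absence (SilicoDArT) loci
    from DArT-style genotyping reports by contrasting male and female
    genotype frequencies under XY and ZW heterogamety hypotheses at graded
    stringencies (70:30 through 100:0), and classifies retained loci as
    perfectly or moderately sex-linked. Supporting statistics include
    pairwise proportional Hamming distances with within- and between-sex
    summaries, the Cochran-Armitage trend test, polymorphism information
    content, the probability of spurious sex-linkage at a given sample
    size, and criterion-comparison tests (chi-square, Kruskal-Wallis with
    Nemenyi post hoc). A quantitative PCR module implements molecular
    sexing by relative gene dosage: crossing-point based dosage, male to
    female dosage ratios with an exact rank-sum test, standard-curve
    amplification efficiency, and replicate coefficient-of-variation
    gates. A synthetic-data generator produces genotype matrices and qPCR
    plates with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
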