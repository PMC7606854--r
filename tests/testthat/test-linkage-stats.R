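test_that("hamming distances use the pairwise-complete denominator", {
  x <- make_snp(list(c("0", "0"), c("2", "0"), c("1", "1"), c(NA, "0")))
  d <- hamming_matrix(x)
  expect_equal(d["s1", "s2"], 1 / 3)  # jointly called at 3 loci, differ at 1
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  same <- make_snp(list(c("2", "2"), c("0", "0")))
  expect_equal(hamming_matrix(same)["s1", "s2"], 0)

  opposite <- make_snp(list(c("2", "0"), c("2", "0"), c("2", "0")))
  expect_equal(hamming_matrix(opposite)["s1", "s2"], 1)
})

test_that("pairs with no jointly called locus are flagged undefined", {
  x <- make_snp(list(c("0", NA, "0"), c(NA, "2", "0")))
  d <- hamming_matrix(x)
  expect_true(is.na(d["s1", "s2"]))
  expect_identical(attr(d, "n_undefined"), 1L)
  expect_error(
    hamming_matrix(make_snp(list(c(NA_character_, NA_character_)))),
    "missing")
})

test_that("hamming_matrix equals the exhaustive per-pair oracle on random matrices", {
  set.seed(99)
  for (rep in 1:5) {
    calls <- matrix(sample(c("0", "1", "2", NA), 200, replace = TRUE,
                           prob = c(0.35, 0.2, 0.35, 0.1)),
                    nrow = 10,
                    dimnames = list(sprintf("L%d", 1:10),
                                    sprintf("s%d", 1:20)))
    d <- hamming_matrix(calls)
    for (i in 1:19) for (j in (i + 1):20) {
      expect_equal(d[i, j], brute_hamming(calls[, i], calls[, j]))
    }
  }
})

test_that("group distance summaries match hand-computed pair averages", {
  # 2 males a,b and 2 females c,d with hand-set call vectors
  x <- make_snp(list(c("2", "2", "0", "0"),
                     c("2", "0", "0", "0"),
                     c("2", "2", "0", "2")),
                samples = c("a", "b", "c", "d"))
  d <- hamming_matrix(x)
  s <- summarize_distances(d, c("male", "male", "female", "female"))
  # within male: d(a,b) = 1/3; within female: d(c,d) = 1/3
  expect_equal(s$mean[s$group == "within_male"], 1 / 3)
  expect_equal(s$mean[s$group == "within_female"], 1 / 3)
  # between: d(a,c)=1, d(a,d)=2/3, d(b,c)=2/3, d(b,d)=1/3
  expect_equal(s$mean[s$group == "between"], mean(c(1, 2 / 3, 2 / 3, 1 / 3)))
  expect_identical(s$n_pairs, c(1L, 1L, 4L))
})

test_that("loci passing the 100:0 XY filter separate the sexes completely", {
  sim <- simulate_population(tiny_config(missing_rate = 0, error_rate = 0))
  res <- run_filter(sim$snp, sim$sexes, list(filter_criterion("XY", 1.0)))
  sub <- subset_loci(sim$snp, res$XY_100$retained)
  s <- summarize_distances(hamming_matrix(sub), align_sexes(sub, sim$sexes))
  expect_equal(s$mean[s$group == "between"], 1)
  expect_equal(s$sd[s$group == "between"], 0)
  expect_equal(s$mean[s$group == "within_male"], 0)
  expect_equal(s$se[s$group == "within_male"], 0)
})

test_that("a sex with fewer than two members yields an undefined within-sex summary", {
  x <- make_snp(list(c("2", "0", "0")), samples = c("m1", "f1", "f2"))
  s <- summarize_distances(hamming_matrix(x), c("male", "female", "female"))
  expect_false(s$defined[s$group == "within_male"])
  expect_true(is.na(s$mean[s$group == "within_male"]))
})

test_that("CATT equals N under complete separation and 0 under identical distributions", {
  full <- tally_locus(c(rep("2", 14), rep("0", 15)), sex_vector(14, 15),
                      "snp")
  expect_equal(catt(full)$statistic, 29)
  for (nm in c(1, 3, 8)) for (nf in c(1, 5, 12)) {
    counts <- tally_locus(c(rep("2", nm), rep("0", nf)),
                          sex_vector(nm, nf), "snp")
    expect_equal(catt(counts)$statistic, nm + nf)
  }
  same <- tally_locus(c(rep(c("0", "2", "1"), 4), rep(c("0", "2", "1"), 5)),
                      sex_vector(12, 15), "snp")
  expect_equal(catt(same)$statistic, 0)
})

test_that("CATT matches the enumerated N*r^2 value on the worked example", {
  counts <- snp_counts(m_ref = 5, m_het = 5, f_ref = 10)
  got <- catt(counts)
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(got$statistic, brute_catt(counts), tolerance = 1e-12)
  expect_equal(got$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE))
})

test_that("CATT agrees with independent oracles on random tables", {
  set.seed(123)
  for (rep in 1:25) {
    cnt <- sample(0:8, 6, replace = TRUE)
    counts <- snp_counts(m_ref = cnt[1], m_het = cnt[2], m_alt = cnt[3],
                         f_ref = cnt[4], f_het = cnt[5], f_alt = cnt[6])
    if (counts$male[["called"]] == 0 || counts$female[["called"]] == 0) {
      expect_false(catt(counts)$defined)
      next
    }
    expect_equal(catt(counts)$statistic, brute_catt(counts),
                 tolerance = 1e-10)
    # base-R trend-test oracle (events = males per genotype category)
    keep <- (cnt[1:3] + cnt[4:6]) > 0
    if (sum(keep) >= 2) {
      or <- suppressWarnings(stats::prop.trend.test(
        cnt[1:3][keep], (cnt[1:3] + cnt[4:6])[keep],
        score = c(0, 1, 2)[keep]))
      expect_equal(catt(counts)$statistic, unname(or$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("CATT on a two-category table equals the Pearson chi-square of the collapsed 2x2", {
  set.seed(321)
  for (rep in 1:20) {
    cnt <- sample(1:10, 4, replace = TRUE)
    counts <- snp_counts(m_ref = cnt[1], m_het = cnt[2],
                         f_ref = cnt[3], f_het = cnt[4])
    tab <- matrix(cnt, 2, byrow = TRUE)
    pearson <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(catt(counts)$statistic, unname(pearson$statistic),
                 tolerance = 1e-10)
  }
})

test_that("PA loci use presence/absence scores in the trend test", {
  counts <- pa_counts(m_pres = 14, f_abs = 15)
  expect_equal(catt(counts)$statistic, 29)
  expect_identical(names(catt(counts)$scores), c("absent", "present"))
})

test_that("PIC follows 2p(1-p) and is invariant to allele-label swap", {
  expect_equal(pic(0.5), 0.5)
  expect_equal(pic(0.9), 0.18)
  expect_equal(pic(0), 0)
  expect_equal(pic(1), 0)
  p <- stats::runif(20)
  expect_equal(pic(p), pic(1 - p))
  # from counts: 10 ref-hom + 10 het + 0 alt-hom -> p = 0.75
  counts <- snp_counts(m_ref = 5, m_het = 5, f_ref = 5, f_het = 5)
  expect_equal(pic(counts), 2 * 0.75 * 0.25)
  # monomorphic locus is uninformative
  expect_equal(pic(snp_counts(m_ref = 14, f_ref = 15)), 0)
  expect_true(is.na(pic(snp_counts(m_miss = 3, f_miss = 3))))
})

test_that("random sex-linkage probability is exact and halves per individual", {
  est <- random_linkage(29, 173144)
  expect_equal(est$p_random, 0.5^29)
  expect_equal(est$p_random, 1.86e-9, tolerance = 0.01)
  expect_equal(est$expected, 173144 * 0.5^29)
  expect_equal(est$expected, 3.23e-4, tolerance = 0.01)

  expect_equal(random_linkage(1, 10)$p_random, 0.5)
  expect_equal(random_linkage(10, 1000)$p_random, 9.765625e-4)
  expect_equal(random_linkage(10, 1000)$expected, 0.9765625)
  for (n in c(1, 5, 17))
    expect_equal(random_linkage(n + 1, 10)$p_random,
                 random_linkage(n, 10)$p_random / 2)
  expect_error(random_linkage(0, 10), "n must be")
  expect_error(random_linkage(5, 0), "n_loci")
})

test_that("criteria comparison: identical groups give boundary statistics", {
  het <- list(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3),
              c = c(0.1, 0.2, 0.3), d = c(0.1, 0.2, 0.3))
  counts <- matrix(10, 2, 2)
  cmp <- compare_criteria(counts, het)
  expect_equal(cmp$chisq$statistic, 0)
  expect_equal(cmp$kruskal$statistic, 0, tolerance = 1e-10)
  expect_equal(cmp$kruskal$p_value, 1)
  expect_true(isSymmetric(cmp$nemenyi))
  expect_equal(unname(diag(cmp$nemenyi)), rep(1, 4))
})

test_that("Kruskal-Wallis statistic matches a hand-ranked computation for two groups", {
  het <- list(lo = c(0.1, 0.2, 0.3), hi = c(0.7, 0.8, 0.9))
  cmp <- compare_criteria(c(lo = 3, hi = 3), het)
  # ranks 1..6, no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  h_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(cmp$kruskal$statistic, h_hand)
  # complete separation of ranks: Nemenyi p small, below the KW p
  expect_lt(cmp$nemenyi["lo", "hi"], 0.2)
})

test_that("groups with zero loci are excluded with a warning", {
  het <- list(a = c(0.1, 0.2), b = numeric(0), c = c(0.4, 0.5))
  expect_warning(cmp <- compare_criteria(c(a = 2, c = 2), het), "b")
  expect_identical(dim(cmp$nemenyi), c(2L, 2L))
  expect_error(suppressWarnings(
    compare_criteria(c(a = 2), list(a = c(0.1), b = numeric(0)))),
    "at least two")
})

test_that("all-ties heterozygosity collapses the KW test to its boundary", {
  het <- list(a = c(0.5, 0.5), b = c(0.5, 0.5))
  cmp <- compare_criteria(c(a = 2, b = 2), het)
  expect_equal(cmp$kruskal$statistic, 0)
  expect_equal(cmp$kruskal$p_value, 1)
})
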