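test_that("tally_locus counts per-sex call states exactly", {
  c1 <- tally_locus(c(rep("2", 14), rep("0", 15)), sex_vector(14, 15), "snp")
  expect_identical(unname(c1$male[["het"]]), 14L)
  expect_identical(unname(c1$male[["called"]]), 14L)
  expect_identical(unname(c1$female[["ref_hom"]]), 15L)
  expect_identical(unname(c1$female[["called"]]), 15L)

  c2 <- tally_locus(rep(NA_character_, 6), sex_vector(3, 3), "snp")
  expect_identical(unname(c2$male[["called"]]), 0L)
  expect_identical(unname(c2$female[["called"]]), 0L)

  # mixed toy against a hand enumeration
  calls <- c("0", "2", NA, "1", "0", "2")
  sexes <- c("male", "male", "male", "female", "female", "female")
  c3 <- tally_locus(calls, sexes, "snp")
  expect_identical(unname(c3$male[c("ref_hom", "het", "alt_hom", "missing")]),
                   c(1L, 1L, 0L, 1L))
  expect_identical(unname(c3$female[c("ref_hom", "het", "alt_hom", "missing")]),
                   c(1L, 1L, 1L, 0L))
  expect_error(tally_locus(calls, sexes[-1]), "length")
})

test_that("the perfect XY SNP pattern is retained at stringency 1.00 and near-misses are not", {
  perfect <- snp_counts(m_het = 14, f_ref = 15)
  expect_true(classify_snp_locus(perfect, filter_criterion("XY", 1.0)))
  near <- snp_counts(m_het = 13, m_ref = 1, f_ref = 15)
  got <- classify_snp_locus(near, filter_criterion("XY", 1.0))
  expect_false(got)
  expect_identical(attr(got, "status"), "rejected")
  expect_true(classify_snp_locus(near, filter_criterion("XY", 0.9)))
})

test_that("threshold arithmetic at the 70:30 criterion matches the stated fractions", {
  # males 4 RefHom + 10 Het of 14; females 11 RefHom + 2 Het + 2 AltHom of 15
  counts <- snp_counts(m_ref = 4, m_het = 10, f_ref = 11, f_het = 2,
                       f_alt = 2)
  expect_true(classify_snp_locus(counts, filter_criterion("XY", 0.7)))
  # same counts fail at 0.8 (male het 10/14 = 0.714 < 0.8)
  expect_false(classify_snp_locus(counts, filter_criterion("XY", 0.8)))
})

test_that("male SNP-allele homozygosity is unconstrained (recombination allowance)", {
  counts <- snp_counts(m_het = 10, m_alt = 4, f_ref = 15)
  expect_true(classify_snp_locus(counts, filter_criterion("XY", 0.7)))
  # but female SNP-allele homozygosity above the discard bound rejects
  bad_f <- snp_counts(m_het = 14, f_ref = 10, f_alt = 5)
  expect_false(classify_snp_locus(bad_f, filter_criterion("XY", 0.7)))
})

test_that("uncallable loci are flagged distinctly from rejections", {
  all_miss <- snp_counts(m_miss = 14, f_ref = 15)
  got <- classify_snp_locus(all_miss, filter_criterion("XY", 1.0))
  expect_false(got)
  expect_identical(attr(got, "status"), "uncallable")
})

test_that("PA classification compares presence and absence fractions per sex", {
  expect_true(classify_pa_locus(pa_counts(m_pres = 14, f_abs = 15),
                                filter_criterion("XY", 1.0)))
  # present 10/14 males (0.714), absent 11/15 females (0.733) at 70:30
  counts <- pa_counts(m_pres = 10, m_abs = 4, f_pres = 4, f_abs = 11)
  expect_true(classify_pa_locus(counts, filter_criterion("XY", 0.7)))
  expect_false(classify_pa_locus(counts, filter_criterion("XY", 0.8)))
  # present in every individual: never sex-specific
  everyone <- pa_counts(m_pres = 14, f_pres = 15)
  for (s in c(0.7, 0.8, 0.9, 1.0))
    expect_false(classify_pa_locus(everyone, filter_criterion("XY", s)))
})

test_that("cohort denominators are stricter than called denominators", {
  # 10/10 called males het, but 4 missing: cohort fraction 10/14 < 1
  counts <- snp_counts(m_het = 10, m_miss = 4, f_ref = 15)
  expect_true(classify_snp_locus(counts, filter_criterion("XY", 1.0),
                                 denominator = "called"))
  expect_false(classify_snp_locus(counts, filter_criterion("XY", 1.0),
                                  denominator = "cohort"))
})

test_that("planted perfect loci are recovered exactly at XY 100:0 with clean data", {
  sim <- simulate_population(tiny_config(missing_rate = 0, error_rate = 0,
                                         n_partial_snp = 0,
                                         n_partial_pa = 0))
  for (kind in c("snp", "pa")) {
    mat <- sim[[kind]]
    res <- run_filter(mat, sim$sexes, list(filter_criterion("XY", 1.0)))
    planted <- sim$truth$locus_id[sim$truth$class == "perfect_sex_linked" &
                                    sim$truth$kind == kind]
    expect_setequal(res$XY_100$retained, planted)
    # and the ZW mirror retains nothing: no female-specific loci planted
    zw <- run_filter(mat, sim$sexes, list(filter_criterion("ZW", 1.0)))
    expect_length(zw$ZW_100$retained, 0L)
  }
})

test_that("partial loci are retained at 100:0 only when no male recombinant is realised", {
  sim <- simulate_population(tiny_config(missing_rate = 0, error_rate = 0,
                                         n_auto_snp = 30, n_partial_snp = 40,
                                         recomb_fraction = 0.2, seed = 13))
  res <- run_filter(sim$snp, sim$sexes, list(filter_criterion("XY", 1.0)))
  truth <- sim$truth[sim$truth$kind == "snp", ]
  calls <- unclass(sim$snp)
  males <- align_sexes(sim$snp, sim$sexes) == "male"
  for (locus in truth$locus_id[truth$class == "partial_sex_linked"]) {
    all_het <- all(calls[locus, males] == "2")
    expect_identical(locus %in% res$XY_100$retained, all_het)
  }
  # no autosomal locus sneaks in
  expect_length(intersect(res$XY_100$retained,
                          truth$locus_id[truth$class == "autosomal"]), 0L)
})

test_that("retained sets are nested across stringencies on randomised simulations", {
  for (rep in 1:25) {
    sim <- simulate_population(tiny_config(
      n_auto_snp = 30, n_perfect_snp = 3, n_partial_snp = 10,
      n_auto_pa = 0, n_perfect_pa = 0, n_partial_pa = 0,
      recomb_fraction = stats::runif(1, 0, 0.4),
      missing_rate = stats::runif(1, 0, 0.2),
      error_rate = stats::runif(1, 0, 0.1), seed = 1000 + rep))
    res <- run_filter(sim$snp, sim$sexes,
                      criteria_grid(systems = c("XY", "ZW")))
    for (sys in c("XY", "ZW")) {
      expect_true(all(res[[paste0(sys, "_100")]]$retained %in%
                        res[[paste0(sys, "_90")]]$retained))
      expect_true(all(res[[paste0(sys, "_90")]]$retained %in%
                        res[[paste0(sys, "_80")]]$retained))
      expect_true(all(res[[paste0(sys, "_80")]]$retained %in%
                        res[[paste0(sys, "_70")]]$retained))
    }
  }
})

test_that("XY and ZW classification commute with swapping sex labels", {
  set.seed(42)
  for (rep in 1:20) {
    counts <- sample(0:6, 6, replace = TRUE)
    fwd <- snp_counts(m_ref = counts[1], m_het = counts[2],
                      m_alt = counts[3], f_ref = counts[4],
                      f_het = counts[5], f_alt = counts[6])
    rev <- snp_counts(m_ref = counts[4], m_het = counts[5],
                      m_alt = counts[6], f_ref = counts[1],
                      f_het = counts[2], f_alt = counts[3])
    if (fwd$male[["called"]] == 0 || fwd$female[["called"]] == 0) next
    for (s in c(0.7, 1.0)) {
      expect_identical(
        as.logical(classify_snp_locus(fwd, filter_criterion("XY", s))),
        as.logical(classify_snp_locus(rev, filter_criterion("ZW", s))))
    }
  }
})

test_that("classification is invariant to permuting individuals within a sex", {
  set.seed(7)
  calls <- c(sample(rep(c("2", "0"), c(12, 2))), sample(rep("0", 15)))
  sexes <- sex_vector(14, 15)
  base <- classify_snp_locus(tally_locus(calls, sexes, "snp"),
                             filter_criterion("XY", 0.8))
  for (i in 1:5) {
    perm <- c(sample(1:14), 14 + sample(1:15))
    got <- classify_snp_locus(tally_locus(calls[perm], sexes, "snp"),
                              filter_criterion("XY", 0.8))
    expect_identical(as.logical(got), as.logical(base))
  }
})

test_that("run_filter rejects an empty criteria list and misaligned sexes", {
  x <- make_snp(list(c("0", "2")))
  expect_error(run_filter(x, c("male", "female"), list()), "empty criteria")
  expect_error(run_filter(x, "male", list(filter_criterion("XY", 1))),
               "length")
})

test_that("criterion constructor validates stringency and labels criteria", {
  expect_error(filter_criterion("XY", 0.5), "stringency")
  expect_error(filter_criterion("XY", 1.2), "stringency")
  expect_identical(criterion_label(filter_criterion("ZW", 0.7)), "ZW_70")
  grid <- criteria_grid()
  expect_length(grid, 8L)
})
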