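# Summary statistics for sex-linkage analyses: proportional Hamming
# distances, Cochran-Armitage trend test, polymorphism information content,
# random sex-linkage probability, and criterion-comparison tests.

#' Pairwise proportional Hamming distance matrix
#'
#' For each pair of samples, the fraction of jointly called loci at which
#' their calls differ (pairwise-complete denominator). Pairs with zero
#' jointly called loci get an `NA` distance and are counted in the
#' `n_undefined` attribute.
#'
#' @param x a [snp_matrix()], [pa_matrix()] or plain character matrix
#'   (loci as rows, samples as columns, `NA` = missing).
#' @return A symmetric numeric matrix with zero diagonal and attributes
#'   `n_loci` (loci available) and `n_undefined` (pairs with no jointly
#'   called locus).
#' @examples
#' m <- rbind(L1 = c(a = "0", b = "0"), L2 = c(a = "2", b = "0"))
#' hamming_matrix(m)  # one of two loci differs: 0.5
#' @export
hamming_matrix <- function(x) {
  mat <- unclass(x)
  if (!is.matrix(mat)) stop("x must be a matrix", call. = FALSE)
  n <- ncol(mat)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  if (nrow(mat) < 1L) stop("need at least one locus", call. = FALSE)
  if (all(is.na(mat))) stop("all calls are missing", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  called <- !is.na(mat)
  undefined <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- called[, i] & called[, j]
      nb <- sum(both)
      if (nb == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- undefined + 1L
      } else {
        d[i, j] <- d[j, i] <- sum(mat[both, i] != mat[both, j]) / nb
      }
    }
  }
  structure(d, n_loci = nrow(mat), n_undefined = undefined)
}

#' Within- and between-sex distance summaries
#'
#' Averages the pairwise distances over the three pair sets (within males,
#' within females, between sexes). Dispersion is reported both as the
#' standard error of the pairwise-distance set (headline, `se`) and as the
#' standard deviation (`sd`). Undefined (`NA`) distances are excluded and
#' counted.
#'
#' @param d distance matrix from [hamming_matrix()].
#' @param sexes `"male"`/`"female"` vector aligned to the matrix samples,
#'   or a metadata data frame with matching `sample_id`s.
#' @return A data frame with one row per group (`within_male`,
#'   `within_female`, `between`): `mean`, `se`, `sd`, `n_pairs`,
#'   `n_excluded`, and `defined` (FALSE when the group has no pairs, e.g. a
#'   sex with fewer than two members).
#' @export
summarize_distances <- function(d, sexes) {
  if (is.data.frame(sexes))
    sexes <- as.character(sexes$sex)[match(colnames(d), sexes$sample_id)]
  if (length(sexes) != ncol(d))
    stop("sexes length does not match distance matrix", call. = FALSE)
  male <- which(sexes == "male"); female <- which(sexes == "female")
  pick <- function(rows, cols, within) {
    if (within) {
      if (length(rows) < 2L) return(numeric(0))
      v <- d[rows, rows, drop = FALSE]
      v[upper.tri(v)]
    } else {
      if (length(rows) == 0L || length(cols) == 0L) return(numeric(0))
      as.vector(d[rows, cols, drop = FALSE])
    }
  }
  groups <- list(within_male = pick(male, male, TRUE),
                 within_female = pick(female, female, TRUE),
                 between = pick(male, female, FALSE))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    excl <- sum(is.na(v)); v <- v[!is.na(v)]
    n <- length(v)
    data.frame(group = g,
               mean = if (n) mean(v) else NA_real_,
               se = if (n > 1L) stats::sd(v) / sqrt(n) else if (n == 1L) 0 else NA_real_,
               sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
               n_pairs = n, n_excluded = excl, defined = n > 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Vectorised CATT + PIC over the per-locus count list from .count_matrix().
# CATT: chi2 = N * r^2 with r the correlation between the allele-dose score
# (SNP: 0/1/2 for reference homozygote / heterozygote / SNP homozygote;
# PA: 0/1 for absent/present) and the binary sex indicator over called
# individuals. PIC = 2p(1-p) with p from allele counting over both sexes.
.locus_stats <- function(cnt, kind) {
  if (kind == "snp") {
    sx_m <- cnt$het_m + 2 * cnt$alt_hom_m
    sx_f <- cnt$het_f + 2 * cnt$alt_hom_f
    sxx_m <- cnt$het_m + 4 * cnt$alt_hom_m
    sxx_f <- cnt$het_f + 4 * cnt$alt_hom_f
    p_ref <- (2 * (cnt$ref_hom_m + cnt$ref_hom_f) + cnt$het_m + cnt$het_f) /
      (2 * pmax(cnt$called_m + cnt$called_f, 1L))
  } else {
    sx_m <- cnt$present_m; sx_f <- cnt$present_f
    sxx_m <- cnt$present_m; sxx_f <- cnt$present_f
    p_ref <- (cnt$present_m + cnt$present_f) /
      pmax(cnt$called_m + cnt$called_f, 1L)
  }
  n <- cnt$called_m + cnt$called_f
  sx <- sx_m + sx_f; sxx <- sxx_m + sxx_f
  sy <- cnt$called_m                      # sex indicator: male = 1
  num <- n * sx_m - sx * sy               # n * Sxy - Sx * Sy
  den <- (n * sxx - sx^2) * (n * sy - sy^2)
  chi2 <- ifelse(den > 0, n * num^2 / den, 0)
  chi2[cnt$called_m == 0L | cnt$called_f == 0L] <- NA_real_
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  list(chi2 = chi2, p = p, pic = 2 * p_ref * (1 - p_ref))
}

#' Cochran-Armitage trend test for one locus
#'
#' Tests for a dose-ordered association between genotype and phenotypic
#' sex. Genotypes are scored by SNP-allele dose: 0 (reference homozygote),
#' 1 (heterozygote), 2 (SNP homozygote); presence/absence loci use scores
#' 0 (absent) / 1 (present). The statistic is \eqn{\chi^2 = N r^2}, where
#' `r` is the correlation between dose score and the binary sex indicator
#' over called individuals, referred to the 1-df chi-square distribution.
#' Under complete separation with complete data the statistic equals `N`
#' exactly.
#'
#' @param counts a `locus_counts` object from [tally_locus()].
#' @return A `trend_test` list: `statistic`, `p_value`, `df = 1`, `scores`,
#'   `n`. With zero called individuals in either sex the statistic is `NA`
#'   and `defined` is `FALSE`.
#' @examples
#' counts <- tally_locus(c(rep("2", 14), rep("0", 15)),
#'                       c(rep("male", 14), rep("female", 15)), "snp")
#' catt(counts)$statistic  # 29: complete separation in 29 individuals
#' @export
catt <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  kind <- counts$type
  cnt <- if (kind == "snp") {
    list(ref_hom_m = counts$male[["ref_hom"]],
         het_m = counts$male[["het"]], alt_hom_m = counts$male[["alt_hom"]],
         ref_hom_f = counts$female[["ref_hom"]],
         het_f = counts$female[["het"]], alt_hom_f = counts$female[["alt_hom"]],
         called_m = counts$male[["called"]],
         called_f = counts$female[["called"]])
  } else {
    list(present_m = counts$male[["present"]],
         present_f = counts$female[["present"]],
         called_m = counts$male[["called"]],
         called_f = counts$female[["called"]])
  }
  s <- .locus_stats(cnt, kind)
  structure(list(statistic = s$chi2, p_value = s$p, df = 1L,
                 scores = if (kind == "snp") c(ref_hom = 0, het = 1, alt_hom = 2)
                          else c(absent = 0, present = 1),
                 n = cnt$called_m + cnt$called_f,
                 defined = !is.na(s$chi2)),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Cochran-Armitage trend test: chi2 = %.4f, df = 1, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Polymorphism information content
#'
#' For a biallelic marker, `PIC = 2p(1-p)`: 0 at fixation of either allele,
#' maximal 0.5 at equal allele frequencies. Given a `locus_counts` object,
#' `p` is estimated by allele counting over called genotypes of both sexes
#' (for presence/absence loci the presence frequency is used as the allele
#' proxy).
#'
#' @param x an allele frequency in `[0, 1]` (vectorised) or a
#'   `locus_counts` object.
#' @return Numeric value(s) in `[0, 0.5]`; `NA` with zero called
#'   individuals.
#' @examples
#' pic(0.5)   # 0.5
#' pic(0.9)   # 0.18
#' @export
pic <- function(x) UseMethod("pic")

#' @export
pic.numeric <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("allele frequency must be in [0, 1]", call. = FALSE)
  2 * x * (1 - x)
}

#' @export
pic.locus_counts <- function(x) {
  called <- x$male[["called"]] + x$female[["called"]]
  if (called == 0L) return(NA_real_)
  p <- if (x$type == "snp") {
    (2 * (x$male[["ref_hom"]] + x$female[["ref_hom"]]) +
       x$male[["het"]] + x$female[["het"]]) / (2 * called)
  } else {
    (x$male[["present"]] + x$female[["present"]]) / called
  }
  2 * p * (1 - p)
}

#' Probability of sex-linkage by chance
#'
#' With `n` individuals genotyped at a locus, the probability that the
#' locus shows a perfectly sex-concordant pattern by chance is
#' \eqn{P_i = 0.5^n}; across `n_loci` screened loci the expected number of
#' spurious sex-linked loci is \eqn{L \cdot P_i}.
#'
#' @param n number of individuals genotyped (>= 1).
#' @param n_loci total number of loci screened (>= 1).
#' @return A `random_linkage` list: `n`, `n_loci`, `p_random` and
#'   `expected`.
#' @examples
#' random_linkage(29, 173144)  # P about 1.86e-9, expected about 3.2e-4
#' @export
random_linkage <- function(n, n_loci) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop("n_loci must be positive", call. = FALSE)
  p <- 0.5^n
  structure(list(n = n, n_loci = n_loci, p_random = p, expected = n_loci * p),
            class = "random_linkage")
}

#' @export
print.random_linkage <- function(x, ...) {
  cat(sprintf("P(sex-linked by chance | n = %d) = %.3g; expected among %s loci = %.3g\n",
              x$n, x$p_random, format(x$n_loci, big.mark = ","), x$expected))
  invisible(x)
}

#' Nemenyi all-pairs post hoc test on ranks
#'
#' Tukey-type all-pairs comparison of mean ranks after a Kruskal-Wallis
#' test, using the studentized range distribution; ties are handled by
#' midranks.
#'
#' @param values numeric vector of observations.
#' @param groups group labels aligned to `values`.
#' @return Symmetric matrix of pairwise p-values with unit diagonal.
#' @export
nemenyi_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups have different lengths", call. = FALSE)
  r <- rank(values)
  n <- length(values)
  k <- nlevels(groups)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  pmat <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      q <- abs(rbar[i] - rbar[j]) /
        sqrt(n * (n + 1) / 12 * (1 / ni[i] + 1 / ni[j]))
      pmat[i, j] <- pmat[j, i] <-
        stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    }
  }
  pmat
}

#' Compare retained-locus sets across filtering criteria
#'
#' Chi-square test over the retained-locus count table, plus a
#' Kruskal-Wallis test on per-locus heterozygosity across criterion groups
#' with a Nemenyi all-pairs post hoc. Groups with zero loci are excluded
#' with a warning.
#'
#' @param counts retained-locus counts: a matrix/table (tested as a
#'   contingency table) or a named vector (goodness of fit against equal
#'   proportions). No continuity correction is applied.
#' @param heterozygosity named list of per-locus heterozygosity values, one
#'   element per criterion group.
#' @return A `criteria_comparison` list: `chisq` (statistic, p), `kruskal`
#'   (statistic, df, p), `nemenyi` (pairwise p matrix) and the group sizes.
#' @export
compare_criteria <- function(counts, heterozygosity) {
  empty <- vapply(heterozygosity, length, 0L) == 0L
  if (any(empty)) {
    warning("excluding groups with zero loci: ",
            paste(names(heterozygosity)[empty], collapse = ", "))
    heterozygosity <- heterozygosity[!empty]
  }
  if (length(heterozygosity) < 2L)
    stop("need at least two non-empty criterion groups", call. = FALSE)
  chi <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  values <- unlist(heterozygosity, use.names = FALSE)
  groups <- factor(rep(names(heterozygosity),
                       vapply(heterozygosity, length, 0L)),
                   levels = names(heterozygosity))
  kw <- stats::kruskal.test(values, groups)
  kw_stat <- unname(kw$statistic)
  kw_p <- kw$p.value
  if (is.nan(kw_stat)) { kw_stat <- 0; kw_p <- 1 }  # all values tied
  structure(list(
    chisq = list(statistic = unname(chi$statistic), p_value = chi$p.value),
    kruskal = list(statistic = kw_stat, df = unname(kw$parameter),
                   p_value = kw_p),
    nemenyi = nemenyi_test(values, groups),
    group_sizes = table(groups)), class = "criteria_comparison")
}

#' Per-locus heterozygosity by criterion group
#'
#' Convenience extractor feeding [compare_criteria()]: for each criterion
#' in a [run_filter()] result, the fraction of called individuals that are
#' heterozygous (SNP) at each retained locus.
#'
#' @param results a `sex_linkage_results` object for SNP markers.
#' @return Named list of numeric vectors.
#' @export
heterozygosity_by_criterion <- function(results) {
  lapply(results, function(r) {
    tab <- r$table
    if (nrow(tab) == 0L || r$marker_type != "snp") return(numeric(0))
    (tab$het_m + tab$het_f) / (tab$called_m + tab$called_f)
  })
}
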