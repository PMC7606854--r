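# Shared fixture builders: everything is generated in code at test time.

# Build a snp_matrix from a list of per-locus call vectors
make_snp <- function(calls_by_locus, samples = NULL, tags = NULL) {
  m <- do.call(rbind, calls_by_locus)
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  snp_matrix(m, tags)
}

make_pa <- function(calls_by_locus, samples = NULL, tags = NULL) {
  m <- do.call(rbind, calls_by_locus)
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  pa_matrix(m, tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulation config for fast tests; override any field
tiny_config <- function(...) {
  defaults <- list(n_males = 14, n_females = 15,
                   n_auto_snp = 60, n_perfect_snp = 4, n_partial_snp = 8,
                   n_auto_pa = 60, n_perfect_pa = 4, n_partial_pa = 8,
                   recomb_fraction = 0.15, missing_rate = 0.05,
                   error_rate = 0.01, seed = 101)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Cohort of 14 males then 15 females, as a sexes data frame
study_sexes <- function(n_males = 14, n_females = 15) {
  data.frame(
    sample_id = c(sprintf("M%02d", seq_len(n_males)),
                  sprintf("F%02d", seq_len(n_females))),
    sex = factor(rep(c("male", "female"), c(n_males, n_females)),
                 levels = c("male", "female")),
    stringsAsFactors = FALSE)
}

sex_vector <- function(n_males, n_females) {
  rep(c("male", "female"), c(n_males, n_females))
}

# locus_counts built directly from per-sex state counts
snp_counts <- function(m_ref = 0, m_het = 0, m_alt = 0, m_miss = 0,
                       f_ref = 0, f_het = 0, f_alt = 0, f_miss = 0) {
  calls <- c(rep(c("0", "2", "1", NA), c(m_ref, m_het, m_alt, m_miss)),
             rep(c("0", "2", "1", NA), c(f_ref, f_het, f_alt, f_miss)))
  sexes <- sex_vector(m_ref + m_het + m_alt + m_miss,
                      f_ref + f_het + f_alt + f_miss)
  tally_locus(calls, sexes, "snp")
}

pa_counts <- function(m_pres = 0, m_abs = 0, m_miss = 0,
                      f_pres = 0, f_abs = 0, f_miss = 0) {
  calls <- c(rep(c("1", "0", NA), c(m_pres, m_abs, m_miss)),
             rep(c("1", "0", NA), c(f_pres, f_abs, f_miss)))
  sexes <- sex_vector(m_pres + m_abs + m_miss, f_pres + f_abs + f_miss)
  tally_locus(calls, sexes, "pa")
}

# Brute-force proportional Hamming distance between two call vectors
brute_hamming <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  if (!any(both)) return(NA_real_)
  sum(x[both] != y[both]) / sum(both)
}

# Independent CATT oracle: chi2 = N * r^2 computed from expanded vectors
brute_catt <- function(counts) {
  if (counts$type == "snp") {
    score_m <- rep(c(0, 1, 2), counts$male[c("ref_hom", "het", "alt_hom")])
    score_f <- rep(c(0, 1, 2), counts$female[c("ref_hom", "het", "alt_hom")])
  } else {
    score_m <- rep(c(1, 0), counts$male[c("present", "absent")])
    score_f <- rep(c(1, 0), counts$female[c("present", "absent")])
  }
  x <- c(score_m, score_f)
  y <- rep(c(1, 0), c(length(score_m), length(score_f)))
  n <- length(x)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  n * stats::cor(x, y)^2
}
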