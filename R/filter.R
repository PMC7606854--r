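# Retention/discard rules for candidate sex-linked loci under XY and ZW
# heterogamety hypotheses at graded stringencies.
#
# XY SNP rule at stringency s (fractions over called individuals of the sex):
#   females: reference-homozygote fraction >= s, SNP-homozygote <= d,
#            heterozygote <= d (d = 0.30 discard bound)
#   males:   heterozygote fraction >= s, reference-homozygote <= 1 - s;
#            SNP-allele homozygosity in males is deliberately unconstrained,
#            because X-Y recombination can fix the SNP allele on some X
#            copies and make males SNP-homozygous.
# XY PA rule: fragment present in >= s of males and absent in >= s of
# females. ZW rules are the exact sex mirror.

# tolerance absorbing float noise in frequency-vs-threshold comparisons;
# comparisons are inclusive ("at least 70%")
.FREQ_EPS <- 1e-9

#' Define a sex-linkage filtering criterion
#'
#' A criterion is a heterogamety hypothesis (`XY` or `ZW`) plus a stringency
#' `s`: the minimum fraction of the heterogametic sex that must show the
#' sex-linked state (and of the homogametic sex that must show the
#' alternative state). `s = 1` defines perfectly sex-linked loci; lower
#' stringencies define moderately sex-linked loci, interpreted as evidence
#' of X-Y (or Z-W) recombination.
#'
#' @param system `"XY"` (male heterogamety) or `"ZW"` (female heterogamety).
#' @param stringency retention threshold in (0.5, 1].
#' @param discard upper bound on the disallowed genotype fractions in the
#'   homogametic sex (SNP rule only); fixed at 0.30 by default.
#' @return A `filter_criterion` object.
#' @seealso [criteria_grid()], [run_filter()]
#' @export
filter_criterion <- function(system = c("XY", "ZW"), stringency,
                             discard = 0.30) {
  system <- match.arg(system)
  if (!is.numeric(stringency) || length(stringency) != 1L ||
      stringency <= 0.5 || stringency > 1)
    stop("stringency must be a single value in (0.5, 1]", call. = FALSE)
  if (!is.numeric(discard) || discard < 0 || discard > 0.5)
    stop("discard bound must be in [0, 0.5]", call. = FALSE)
  structure(list(system = system, stringency = stringency, discard = discard),
            class = "filter_criterion")
}

#' @export
print.filter_criterion <- function(x, ...) {
  cat(criterion_label(x), "\n")
  invisible(x)
}

#' Label for a criterion, e.g. "XY_100" for the 100:0 XY filter
#' @param criterion a [filter_criterion()].
#' @return A character scalar.
#' @export
criterion_label <- function(criterion) {
  sprintf("%s_%d", criterion$system, round(100 * criterion$stringency))
}

#' Build the default criteria grid
#'
#' Both heterogamety hypotheses crossed with the 70:30, 80:20, 90:10 and
#' 100:0 stringencies.
#'
#' @param systems hypotheses to include.
#' @param stringencies stringency levels.
#' @param discard discard bound passed to each criterion.
#' @return A list of [filter_criterion()] objects.
#' @export
criteria_grid <- function(systems = c("XY", "ZW"),
                          stringencies = c(0.70, 0.80, 0.90, 1.00),
                          discard = 0.30) {
  out <- list()
  for (sys in systems)
    for (s in sort(stringencies))
      out[[length(out) + 1L]] <- filter_criterion(sys, s, discard)
  out
}

#' Tally per-sex call-state counts at one locus
#'
#' @param calls character vector of calls for one locus (one per sample,
#'   `NA` = missing).
#' @param sexes character vector of `"male"`/`"female"`, aligned to `calls`.
#' @param type `"snp"` or `"pa"`; inferred from the call alphabet when
#'   possible.
#' @return A `locus_counts` object: per sex, counts of each call state plus
#'   `called` (non-missing) and `missing`.
#' @examples
#' tally_locus(c("2", "2", "0", "0"), c("male", "male", "female", "female"),
#'             type = "snp")
#' @export
tally_locus <- function(calls, sexes, type = c("snp", "pa")) {
  if (length(calls) != length(sexes))
    stop("calls and sexes have different lengths", call. = FALSE)
  type <- match.arg(type)
  states <- if (type == "snp") SNP_STATES else PA_STATES
  tally_sex <- function(v) {
    n <- vapply(states, function(s) sum(v == s, na.rm = TRUE), 0L)
    c(n, called = sum(!is.na(v)), missing = sum(is.na(v)))
  }
  structure(list(type = type,
                 male = tally_sex(calls[sexes == "male"]),
                 female = tally_sex(calls[sexes == "female"])),
            class = "locus_counts")
}

# Per-sex frequency denominator: called individuals (default) or full cohort
.denominator <- function(counts_sex, denominator) {
  if (denominator == "called") counts_sex[["called"]]
  else counts_sex[["called"]] + counts_sex[["missing"]]
}

.classify_status <- function(retained, uncallable) {
  structure(retained,
            status = if (uncallable) "uncallable"
                     else if (retained) "retained" else "rejected")
}

#' Classify one SNP locus against a criterion
#'
#' Applies the codominant retention rule (see the package vignette for the
#' full rule). A locus with fewer than `min_called` called individuals in
#' either sex is never retained and is flagged `"uncallable"` (in the
#' `status` attribute), distinct from an ordinary rejection.
#'
#' @param counts a `locus_counts` object from [tally_locus()].
#' @param criterion a [filter_criterion()].
#' @param denominator `"called"` (frequencies over called individuals of the
#'   sex, the default) or `"cohort"` (over all individuals of the sex).
#' @param min_called minimum called individuals per sex.
#' @return Logical scalar: retained or not, with a `status` attribute in
#'   `{"retained", "rejected", "uncallable"}`.
#' @export
classify_snp_locus <- function(counts, criterion,
                               denominator = c("called", "cohort"),
                               min_called = 1L) {
  stopifnot(inherits(counts, "locus_counts"), counts$type == "snp")
  denominator <- match.arg(denominator)
  if (counts$male[["called"]] < min_called ||
      counts$female[["called"]] < min_called)
    return(.classify_status(FALSE, TRUE))
  # het = heterogametic sex (male under XY, female under ZW)
  if (criterion$system == "XY") {
    het <- counts$male; hom <- counts$female
  } else {
    het <- counts$female; hom <- counts$male
  }
  dh <- .denominator(het, denominator)
  dm <- .denominator(hom, denominator)
  s <- criterion$stringency; d <- criterion$discard; eps <- .FREQ_EPS
  ok <- hom[["ref_hom"]] / dm >= s - eps &&
    hom[["alt_hom"]] / dm <= d + eps &&
    hom[["het"]] / dm <= d + eps &&
    het[["het"]] / dh >= s - eps &&
    het[["ref_hom"]] / dh <= (1 - s) + eps
  .classify_status(ok, FALSE)
}

#' Classify one presence/absence locus against a criterion
#'
#' Retained under XY iff the fragment is present in at least `s` of called
#' males and absent in at least `s` of called females; ZW is the mirror.
#'
#' @inheritParams classify_snp_locus
#' @return As [classify_snp_locus()].
#' @export
classify_pa_locus <- function(counts, criterion,
                              denominator = c("called", "cohort"),
                              min_called = 1L) {
  stopifnot(inherits(counts, "locus_counts"), counts$type == "pa")
  denominator <- match.arg(denominator)
  if (counts$male[["called"]] < min_called ||
      counts$female[["called"]] < min_called)
    return(.classify_status(FALSE, TRUE))
  if (criterion$system == "XY") {
    het <- counts$male; hom <- counts$female
  } else {
    het <- counts$female; hom <- counts$male
  }
  s <- criterion$stringency; eps <- .FREQ_EPS
  ok <- het[["present"]] / .denominator(het, denominator) >= s - eps &&
    hom[["absent"]] / .denominator(hom, denominator) >= s - eps
  .classify_status(ok, FALSE)
}

# Vectorised per-locus, per-sex state counts for a whole matrix.
# Returns a list of integer vectors (one per state and sex) plus called.
.count_matrix <- function(x, sexes) {
  states <- if (marker_kind(x) == "snp") SNP_STATES else PA_STATES
  m <- unclass(x)[, sexes == "male", drop = FALSE]
  f <- unclass(x)[, sexes == "female", drop = FALSE]
  count <- function(block, s) as.integer(rowSums(block == s, na.rm = TRUE))
  out <- list()
  for (nm in names(states)) {
    out[[paste0(nm, "_m")]] <- count(m, states[[nm]])
    out[[paste0(nm, "_f")]] <- count(f, states[[nm]])
  }
  out$called_m <- as.integer(rowSums(!is.na(m)))
  out$called_f <- as.integer(rowSums(!is.na(f)))
  out$cohort_m <- ncol(m)
  out$cohort_f <- ncol(f)
  out
}

# Vectorised retention over all loci for one criterion
.retained_vector <- function(cnt, kind, criterion, denominator) {
  s <- criterion$stringency; d <- criterion$discard; eps <- .FREQ_EPS
  if (denominator == "called") {
    dm <- cnt$called_m; df <- cnt$called_f
  } else {
    dm <- rep(cnt$cohort_m, length(cnt$called_m))
    df <- rep(cnt$cohort_f, length(cnt$called_f))
  }
  xy <- criterion$system == "XY"
  if (kind == "snp") {
    if (xy) {
      hom_ref <- cnt$ref_hom_f / df; hom_alt <- cnt$alt_hom_f / df
      hom_het <- cnt$het_f / df
      het_het <- cnt$het_m / dm; het_ref <- cnt$ref_hom_m / dm
    } else {
      hom_ref <- cnt$ref_hom_m / dm; hom_alt <- cnt$alt_hom_m / dm
      hom_het <- cnt$het_m / dm
      het_het <- cnt$het_f / df; het_ref <- cnt$ref_hom_f / df
    }
    ok <- hom_ref >= s - eps & hom_alt <= d + eps & hom_het <= d + eps &
      het_het >= s - eps & het_ref <= (1 - s) + eps
  } else {
    if (xy) {
      pres_het <- cnt$present_m / dm; abs_hom <- cnt$absent_f / df
    } else {
      pres_het <- cnt$present_f / df; abs_hom <- cnt$absent_m / dm
    }
    ok <- pres_het >= s - eps & abs_hom >= s - eps
  }
  ok & !is.na(ok)
}

#' Run the sex-linkage filter over a call matrix
#'
#' Applies every requested criterion in one pass, attaches the per-locus
#' Cochran-Armitage trend test and polymorphism information content to
#' retained loci, and labels each retained locus perfectly (`s = 1`) or
#' moderately (`s < 1`) sex-linked. Retained sets are nested across
#' stringencies within a system by construction; this is verified after the
#' pass.
#'
#' @param x a [snp_matrix()] or [pa_matrix()].
#' @param sexes sex metadata: either the data frame from
#'   [read_sex_metadata()] (joined by sample id) or a character vector of
#'   `"male"`/`"female"` aligned to the matrix columns.
#' @param criteria list of [filter_criterion()] objects; defaults to the
#'   full [criteria_grid()].
#' @param denominator frequency denominator, `"called"` or `"cohort"`.
#' @param min_called minimum called individuals per sex for a locus to be
#'   classifiable; loci below it are flagged uncallable.
#' @return A `sex_linkage_results` list with one `sex_linkage_result` per
#'   criterion (named by [criterion_label()]), each holding the retained
#'   locus ids, a per-locus table (counts, CATT chi-square and p, PIC,
#'   linkage class) and the uncallable locus ids.
#' @examples
#' sim <- simulate_population(sim_config(n_auto_snp = 50, n_perfect_snp = 3,
#'   n_partial_snp = 0, n_auto_pa = 0, n_perfect_pa = 0, n_partial_pa = 0,
#'   missing_rate = 0, error_rate = 0, seed = 1))
#' res <- run_filter(sim$snp, sim$sexes)
#' res$XY_100$retained
#' @export
run_filter <- function(x, sexes, criteria = criteria_grid(),
                       denominator = c("called", "cohort"), min_called = 1L) {
  stopifnot(inherits(x, "dart_matrix"))
  if (length(criteria) == 0L) stop("empty criteria list", call. = FALSE)
  if (inherits(criteria, "filter_criterion")) criteria <- list(criteria)
  denominator <- match.arg(denominator)
  if (is.data.frame(sexes)) sexes <- align_sexes(x, sexes)
  if (length(sexes) != ncol(x))
    stop("sexes length does not match sample count", call. = FALSE)
  if (!all(sexes %in% c("male", "female")))
    stop("sexes must be \"male\"/\"female\"", call. = FALSE)

  kind <- marker_kind(x)
  cnt <- .count_matrix(x, sexes)
  uncallable <- cnt$called_m < min_called | cnt$called_f < min_called
  loci <- locus_ids(x)

  stats <- .locus_stats(cnt, kind)  # CATT + PIC for every locus, vectorised

  out <- list()
  for (cr in criteria) {
    keep <- .retained_vector(cnt, kind, cr, denominator) & !uncallable
    tab <- data.frame(locus_id = loci[keep], stringsAsFactors = FALSE)
    if (kind == "snp") {
      tab$ref_hom_m <- cnt$ref_hom_m[keep]; tab$het_m <- cnt$het_m[keep]
      tab$alt_hom_m <- cnt$alt_hom_m[keep]
      tab$ref_hom_f <- cnt$ref_hom_f[keep]; tab$het_f <- cnt$het_f[keep]
      tab$alt_hom_f <- cnt$alt_hom_f[keep]
    } else {
      tab$present_m <- cnt$present_m[keep]; tab$absent_m <- cnt$absent_m[keep]
      tab$present_f <- cnt$present_f[keep]; tab$absent_f <- cnt$absent_f[keep]
    }
    tab$called_m <- cnt$called_m[keep]; tab$called_f <- cnt$called_f[keep]
    tab$catt_chi2 <- stats$chi2[keep]
    tab$catt_p <- stats$p[keep]
    tab$catt_p_bonferroni <- pmin(1, stats$p[keep] * length(loci))
    tab$pic <- stats$pic[keep]
    tab$class <- rep(if (cr$stringency >= 1) "perfect" else "moderate",
                     nrow(tab))
    out[[criterion_label(cr)]] <-
      structure(list(criterion = cr, marker_type = kind,
                     retained = loci[keep], table = tab,
                     uncallable = loci[uncallable], n_loci = length(loci)),
                class = "sex_linkage_result")
  }
  .check_nesting(out)
  structure(out, class = "sex_linkage_results", denominator = denominator)
}

# Retained sets must be nested across stringencies within a system; the
# rules are monotone in s, so a violation indicates an implementation bug.
.check_nesting <- function(results) {
  crits <- lapply(results, `[[`, "criterion")
  for (sys in unique(vapply(crits, `[[`, "", "system"))) {
    idx <- which(vapply(crits, `[[`, "", "system") == sys)
    idx <- idx[order(vapply(crits[idx], `[[`, 0, "stringency"),
                     decreasing = TRUE)]
    for (k in seq_along(idx)[-1L]) {
      hi <- results[[idx[k - 1L]]]$retained
      lo <- results[[idx[k]]]$retained
      if (!all(hi %in% lo))
        stop("internal error: retained sets are not nested across ",
             "stringencies for system ", sys, call. = FALSE)
    }
  }
  invisible(results)
}

#' @export
print.sex_linkage_result <- function(x, ...) {
  cat(sprintf("%s filter (%s markers): %d/%d loci retained (%s)\n",
              criterion_label(x$criterion), toupper(x$marker_type),
              length(x$retained), x$n_loci,
              if (x$criterion$stringency >= 1) "perfectly sex-linked"
              else "moderately sex-linked"))
  invisible(x)
}

#' @export
print.sex_linkage_results <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Flatten filter results into one long table
#'
#' @param results a `sex_linkage_results` object from [run_filter()].
#' @return A data frame with one row per retained locus per criterion,
#'   including the criterion label, counts, CATT statistics, PIC and
#'   linkage class.
#' @export
retained_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    tab <- results[[nm]]$table
    if (nrow(tab) == 0L) return(NULL)
    cbind(criterion = nm, marker = results[[nm]]$marker_type, tab,
          stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(criterion = character(), marker = character(),
                      locus_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
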