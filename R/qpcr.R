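# Molecular sexing by qPCR relative gene dosage.
#
# A gene on the X-specific region is present in two copies in females (XX)
# and one in males (XY) when the Y copy is degenerate, so the male:female
# dosage ratio r is expected near 0.5 for X-linked genes and near 1 for
# autosomal or pseudoautosomal genes.

#' Relative gene dosage from crossing points
#'
#' Dosage of a target gene normalised to a reference gene from the same
#' sample: \eqn{R = (2^{Cp_{target}} / 2^{Cp_{reference}})^{-1}
#' = 2^{\bar{Cp}_{ref} - \bar{Cp}_{target}}}. Replicate crossing points are
#' averaged before the difference is taken. Only the Cp difference matters:
#' adding a constant to both means leaves R unchanged.
#'
#' @param cp_target replicate crossing points (cycles) for the target gene.
#' @param cp_reference replicate crossing points for the reference gene.
#' @return Dimensionless dosage R > 0.
#' @examples
#' gene_dosage(21, 20)  # one extra cycle: half the dosage, 0.5
#' @export
gene_dosage <- function(cp_target, cp_reference) {
  for (v in list(cp_target, cp_reference)) {
    if (length(v) == 0L || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("crossing points must be finite positive cycle numbers",
           call. = FALSE)
  }
  2^(mean(cp_reference) - mean(cp_target))
}

#' Exact Mann-Whitney/Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of two independent samples. For combined sample
#' sizes up to `max_exact` the null distribution of the Mann-Whitney U
#' statistic is obtained by full enumeration of all
#' \eqn{\binom{n_x + n_y}{n_x}} rank assignments (midranks under ties), so
#' the p-value is exact even with tied observations. Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param max_exact largest combined size for which full enumeration is
#'   used (default 20).
#' @return A `rank_sum_test` list: `statistic` (U for `x`), `p_value`,
#'   `method`, `n_x`, `n_y`.
#' @examples
#' rank_sum_test(rep(1, 5), rep(2, 5))$p_value  # 2/252
#' @export
rank_sum_test <- function(x, y, max_exact = 20L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mn <- nx * ny
  if (n <= max_exact) {
    sets <- utils::combn(n, nx)
    us <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    lo <- min(u, mn - u); hi <- max(u, mn - u)
    p <- (sum(us <= lo + 1e-9) + sum(us >= hi - 1e-9)) / ncol(sets)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- mn / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mn / 2)
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corrected
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = u, p_value = min(p, 1), method = method,
                 n_x = nx, n_y = ny), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Male:female relative gene dosage ratio
#'
#' \eqn{r = \bar{R}_{male} / \bar{R}_{female}} over per-sample dosages,
#' with a two-sided exact rank-sum test of the male vs female dosage sets.
#' Interpretation: r near 0.5 indicates an X-linked gene degenerate on the
#' Y; r near 1 an autosomal or pseudoautosomal gene.
#'
#' @param male_dosage,female_dosage per-sample dosages R from
#'   [gene_dosage()]; at least one sample per sex, at least two per sex for
#'   the rank test.
#' @return A `dosage_ratio` list: `r`, `statistic` (rank-sum W), `p_value`,
#'   `n_male`, `n_female`.
#' @export
dosage_ratio <- function(male_dosage, female_dosage) {
  if (length(male_dosage) < 1L || length(female_dosage) < 1L)
    stop("need at least one dosage per sex", call. = FALSE)
  fmean <- mean(female_dosage)
  if (fmean == 0) stop("female mean dosage is zero", call. = FALSE)
  r <- mean(male_dosage) / fmean
  w <- p <- NA_real_
  if (length(male_dosage) >= 2L && length(female_dosage) >= 2L) {
    test <- rank_sum_test(male_dosage, female_dosage)
    w <- test$statistic; p <- test$p_value
  }
  structure(list(r = r, statistic = w, p_value = p,
                 n_male = length(male_dosage),
                 n_female = length(female_dosage)),
            class = "dosage_ratio")
}

#' @export
print.dosage_ratio <- function(x, ...) {
  cat(sprintf("relative gene dosage ratio r = %.3f (W = %g, p = %.4g; %d males vs %d females)\n",
              x$r, x$statistic, x$p_value, x$n_male, x$n_female))
  invisible(x)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of mean crossing point against log10 template
#' concentration over a dilution series. Amplification efficiency is
#' \eqn{E = -1 + 10^{-1/slope}}; a perfect-doubling assay (E = 1) has slope
#' \eqn{-1/\log_{10} 2 \approx -3.32}. A non-negative slope flags the curve
#' invalid and leaves E undefined.
#'
#' @param concentration template concentrations (> 0), at least two
#'   distinct values.
#' @param cp mean crossing point per dilution.
#' @return A `standard_curve` list: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `valid`, `n_points`.
#' @examples
#' conc <- 25 / 3^(0:4)
#' cp <- 20 - log2(conc)          # perfect doubling
#' standard_curve(conc, cp)$efficiency  # 1
#' @export
standard_curve <- function(concentration, cp) {
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be positive and finite", call. = FALSE)
  if (length(unique(concentration)) < 2L)
    stop("need at least two distinct concentrations", call. = FALSE)
  if (length(concentration) != length(cp))
    stop("concentration and cp lengths differ", call. = FALSE)
  fit <- stats::lm(cp ~ log10(concentration))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  valid <- is.finite(slope) && slope < 0
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = if (valid) -1 + 10^(-1 / slope) else NA_real_,
                 valid = valid, n_points = length(cp)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope = %.4f, R^2 = %.4f, E = %s (%d points)%s\n",
              x$slope, x$r_squared,
              if (x$valid) sprintf("%.4f", x$efficiency) else "undefined",
              x$n_points, if (x$valid) "" else " [invalid: slope >= 0]"))
  invisible(x)
}

#' Replicate coefficient-of-variation report
#'
#' Intra-assay CV: per sample-gene-plate replicate group, the sample
#' (n-1) standard deviation of the replicate crossing points divided by
#' their mean, times 100. Inter-assay CV: the same ratio over the per-plate
#' means of each sample-gene combination run on multiple plates.
#' Acceptance gates follow common qPCR practice: intra-assay CV < 10%,
#' inter-assay CV < 15%.
#'
#' @param plate data frame with columns `sample`, `gene`, `plate`,
#'   `replicate`, `cp` (see [simulate_qpcr_plate()] / [read_qpcr_plate()]).
#' @param intra_gate,inter_gate CV acceptance thresholds in percent.
#' @return A `cv_report` list with data frames `intra` (per replicate
#'   group: `mean_cp`, `sd_cp`, `cv`, `n`, `pass`) and `inter` (per
#'   sample-gene: `cv`, `n_plates`, `pass`). Groups with fewer than two
#'   replicates (or plates) get `NA` CV and `NA` pass.
#' @export
assay_cv <- function(plate, intra_gate = 10, inter_gate = 15) {
  need <- c("sample", "gene", "plate", "cp")
  if (!all(need %in% names(plate)))
    stop("plate data need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cv_of <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / m
  }
  grp <- interaction(plate$sample, plate$gene, plate$plate, drop = TRUE)
  intra <- do.call(rbind, lapply(split(plate, grp), function(g) {
    data.frame(sample = g$sample[1L], gene = g$gene[1L], plate = g$plate[1L],
               mean_cp = mean(g$cp), sd_cp = if (nrow(g) > 1L) stats::sd(g$cp) else NA_real_,
               cv = cv_of(g$cp), n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(intra) <- NULL
  intra$pass <- ifelse(is.na(intra$cv), NA, intra$cv < intra_gate)

  grp2 <- interaction(intra$sample, intra$gene, drop = TRUE)
  inter <- do.call(rbind, lapply(split(intra, grp2), function(g) {
    data.frame(sample = g$sample[1L], gene = g$gene[1L],
               cv = cv_of(g$mean_cp), n_plates = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(inter) <- NULL
  inter$pass <- ifelse(is.na(inter$cv), NA, inter$cv < inter_gate)

  structure(list(intra = intra, inter = inter,
                 gates = c(intra = intra_gate, inter = inter_gate)),
            class = "cv_report")
}

#' Read a qPCR plate table
#'
#' Long-format CSV with one row per replicate well: columns `sample`,
#' `sex` (optional), `gene`, `role` (`target`/`reference`), `plate`,
#' `replicate`, `cp`.
#'
#' @param path path to the CSV file.
#' @return Data frame with validated columns.
#' @export
read_qpcr_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "role", "plate", "replicate", "cp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qPCR plate file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$role %in% c("target", "reference")))
    stop("role must be \"target\" or \"reference\"", call. = FALSE)
  df$cp <- as.numeric(df$cp)
  if (any(!is.finite(df$cp)) || any(df$cp <= 0))
    stop("crossing points must be finite and positive", call. = FALSE)
  df
}

#' Per-sample dosages and sex-wise ratios from a plate table
#'
#' Convenience wrapper: averages replicate crossing points per sample and
#' gene, computes per-sample dosage of each target gene against the
#' reference gene on the same plate, and (when a `sex` column is present)
#' the male:female dosage ratio with its rank-sum test per target gene.
#'
#' @param plate plate data frame (see [read_qpcr_plate()]).
#' @return A list with `dosages` (data frame: sample, gene, plate, R) and,
#'   when sexes are available, `ratios` (one [dosage_ratio()] per target
#'   gene).
#' @export
plate_dosages <- function(plate) {
  ref <- plate[plate$role == "reference", , drop = FALSE]
  tgt <- plate[plate$role == "target", , drop = FALSE]
  if (nrow(ref) == 0L) stop("no reference gene in plate", call. = FALSE)
  rows <- list()
  grp <- interaction(tgt$sample, tgt$gene, tgt$plate, drop = TRUE)
  for (g in split(tgt, grp)) {
    rmatch <- ref[ref$sample == g$sample[1L] & ref$plate == g$plate[1L], ]
    if (nrow(rmatch) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample = g$sample[1L], gene = g$gene[1L], plate = g$plate[1L],
      sex = if ("sex" %in% names(g)) g$sex[1L] else NA_character_,
      R = gene_dosage(g$cp, rmatch$cp), stringsAsFactors = FALSE)
  }
  dosages <- do.call(rbind, rows)
  out <- list(dosages = dosages)
  if (!all(is.na(dosages$sex))) {
    out$ratios <- lapply(split(dosages, dosages$gene), function(d) {
      dosage_ratio(d$R[d$sex == "male"], d$R[d$sex == "female"])
    })
  }
  out
}
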