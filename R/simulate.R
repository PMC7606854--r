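# Synthetic genotype matrices and qPCR plates with known ground truth.
#
# The generator emulates the data regime the filter assumes: a cohort of
# known-sex individuals genotyped at loci of three classes:
#   autosomal           Hardy-Weinberg draws, identical in both sexes
#   perfect_sex_linked  reference allele fixed on the X (Z), SNP allele on
#                       the Y (W): every male heterozygous, every female
#                       reference-homozygous under XY (PA: fragment present
#                       in every male, absent in every female)
#   partial_sex_linked  as perfect, but each heterogametic individual's Y
#                       (W) haplotype carries the X-type (Z-type) state with
#                       probability rho, emulating X-Y recombination
# Missingness is applied first, then genotyping error, independently per
# call; an erroneous call is replaced by a uniform draw from the other
# valid call states.

.check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop("invalid ", field, ": must be a non-negative integer", call. = FALSE)
  as.integer(x)
}

.check_prob <- function(x, field, closed_top = TRUE) {
  top_ok <- if (closed_top) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !top_ok)
    stop("invalid ", field, ": must be a probability in [0, ",
         if (closed_top) "1]" else "1)", call. = FALSE)
  as.numeric(x)
}

#' Simulation configuration
#'
#' Defines a simulated study: cohort sizes, number of loci per class and
#' marker kind, the recombination fraction at partially sex-linked loci,
#' missingness and genotyping error rates, the autosomal allele-frequency
#' range, and the heterogamety system. Defaults describe a cohort of 14
#' males and 15 females genotyped at 20,000 loci (10,000 SNP + 10,000 PA)
#' dominated by autosomal loci with small planted sex-linked classes; see
#' the package vignette for the rationale behind each default.
#'
#' @param n_males,n_females cohort sizes (each >= 2).
#' @param n_auto_snp,n_perfect_snp,n_partial_snp SNP locus counts per class.
#' @param n_auto_pa,n_perfect_pa,n_partial_pa PA locus counts per class.
#' @param recomb_fraction probability in `[0, 1]` that the Y (W) haplotype
#'   of a heterogametic individual carries the X-type (Z-type) state at a
#'   partially sex-linked locus.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param error_rate per-call error probability in `[0, 1)`.
#' @param allele_freq_range interval within (0, 1) from which each
#'   autosomal locus draws its reference-allele (or presence-allele)
#'   frequency.
#' @param system `"XY"` (male heterogamety) or `"ZW"` (the exact
#'   sex-mirrored construction).
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @seealso [simulate_population()], [sim_config_from_yaml()]
#' @export
sim_config <- function(n_males = 14, n_females = 15,
                       n_auto_snp = 9800, n_perfect_snp = 5,
                       n_partial_snp = 195,
                       n_auto_pa = 9770, n_perfect_pa = 30,
                       n_partial_pa = 200,
                       recomb_fraction = 0.15,
                       missing_rate = 0.05, error_rate = 0.01,
                       allele_freq_range = c(0.3, 0.7),
                       system = c("XY", "ZW"), seed = 1L) {
  system <- match.arg(system)
  n_males <- .check_count(n_males, "n_males")
  n_females <- .check_count(n_females, "n_females")
  if (n_males < 2L) stop("invalid n_males: need at least 2", call. = FALSE)
  if (n_females < 2L) stop("invalid n_females: need at least 2", call. = FALSE)
  counts <- list(n_auto_snp = n_auto_snp, n_perfect_snp = n_perfect_snp,
                 n_partial_snp = n_partial_snp, n_auto_pa = n_auto_pa,
                 n_perfect_pa = n_perfect_pa, n_partial_pa = n_partial_pa)
  counts <- mapply(.check_count, counts, names(counts), SIMPLIFY = FALSE)
  if (sum(unlist(counts)) < 1L)
    stop("invalid locus counts: need at least one locus in total",
         call. = FALSE)
  recomb_fraction <- .check_prob(recomb_fraction, "recomb_fraction")
  missing_rate <- .check_prob(missing_rate, "missing_rate", closed_top = FALSE)
  error_rate <- .check_prob(error_rate, "error_rate", closed_top = FALSE)
  if (!is.numeric(allele_freq_range) || length(allele_freq_range) != 2L ||
      any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
      allele_freq_range[1L] > allele_freq_range[2L])
    stop("invalid allele_freq_range: must be an increasing interval within (0, 1)",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    stop("invalid seed: must be an integer", call. = FALSE)
  structure(c(list(n_males = n_males, n_females = n_females), counts,
              list(recomb_fraction = recomb_fraction,
                   missing_rate = missing_rate, error_rate = error_rate,
                   allele_freq_range = as.numeric(allele_freq_range),
                   system = system, seed = as.integer(seed))),
            class = "sim_config")
}

#' Load a simulation configuration from a YAML file
#'
#' Flat key-value YAML with the same field names as [sim_config()];
#' unspecified fields take the defaults.
#'
#' @param path path to the YAML file.
#' @return A `sim_config` list.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

# uniform draw from the other valid call states
.corrupt_calls <- function(calls, states, error_rate) {
  err <- !is.na(calls) & stats::runif(length(calls)) < error_rate
  if (any(err)) {
    cur <- calls[err]
    calls[err] <- vapply(cur, function(s) sample(setdiff(states, s), 1L), "")
  }
  calls
}

.random_tags <- function(n, len = 69L) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

#' Simulate a genotyped population with known sex-linkage ground truth
#'
#' Generates a codominant SNP matrix, a dominant presence/absence matrix,
#' the sample sex list and a truth table mapping every locus to its
#' simulated class. Under `system = "XY"` the heterogametic sex is male;
#' `"ZW"` is the exact sex mirror. See the file header comments and the
#' vignette for the locus-class construction. All randomness flows from a
#' single generator stream seeded with `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list: `snp` ([snp_matrix()] with 69 bp tags), `pa`
#'   ([pa_matrix()] with tags), `sexes` (data frame `sample_id`, `sex`) and
#'   `truth` (data frame `locus_id`, `kind`, `class`, `recomb_fraction`).
#' @examples
#' sim <- simulate_population(sim_config(n_auto_snp = 20, n_perfect_snp = 2,
#'   n_partial_snp = 0, n_auto_pa = 0, n_perfect_pa = 0, n_partial_pa = 0,
#'   missing_rate = 0, error_rate = 0, seed = 42))
#' table(sim$truth$class)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_males; nf <- config$n_females
  samples <- c(sprintf("M%02d", seq_len(nm)), sprintf("F%02d", seq_len(nf)))
  sex <- c(rep("male", nm), rep("female", nf))
  # heterogametic individuals carry the Y (XY) or W (ZW)
  het_idx <- if (config$system == "XY") which(sex == "male") else
    which(sex == "female")
  hom_idx <- setdiff(seq_along(sex), het_idx)
  n <- length(sex)
  rho <- config$recomb_fraction
  fr <- config$allele_freq_range

  sim_snp <- function(n_auto, n_perfect, n_partial) {
    total <- n_auto + n_perfect + n_partial
    calls <- matrix(NA_character_, total, n)
    classes <- rep(c("autosomal", "perfect_sex_linked", "partial_sex_linked"),
                   c(n_auto, n_perfect, n_partial))
    row <- 0L
    for (i in seq_len(n_auto)) {
      p <- stats::runif(1L, fr[1L], fr[2L])   # reference-allele frequency
      row <- row + 1L
      calls[row, ] <- sample(c("0", "2", "1"), n, replace = TRUE,
                             prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
    }
    for (i in seq_len(n_perfect)) {
      row <- row + 1L
      calls[row, het_idx] <- "2"; calls[row, hom_idx] <- "0"
    }
    for (i in seq_len(n_partial)) {
      row <- row + 1L
      recomb <- stats::runif(length(het_idx)) < rho
      calls[row, het_idx] <- ifelse(recomb, "0", "2")
      calls[row, hom_idx] <- "0"
    }
    list(calls = calls, classes = classes)
  }

  sim_pa <- function(n_auto, n_perfect, n_partial) {
    total <- n_auto + n_perfect + n_partial
    calls <- matrix(NA_character_, total, n)
    classes <- rep(c("autosomal", "perfect_sex_linked", "partial_sex_linked"),
                   c(n_auto, n_perfect, n_partial))
    row <- 0L
    for (i in seq_len(n_auto)) {
      q <- stats::runif(1L, fr[1L], fr[2L])   # presence-allele frequency
      row <- row + 1L
      # dominant scoring: present when at least one presence allele carried
      calls[row, ] <- ifelse(stats::runif(n) < 1 - (1 - q)^2, "1", "0")
    }
    for (i in seq_len(n_perfect)) {
      row <- row + 1L
      calls[row, het_idx] <- "1"; calls[row, hom_idx] <- "0"
    }
    for (i in seq_len(n_partial)) {
      row <- row + 1L
      recomb <- stats::runif(length(het_idx)) < rho
      calls[row, het_idx] <- ifelse(recomb, "0", "1")
      calls[row, hom_idx] <- "0"
    }
    list(calls = calls, classes = classes)
  }

  apply_noise <- function(calls, states) {
    if (length(calls) == 0L) return(calls)
    miss <- stats::runif(length(calls)) < config$missing_rate
    calls[miss] <- NA_character_
    .corrupt_calls(calls, states, config$error_rate)
  }

  snp <- sim_snp(config$n_auto_snp, config$n_perfect_snp, config$n_partial_snp)
  pa <- sim_pa(config$n_auto_pa, config$n_perfect_pa, config$n_partial_pa)
  snp$calls <- apply_noise(snp$calls, unname(SNP_STATES))
  pa$calls <- apply_noise(pa$calls, unname(PA_STATES))

  snp_ids <- sprintf("SNP_%05d", seq_len(nrow(snp$calls)))
  pa_ids <- sprintf("PA_%05d", seq_len(nrow(pa$calls)))
  dimnames(snp$calls) <- list(snp_ids, samples)
  dimnames(pa$calls) <- list(pa_ids, samples)
  snp_tags <- .random_tags(nrow(snp$calls))
  pa_tags <- .random_tags(nrow(pa$calls))

  truth <- data.frame(
    locus_id = c(snp_ids, pa_ids),
    kind = rep(c("snp", "pa"), c(length(snp_ids), length(pa_ids))),
    class = c(snp$classes, pa$classes),
    stringsAsFactors = FALSE)
  truth$recomb_fraction <- ifelse(truth$class == "partial_sex_linked", rho, 0)

  list(snp = if (nrow(snp$calls)) snp_matrix(snp$calls, snp_tags) else NULL,
       pa = if (nrow(pa$calls)) pa_matrix(pa$calls, pa_tags) else NULL,
       sexes = data.frame(sample_id = samples,
                          sex = factor(sex, levels = c("male", "female")),
                          stringsAsFactors = FALSE),
       truth = truth,
       config = config)
}

#' Write the simulation truth table
#' @param truth truth data frame from [simulate_population()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate qPCR plates with known dosage ground truth
#'
#' Crossing points are generated as
#' \eqn{Cp = intercept - \log_2(copy \times conc) / \log_2(1 + E) +
#' N(0, noise\_sd)}. X-linked genes give males half the female copy number
#' (1 vs 2); autosomal genes give both sexes two copies. An optional
#' dilution series (reference copy number 2) supports standard-curve
#' fitting: its expected slope is \eqn{-1/\log_{10}(1 + E)}.
#'
#' @param n_males,n_females samples per sex.
#' @param genes data frame with columns `gene`, `role`
#'   (`target`/`reference`) and `linkage` (`x_linked`/`autosomal`);
#'   defaults to one X-linked target and one autosomal reference.
#' @param efficiency amplification efficiency E in (0, 3], recycled per
#'   gene.
#' @param noise_sd standard deviation (cycles) of replicate noise, >= 0.
#' @param n_plates,n_replicates plate and replicate structure.
#' @param dilution `NULL`, or a list `list(start =, fold =, n = )`
#'   describing a serial dilution (needs `n >= 2` points, positive
#'   concentrations).
#' @param intercept baseline Cp at copy 1, concentration 1.
#' @param concentration template concentration of the samples (> 0).
#' @param seed integer seed.
#' @return A list: `plate` (long data frame `sample`, `sex`, `gene`,
#'   `role`, `plate`, `replicate`, `cp`), `standards` (per-gene dilution
#'   data frame or `NULL`) and `truth` (per-gene copy ratio and
#'   efficiency).
#' @examples
#' sim <- simulate_qpcr_plate(noise_sd = 0, seed = 1)
#' plate_dosages(sim$plate)$ratios$SEXL1$r  # 0.5: X-linked gene
#' @export
simulate_qpcr_plate <- function(n_males = 5, n_females = 5,
                                genes = data.frame(
                                  gene = c("SEXL1", "GAPDH"),
                                  role = c("target", "reference"),
                                  linkage = c("x_linked", "autosomal"),
                                  stringsAsFactors = FALSE),
                                efficiency = 1, noise_sd = 0.15,
                                n_plates = 1L, n_replicates = 3L,
                                dilution = NULL, intercept = 30,
                                concentration = 1, seed = 1L) {
  if (any(efficiency <= 0) || any(efficiency > 3))
    stop("efficiency must be in (0, 3]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  if (!all(c("gene", "role", "linkage") %in% names(genes)))
    stop("genes need columns gene, role, linkage", call. = FALSE)
  if (!is.null(dilution)) {
    if (!all(c("start", "fold", "n") %in% names(dilution)))
      stop("dilution needs fields start, fold, n", call. = FALSE)
    if (dilution$n < 2L)
      stop("dilution series needs at least 2 points", call. = FALSE)
    if (dilution$start <= 0 || dilution$fold <= 1)
      stop("dilution start must be positive and fold > 1", call. = FALSE)
  }
  set.seed(seed)
  eff <- rep_len(efficiency, nrow(genes))
  samples <- c(sprintf("M%02d", seq_len(n_males)),
               sprintf("F%02d", seq_len(n_females)))
  sex <- rep(c("male", "female"), c(n_males, n_females))
  copies <- function(linkage, sex) {
    ifelse(linkage == "x_linked" & sex == "male", 1, 2)
  }
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      plate = seq_len(n_plates),
                      gene_i = seq_len(nrow(genes)),
                      sample_i = seq_along(samples))
  cp_mean <- intercept -
    log2(copies(genes$linkage[rows$gene_i], sex[rows$sample_i]) *
           concentration) / log2(1 + eff[rows$gene_i])
  plate <- data.frame(sample = samples[rows$sample_i],
                      sex = sex[rows$sample_i],
                      gene = genes$gene[rows$gene_i],
                      role = genes$role[rows$gene_i],
                      plate = rows$plate, replicate = rows$replicate,
                      cp = cp_mean + stats::rnorm(nrow(rows), 0, noise_sd),
                      stringsAsFactors = FALSE)
  standards <- NULL
  if (!is.null(dilution)) {
    conc <- dilution$start / dilution$fold^(seq_len(dilution$n) - 1L)
    standards <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      data.frame(gene = genes$gene[i], concentration = conc,
                 cp = intercept - log2(2 * conc) / log2(1 + eff[i]) +
                   stats::rnorm(length(conc), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- data.frame(gene = genes$gene, role = genes$role,
                      linkage = genes$linkage, efficiency = eff,
                      copy_ratio_m_f = ifelse(genes$linkage == "x_linked",
                                              0.5, 1),
                      stringsAsFactors = FALSE)
  list(plate = plate, standards = standards, truth = truth)
}
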