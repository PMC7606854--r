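# End-to-end orchestration: simulate or load reports, filter under both
# heterogamety hypotheses at all stringencies, compute summary statistics,
# and write the report artifacts.

#' Build a pipeline run configuration
#'
#' Exactly one input source must be active: either a [sim_config()]
#' (`simulation`) or report paths (`snp_report`, `pa_report`,
#' `sex_metadata`; the two marker reports are individually optional but at
#' least one is required).
#'
#' @param out_dir output directory (created if absent).
#' @param simulation optional [sim_config()].
#' @param snp_report,pa_report,sex_metadata input file paths.
#' @param criteria list of [filter_criterion()]s, default the full
#'   [criteria_grid()].
#' @param denominator `"called"` or `"cohort"` frequency denominators.
#' @param min_called minimum called individuals per sex per locus.
#' @param seed integer seed controlling any randomness in the run (for a
#'   simulation input it overrides the seed in `simulation` when given).
#' @param verbose print progress.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, simulation = NULL, snp_report = NULL,
                       pa_report = NULL, sex_metadata = NULL,
                       criteria = criteria_grid(),
                       denominator = c("called", "cohort"),
                       min_called = 1L, seed = NULL, verbose = TRUE) {
  denominator <- match.arg(denominator)
  has_sim <- !is.null(simulation)
  has_files <- !is.null(snp_report) || !is.null(pa_report)
  if (has_sim == has_files)
    stop("exactly one of simulation or input report paths must be given",
         call. = FALSE)
  if (has_files && is.null(sex_metadata))
    stop("report inputs need sex_metadata", call. = FALSE)
  if (has_sim) stopifnot(inherits(simulation, "sim_config"))
  structure(list(out_dir = out_dir, simulation = simulation,
                 snp_report = snp_report, pa_report = pa_report,
                 sex_metadata = sex_metadata, criteria = criteria,
                 denominator = denominator, min_called = min_called,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full sex-linkage discovery pipeline
#'
#' Simulates or loads the marker matrices, applies every criterion under
#' both heterogamety hypotheses, computes per-criterion distance summaries
#' and the random sex-linkage estimate, and writes all artifacts to
#' `config$out_dir`: the retained-locus table, a long-format
#' (heatmap-ready) pairwise distance table and a FASTA of retained tags
#' for criteria with retained loci, the random-linkage estimate, a
#' criteria-by-marker summary table, and a plain-text log. Runs are
#' reproducible from the config and seed; partial outputs are removed if
#' the run fails.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list: `summary` (the criteria-by-marker
#'   table), `snp_results`/`pa_results` ([run_filter()] outputs),
#'   `distances` (per criterion and marker kind), `random_linkage`,
#'   `retained` (long table) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$files <- character(0)
  state$log <- character(0)
  note <- function(...) if (config$verbose) message(...)
  logit <- function(...) state$log <- c(state$log, sprintf(...))
  emit <- function(path) state$files <- c(state$files, path)

  tryCatch(.run_pipeline_impl(config, state, note, logit, emit),
           error = function(e) {
             unlink(state$files)
             stop("pipeline failed (partial outputs removed): ",
                  conditionMessage(e), call. = FALSE)
           })
}

.run_pipeline_impl <- function(config, state, note, logit, emit) {
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    if (!is.null(config$seed)) sim_cfg$seed <- as.integer(config$seed)
    note("simulating population (seed ", sim_cfg$seed, ")")
    sim <- simulate_population(sim_cfg)
    snp <- sim$snp; pa <- sim$pa; sexes <- sim$sexes
    logit("input: simulation (system %s, seed %d)", sim_cfg$system,
          sim_cfg$seed)
    if (!is.null(snp)) {
      p <- file.path(config$out_dir, "simulated_snp_report.csv")
      write_snp_report(snp, p); emit(p)
    }
    if (!is.null(pa)) {
      p <- file.path(config$out_dir, "simulated_silicodart_report.csv")
      write_silicodart_report(pa, p); emit(p)
    }
    p <- file.path(config$out_dir, "simulated_sex_metadata.csv")
    write_sex_metadata(sexes, p); emit(p)
    p <- file.path(config$out_dir, "truth_table.tsv")
    write_truth_table(sim$truth, p); emit(p)
  } else {
    sexes <- read_sex_metadata(config$sex_metadata)
    snp <- if (!is.null(config$snp_report))
      read_snp_report(config$snp_report) else NULL
    pa <- if (!is.null(config$pa_report))
      read_silicodart_report(config$pa_report) else NULL
    logit("input: snp=%s pa=%s sexes=%s",
          config$snp_report %||% "-", config$pa_report %||% "-",
          config$sex_metadata)
  }

  n_samples <- nrow(sexes)
  total_loci <- sum(if (!is.null(snp)) nrow(snp) else 0L,
                    if (!is.null(pa)) nrow(pa) else 0L)
  logit("cohort: %d samples (%d male, %d female)", n_samples,
        sum(sexes$sex == "male"), sum(sexes$sex == "female"))
  logit("loci: %d total", total_loci)

  filt <- function(x, kind) {
    if (is.null(x)) return(NULL)
    note("filtering ", kind, " loci (", nrow(x), ")")
    run_filter(x, sexes, config$criteria, config$denominator,
               config$min_called)
  }
  snp_res <- filt(snp, "SNP")
  pa_res <- filt(pa, "PA")

  distances <- list()
  for (set in list(list(res = snp_res, mat = snp, kind = "snp"),
                   list(res = pa_res, mat = pa, kind = "pa"))) {
    if (is.null(set$res)) next
    for (nm in names(set$res)) {
      r <- set$res[[nm]]
      logit("%s %s: %d retained", nm, set$kind, length(r$retained))
      if (length(r$retained) == 0L) next
      sub <- subset_loci(set$mat, r$retained)
      d <- hamming_matrix(sub)
      distances[[paste(nm, set$kind, sep = "_")]] <-
        summarize_distances(d, align_sexes(sub, sexes))
      long <- data.frame(sample_i = rep(colnames(d), each = ncol(d)),
                         sample_j = rep(colnames(d), times = ncol(d)),
                         distance = as.vector(d),
                         stringsAsFactors = FALSE)
      p <- file.path(config$out_dir,
                     sprintf("distances_%s_%s.tsv", nm, set$kind))
      .write_tsv(long, p); emit(p)
      if (!is.null(tag_sequences(set$mat))) {
        p <- file.path(config$out_dir,
                       sprintf("retained_%s_%s.fasta", nm, set$kind))
        export_retained_fasta(r, set$mat, p); emit(p)
      }
    }
  }

  keep_cols <- c("criterion", "marker", "locus_id", "called_m", "called_f",
                 "catt_chi2", "catt_p", "pic", "class")
  pick <- function(res) {
    if (is.null(res)) return(NULL)
    tab <- retained_table(res)
    if (nrow(tab) == 0L) return(NULL)
    tab[keep_cols]
  }
  retained <- rbind(pick(snp_res), pick(pa_res))
  if (is.null(retained))
    retained <- data.frame(criterion = character(), marker = character(),
                           locus_id = character(), stringsAsFactors = FALSE)
  p <- file.path(config$out_dir, "retained_loci.tsv")
  .write_tsv(retained, p); emit(p)

  rl <- random_linkage(n_samples, total_loci)
  p <- file.path(config$out_dir, "random_linkage.tsv")
  .write_tsv(data.frame(n_individuals = rl$n, n_loci = rl$n_loci,
                        p_random = rl$p_random, expected = rl$expected), p)
  emit(p)

  summary_tab <- render_summary(snp_res, pa_res, distances)
  p <- file.path(config$out_dir, "summary.tsv")
  utils::write.table(summary_tab, p, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  emit(p)

  p <- file.path(config$out_dir, "run_log.txt")
  writeLines(state$log, p); emit(p)

  structure(list(summary = summary_tab, snp_results = snp_res,
                 pa_results = pa_res, distances = distances,
                 random_linkage = rl, retained = retained,
                 files = state$files),
            class = "pipeline_result")
}

#' Render the criteria-by-marker summary table
#'
#' A table in the layout of the study-report summaries: rows are total
#' loci, sex-specific (retained) loci, the PIC range over retained loci,
#' and the mean between-sex, within-female and within-male Hamming
#' distances (mean +/- standard error); columns are criterion x marker
#' kind. Undefined cells (no retained loci, or a group without pairs) are
#' rendered `"-"`.
#'
#' @param snp_results,pa_results [run_filter()] outputs (either may be
#'   `NULL`).
#' @param distances named list of [summarize_distances()] outputs, keyed
#'   `<criterion>_<kind>` (as produced by [run_pipeline()]).
#' @return A character data frame, rows as above.
#' @export
render_summary <- function(snp_results, pa_results, distances = list()) {
  crits <- names(snp_results) %||% names(pa_results)
  if (is.null(crits)) stop("no criterion evaluated", call. = FALSE)
  cols <- list()
  for (nm in crits) {
    for (set in list(list(res = snp_results, kind = "snp"),
                     list(res = pa_results, kind = "pa"))) {
      if (is.null(set$res) || is.null(set$res[[nm]])) next
      r <- set$res[[nm]]
      tab <- r$table
      dsum <- distances[[paste(nm, set$kind, sep = "_")]]
      cell <- function(group) {
        if (is.null(dsum)) return("-")
        row <- dsum[dsum$group == group, ]
        if (!row$defined) return("-")
        sprintf("%.3f ± %.3f", row$mean, row$se)
      }
      cols[[paste(nm, toupper(set$kind), sep = "_")]] <- c(
        total_loci = as.character(r$n_loci),
        sex_specific_loci = as.character(length(r$retained)),
        pic_range = if (nrow(tab)) sprintf("%.2f-%.2f", min(tab$pic),
                                           max(tab$pic)) else "-",
        dist_between = cell("between"),
        dist_within_female = cell("within_female"),
        dist_within_male = cell("within_male"))
    }
  }
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("sex-linkage pipeline run\n")
  print(x$random_linkage)
  print(x$summary)
  invisible(x)
}
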