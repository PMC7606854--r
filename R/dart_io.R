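# Readers and writers for DArT-style one-row reports and sex metadata.
#
# Layout of a one-row report: first column = locus id, an optional tag
# sequence column (recognised by name), remaining columns = one call per
# sample. Real exports differ in how they spell a missing call, so "-",
# the Unicode minus, "NA" and the empty cell are all normalised to NA.

MISSING_TOKENS <- c("-", "−", "NA", "")
TAG_COLUMN_NAMES <- c("allelesequence", "tagsequence", "sequence",
                      "tag_sequence", "trimmedsequence")

.read_dart <- function(path, states, what, sep, missing_tokens, tag_column) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("report needs a locus id column and at least one sample column",
         call. = FALSE)
  loci <- raw[[1L]]
  if (anyDuplicated(loci))
    stop("duplicate locus id in ", path, ": ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "),
         call. = FALSE)
  cols <- names(raw)[-1L]
  if (is.null(tag_column)) {
    hit <- cols[tolower(cols) %in% TAG_COLUMN_NAMES]
    tag_column <- if (length(hit)) hit[1L] else NA_character_
  }
  tags <- NULL
  if (!is.na(tag_column)) {
    if (!tag_column %in% cols)
      stop("tag column \"", tag_column, "\" not present in ", path,
           call. = FALSE)
    tags <- raw[[tag_column]]
    tags[tags == ""] <- NA_character_
    cols <- setdiff(cols, tag_column)
  }
  calls <- as.matrix(raw[cols])
  rownames(calls) <- loci
  calls[calls %in% missing_tokens] <- NA_character_
  bad <- !is.na(calls) & !(calls %in% states)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("unknown ", what, " call token \"", calls[bad][1L], "\" in ", path,
         " at locus ", loci[idx[1L]], " (row ", idx[1L] + 1L, "), sample ",
         cols[idx[2L]], call. = FALSE)
  }
  list(calls = calls, tags = tags)
}

#' Read a DArT-style one-row SNP report
#'
#' Parses a CSV genotype report with loci as rows and samples as columns,
#' enforcing the codominant coding (`"0"` reference homozygote, `"1"` SNP
#' homozygote, `"2"` heterozygote). Missing calls may be written `"-"`,
#' the Unicode minus sign, `"NA"` or an empty cell; all are normalised to
#' `NA`. A tag sequence column is picked up automatically when named in a
#' recognised way (e.g. `AlleleSequence`, `TagSequence`).
#'
#' @param path path to the CSV report.
#' @param sep field delimiter, `","` by default.
#' @param missing_tokens tokens interpreted as a missing call.
#' @param tag_column name of the tag sequence column; `NULL` (default)
#'   auto-detects, `NA` disables tag parsing.
#' @return A [snp_matrix()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("locus,s1,s2", "L1,0,2", "L2,1,-"), f)
#' read_snp_report(f)
#' @export
read_snp_report <- function(path, sep = ",", missing_tokens = MISSING_TOKENS,
                            tag_column = NULL) {
  parsed <- .read_dart(path, SNP_STATES, "SNP", sep, missing_tokens, tag_column)
  snp_matrix(parsed$calls, parsed$tags)
}

#' Read a SilicoDArT-style presence/absence report
#'
#' As [read_snp_report()], with the dominant three-state alphabet: `"1"`
#' present, `"0"` absent, missing tokens normalised to `NA`.
#'
#' @inheritParams read_snp_report
#' @return A [pa_matrix()].
#' @export
read_silicodart_report <- function(path, sep = ",",
                                   missing_tokens = MISSING_TOKENS,
                                   tag_column = NULL) {
  parsed <- .read_dart(path, PA_STATES, "PA", sep, missing_tokens, tag_column)
  pa_matrix(parsed$calls, parsed$tags)
}

.write_dart <- function(x, path, sep, missing) {
  df <- data.frame(locus = rownames(x), stringsAsFactors = FALSE,
                   check.names = FALSE)
  tags <- attr(x, "tags")
  if (!is.null(tags)) df[["TagSequence"]] <- unname(tags)
  calls <- unclass(x)
  calls[is.na(calls)] <- missing
  df <- cbind(df, as.data.frame(calls, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write DArT-style reports
#'
#' Emit the same CSV dialect consumed by [read_snp_report()] /
#' [read_silicodart_report()]; `write(read(x))` round-trips call fields
#' byte-for-byte.
#'
#' @param x a [snp_matrix()] or [pa_matrix()].
#' @param path output path.
#' @param sep field delimiter.
#' @param missing token used for missing calls.
#' @return The path, invisibly.
#' @export
write_snp_report <- function(x, path, sep = ",", missing = "-") {
  stopifnot(inherits(x, "snp_matrix"))
  .write_dart(x, path, sep, missing)
}

#' @rdname write_snp_report
#' @export
write_silicodart_report <- function(x, path, sep = ",", missing = "-") {
  stopifnot(inherits(x, "pa_matrix"))
  .write_dart(x, path, sep, missing)
}

#' Read phenotypic sex metadata
#'
#' Reads a two-column table (sample id, sex). Sex tokens are matched
#' case-insensitively against `male_tokens` and `female_tokens`. A header
#' row is detected by checking whether the second field of the first row is
#' itself a valid sex token.
#'
#' @param path path to the CSV file.
#' @param sep field delimiter.
#' @param male_tokens,female_tokens accepted spellings for each sex.
#' @return A data frame with columns `sample_id` and `sex`
#'   (factor, levels `male`, `female`), in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("s1,M", "s2,F"), f)
#' read_sex_metadata(f)
#' @export
read_sex_metadata <- function(path, sep = ",",
                              male_tokens = c("m", "male"),
                              female_tokens = c("f", "female")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, header = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("sex metadata needs two columns (sample id, sex)", call. = FALSE)
  tokens <- c(tolower(male_tokens), tolower(female_tokens))
  if (nrow(raw) > 0L && !(tolower(raw[1L, 2L]) %in% tokens))
    raw <- raw[-1L, , drop = FALSE]  # header row
  if (nrow(raw) == 0L) stop("no samples in ", path, call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  tok <- tolower(raw[[2L]])
  unknown <- !(tok %in% tokens)
  if (any(unknown))
    stop("unknown sex token \"", raw[[2L]][unknown][1L], "\" for sample ",
         ids[unknown][1L], call. = FALSE)
  sex <- ifelse(tok %in% tolower(male_tokens), "male", "female")
  data.frame(sample_id = ids, sex = factor(sex, levels = c("male", "female")),
             stringsAsFactors = FALSE)
}

#' Write sex metadata in the dialect read by [read_sex_metadata()]
#' @param sexes data frame with `sample_id` and `sex` columns.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sex_metadata <- function(sexes, path) {
  tok <- ifelse(as.character(sexes$sex) == "male", "M", "F")
  utils::write.table(data.frame(sexes$sample_id, tok), path, sep = ",",
                     row.names = FALSE, col.names = c("sample_id", "sex"),
                     quote = FALSE)
  invisible(path)
}

#' Align sex metadata to a call matrix
#'
#' Joins by exact sample id. Every matrix sample must appear in the
#' metadata (error otherwise); metadata samples absent from the matrix
#' trigger a warning and are dropped.
#'
#' @param x a [snp_matrix()] or [pa_matrix()].
#' @param sexes data frame from [read_sex_metadata()].
#' @return Character vector of `"male"`/`"female"`, one per matrix sample,
#'   in matrix column order.
#' @export
align_sexes <- function(x, sexes) {
  ids <- sample_ids(x)
  miss <- setdiff(ids, sexes$sample_id)
  if (length(miss))
    stop("samples in matrix without sex metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(sexes$sample_id, ids)
  if (length(extra))
    warning("sex metadata for samples absent from matrix: ",
            paste(extra, collapse = ", "), call. = FALSE)
  as.character(sexes$sex)[match(ids, sexes$sample_id)]
}

#' Export tag sequences of retained loci as FASTA
#'
#' Writes one FASTA record per retained locus, identified as
#' `<locus id>|<criterion label>`, ready for downstream homology searches.
#' Loci without a tag sequence are skipped with a warning. Zero retained
#' loci produce an empty file.
#'
#' @param result a single-criterion element of a [run_filter()] result.
#' @param x the call matrix the filter was run on (supplies tag sequences).
#' @param path output FASTA path.
#' @return Number of records written, invisibly.
#' @export
export_retained_fasta <- function(result, x, path) {
  stopifnot(inherits(result, "sex_linkage_result"))
  tags <- tag_sequences(x)
  loci <- result$retained
  if (length(loci) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  if (is.null(tags)) {
    warning("matrix has no tag sequences; no FASTA records written")
    file.create(path)
    return(invisible(0L))
  }
  have <- loci[!is.na(tags[loci])]
  skipped <- setdiff(loci, have)
  if (length(skipped))
    warning("skipping loci without tag sequence: ",
            paste(skipped, collapse = ", "))
  if (length(have) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  label <- criterion_label(result$criterion)
  seqinr::write.fasta(as.list(tags[have]),
                      names = paste(have, label, sep = "|"),
                      file.out = path, nbchar = 80)
  invisible(length(have))
}
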