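# Call containers for DArT-style marker matrices.
#
# Both marker kinds are stored as character matrices (loci as rows, samples
# as columns) with missing calls as NA:
#   SNP (codominant): "0" reference-allele homozygote, "1" SNP-allele
#   homozygote, "2" heterozygote.
#   PA (dominant, SilicoDArT): "1" fragment present, "0" fragment absent.

SNP_STATES <- c(ref_hom = "0", alt_hom = "1", het = "2")
PA_STATES <- c(present = "1", absent = "0")

# IUPAC nucleotide alphabet accepted in tag sequences
IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

.check_call_matrix <- function(calls, states, what) {
  if (!is.matrix(calls) || !is.character(calls))
    stop(what, " calls must be a character matrix", call. = FALSE)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop(what, " call matrix needs locus row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(calls)))
    stop("duplicate locus ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "), call. = FALSE)
  bad <- !is.na(calls) & !(calls %in% states)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid ", what, " call \"", calls[bad][1L], "\" at locus ",
         rownames(calls)[idx[1L]], ", sample ", colnames(calls)[idx[2L]],
         call. = FALSE)
  }
  invisible(calls)
}

.check_tags <- function(tags, n_loci) {
  if (length(tags) != n_loci)
    stop("tag_sequence length (", length(tags),
         ") does not match locus count (", n_loci, ")", call. = FALSE)
  seen <- tags[!is.na(tags)]
  if (length(seen)) {
    letters_seen <- unique(strsplit(paste(toupper(seen), collapse = ""), "")[[1L]])
    bad <- setdiff(letters_seen, IUPAC_LETTERS)
    if (length(bad))
      stop("tag sequences contain non-IUPAC characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(tags)
}

#' Construct a codominant SNP call matrix
#'
#' Builds the loci-by-samples container for DArT-style SNP genotype reports.
#' Calls use the one-row report coding: `"0"` reference-allele homozygote,
#' `"1"` SNP-allele homozygote, `"2"` heterozygote, and `NA` for a missing
#' (null/null) call.
#'
#' @param calls character matrix of calls, loci as rows (row names are locus
#'   ids), samples as columns (column names are sample ids).
#' @param tags optional character vector of sequence tags (one per locus,
#'   IUPAC letters; DArT tags are typically 69 bp). `NA` entries are allowed.
#' @return A `snp_matrix` object (character matrix with a `tags` attribute).
#' @seealso [pa_matrix()], [read_snp_report()]
#' @examples
#' calls <- matrix(c("0", "2", "1", NA), 2, 2,
#'                 dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' snp_matrix(calls)
#' @export
snp_matrix <- function(calls, tags = NULL) {
  .check_call_matrix(calls, SNP_STATES, "SNP")
  if (!is.null(tags)) {
    .check_tags(tags, nrow(calls))
    names(tags) <- rownames(calls)
  }
  structure(calls, tags = tags, class = c("snp_matrix", "dart_matrix",
                                          "matrix", "array"))
}

#' Construct a dominant presence/absence call matrix
#'
#' Container for SilicoDArT-style restriction-fragment presence/absence
#' reports: `"1"` present, `"0"` absent, `NA` missing.
#'
#' @inheritParams snp_matrix
#' @return A `pa_matrix` object.
#' @seealso [snp_matrix()], [read_silicodart_report()]
#' @export
pa_matrix <- function(calls, tags = NULL) {
  .check_call_matrix(calls, PA_STATES, "PA")
  if (!is.null(tags)) {
    .check_tags(tags, nrow(calls))
    names(tags) <- rownames(calls)
  }
  structure(calls, tags = tags, class = c("pa_matrix", "dart_matrix",
                                          "matrix", "array"))
}

#' @export
print.dart_matrix <- function(x, ...) {
  kind <- if (inherits(x, "snp_matrix")) "SNP" else "presence/absence"
  cat(sprintf("%s call matrix: %d loci x %d samples (%.1f%% missing%s)\n",
              kind, nrow(x), ncol(x), 100 * mean(is.na(x)),
              if (is.null(attr(x, "tags"))) "" else ", with tag sequences"))
  invisible(x)
}

#' Locus, sample and tag accessors
#'
#' @param x a [snp_matrix()] or [pa_matrix()].
#' @return `locus_ids()` and `sample_ids()` return character vectors;
#'   `tag_sequences()` returns the per-locus tag vector or `NULL`.
#' @export
locus_ids <- function(x) rownames(x)

#' @rdname locus_ids
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname locus_ids
#' @export
tag_sequences <- function(x) attr(x, "tags")

# Marker kind of a dart matrix ("snp" or "pa")
marker_kind <- function(x) {
  if (inherits(x, "snp_matrix")) "snp"
  else if (inherits(x, "pa_matrix")) "pa"
  else stop("not a dart matrix", call. = FALSE)
}

#' Subset a call matrix by locus id, keeping class and tags aligned
#'
#' @param x a [snp_matrix()] or [pa_matrix()].
#' @param loci locus ids (or row indices) to keep.
#' @return A matrix of the same class restricted to `loci`.
#' @export
subset_loci <- function(x, loci) {
  tags <- attr(x, "tags")
  out <- unclass(x)[loci, , drop = FALSE]
  if (!is.null(tags)) tags <- tags[rownames(out)]
  if (inherits(x, "snp_matrix")) snp_matrix(out, tags) else pa_matrix(out, tags)
}
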