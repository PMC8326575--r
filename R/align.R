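# Pairwise local alignment: the coverage/identity contract shared by
# reference assignment and de novo clustering.

#' Alignment scoring parameters
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open -5, gap extend -2.
#' A gap of length L scores `gap_open + L * gap_extend` (existence plus
#' per-base extension), so the first gap column costs 7 under the defaults.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch penalty.
#' @param gap_open Non-positive gap existence penalty.
#' @param gap_extend Negative per-base gap extension penalty.
#' @return A list of scoring parameters, class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                          gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be positive")
  if (mismatch >= 0L || gap_extend >= 0L || gap_open > 0L) {
    stop("mismatch and gap penalties must be negative (gap_open <= 0)")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

check_seq <- function(x, what) {
  if (length(x) == 0 || any(!nzchar(x))) stop(what, " sequence must be non-empty")
  if (any(grepl("[^ACGT]", x))) stop(what, " sequence must be over ACGT")
  invisible(x)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment with affine gaps under `scoring`. Percent
#' identity is `100 * matches / alignment_columns` with gap columns counted;
#' query coverage is `100 * (q_end - q_start + 1) / query length`. Ties are
#' broken deterministically (earliest best-scoring end cell, fixed traceback
#' preference), so identical inputs always give identical alignments.
#'
#' @param query,subject Non-empty ACGT strings.
#' @param scoring An [align_scoring()] object.
#' @param query_id,subject_id Identifiers copied into the hit.
#' @return A one-row data frame: `query_id`, `subject_id`, `score`,
#'   `identity`, `coverage`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `matches`, `columns`.
#' @examples
#' align_pair("ACGTACGTAC", "ACGTACGTAC")$identity  # 100
#' @export
align_pair <- function(query, subject, scoring = align_scoring(),
                       query_id = "query", subject_id = "subject") {
  check_seq(query, "query"); check_seq(subject, "subject")
  r <- .sw_pair_cpp(toupper(query), toupper(subject), scoring$match,
                    scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  data.frame(query_id = query_id, subject_id = subject_id,
             score = r$score, identity = r$identity, coverage = r$coverage,
             q_start = r$q_start, q_end = r$q_end,
             s_start = r$s_start, s_end = r$s_end,
             matches = r$matches, columns = r$columns,
             stringsAsFactors = FALSE)
}

#' All-against-all local alignment statistics
#'
#' Aligns every query against every subject and returns score, identity and
#' coverage matrices (queries in rows). This is the batch engine behind
#' taxon assignment and clustering.
#'
#' @param queries,subjects Character vectors of ACGT sequences.
#' @param scoring An [align_scoring()] object.
#' @return A list of numeric matrices `score`, `identity`, `coverage`.
#' @export
align_batch <- function(queries, subjects, scoring = align_scoring()) {
  check_seq(queries, "query"); check_seq(subjects, "subject")
  out <- .sw_batch_cpp(toupper(queries), toupper(subjects), scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  for (k in seq_along(out)) {
    dimnames(out[[k]]) <- list(names(queries), names(subjects))
  }
  out
}

#' Dual acceptance criterion on an alignment hit
#'
#' `TRUE` when query coverage and percent identity both reach their
#' thresholds; bounds are inclusive, so coverage exactly 80 with identity
#' exactly 97 passes under the defaults.
#'
#' @param coverage,identity Numeric vectors (percent).
#' @param min_cov Minimum query coverage, percent (default 80).
#' @param min_id Minimum percent identity (default 97).
#' @return Logical vector.
#' @export
passes_criteria <- function(coverage, identity, min_cov = 80, min_id = 97) {
  coverage >= min_cov & identity >= min_id
}

#' Export alignment hits as a BLAST outfmt-6-like table
#'
#' @param hits A data frame of hits as returned by [align_pair()] (rows can
#'   be concatenated).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits[, c("query_id", "subject_id", "identity", "coverage", "score")]
  names(out) <- c("qseqid", "sseqid", "pident", "qcovs", "score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
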