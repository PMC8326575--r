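# Assignment of QC-passed reads to known reference taxa under the dual
# coverage >= 80% / identity >= 97% criterion.

best_passing_hit <- function(score, identity, coverage, accession,
                             min_cov, min_id) {
  ok <- which(passes_criteria(coverage, identity, min_cov, min_id))
  if (length(ok) == 0) return(NA_integer_)
  ord <- order(-score[ok], -identity[ok], accession[ok], method = "radix")
  ok[ord[1]]
}

#' Assign one read to a known reference taxon
#'
#' The read is aligned against every reference; among hits that satisfy the
#' dual criterion the highest-scoring one wins, with ties broken by higher
#' identity and then by lexicographically smallest accession. When no hit
#' passes, the read is routed to the de novo pool.
#'
#' @param bases Read sequence (ACGT string).
#' @param ref_db A reference data frame ([reference_db()]); must be
#'   non-empty.
#' @param scoring An [align_scoring()] object.
#' @param min_cov,min_id Dual-criterion thresholds (percent).
#' @param read_id Identifier copied into the result.
#' @return A one-row data frame: `read_id`, `kind` (`"known"` or
#'   `"de_novo_pool"`), `taxon_label`, `accession`, `score`, `identity`,
#'   `coverage`.
#' @export
assign_known <- function(bases, ref_db, scoring = align_scoring(),
                         min_cov = 80, min_id = 97, read_id = "read") {
  if (nrow(ref_db) == 0) stop("reference database is empty")
  ab <- align_batch(bases, ref_db$bases, scoring)
  i <- best_passing_hit(ab$score[1, ], ab$identity[1, ], ab$coverage[1, ],
                        ref_db$accession, min_cov, min_id)
  if (is.na(i)) {
    data.frame(read_id = read_id, kind = "de_novo_pool", taxon_label = "",
               accession = NA_character_, score = NA_real_,
               identity = NA_real_, coverage = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = read_id, kind = "known",
               taxon_label = lineage_label(ref_db$family[i], ref_db$genus[i],
                                           ref_db$species[i], ref_db$status[i]),
               accession = ref_db$accession[i], score = ab$score[1, i],
               identity = ab$identity[1, i], coverage = ab$coverage[1, i],
               stringsAsFactors = FALSE)
  }
}

#' Assign all reads and tabulate known-taxon counts per sample
#'
#' Reads with identical sequences are aligned once and share the resulting
#' assignment. Every read lands in exactly one of the known-count table or
#' the de novo pool, so counts are conserved. References that share a
#' lineage label pool into a single taxon row.
#'
#' @param reads A read data frame with the `sample` column filled.
#' @param ref_db A non-empty reference data frame.
#' @param scoring An [align_scoring()] object.
#' @param min_cov,min_id Dual-criterion thresholds (percent).
#' @param samples Optional character vector fixing the column order of the
#'   count table; defaults to the samples present in `reads`.
#' @return A list with `assignments` (one row per read), `known_counts`
#'   (integer matrix, taxon labels x samples) and `pool` (the unassigned
#'   reads, a read data frame).
#' @export
assign_all <- function(reads, ref_db, scoring = align_scoring(),
                       min_cov = 80, min_id = 97, samples = NULL) {
  if (nrow(ref_db) == 0) stop("reference database is empty")
  if (is.null(samples)) samples <- unique(reads$sample)
  ub <- unique(reads$bases)
  labels <- lineage_label(ref_db$family, ref_db$genus, ref_db$species,
                          ref_db$status)
  if (length(ub)) {
    ab <- align_batch(ub, ref_db$bases, scoring)
    pick <- integer(length(ub))
    for (i in seq_along(ub)) {
      pick[i] <- best_passing_hit(ab$score[i, ], ab$identity[i, ],
                                  ab$coverage[i, ], ref_db$accession,
                                  min_cov, min_id)
    }
  } else {
    pick <- integer(0)
  }
  m <- match(reads$bases, ub)
  hit <- pick[m]
  known <- !is.na(hit)
  score_v <- identity_v <- coverage_v <- rep(NA_real_, nrow(reads))
  if (any(known)) {
    idx <- cbind(m[known], hit[known])
    score_v[known] <- ab$score[idx]
    identity_v[known] <- ab$identity[idx]
    coverage_v[known] <- ab$coverage[idx]
  }
  assignments <- data.frame(
    read_id = reads$read_id, sample = reads$sample,
    kind = ifelse(known, "known", "de_novo_pool"),
    taxon_label = ifelse(known, labels[hit], ""),
    accession = ifelse(known, ref_db$accession[hit], NA_character_),
    score = score_v, identity = identity_v, coverage = coverage_v,
    stringsAsFactors = FALSE)
  taxa <- sort(unique(assignments$taxon_label[known]))
  known_counts <- matrix(0L, nrow = length(taxa), ncol = length(samples),
                         dimnames = list(taxa, samples))
  if (length(taxa)) {
    tb <- table(factor(assignments$taxon_label[known], levels = taxa),
                factor(assignments$sample[known], levels = samples))
    known_counts[] <- as.integer(tb)
  }
  list(assignments = assignments,
       known_counts = known_counts,
       pool = reads[!known, , drop = FALSE])
}
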