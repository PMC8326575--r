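# Greedy de novo clustering of reads that failed reference assignment,
# under the same dual coverage/identity criterion.

#' Collapse exact-duplicate sequences
#'
#' Sequences are uppercased before comparison. Multiplicities sum to the
#' input size.
#'
#' @param bases Character vector of sequences.
#' @param read_ids Optional identifiers parallel to `bases`; defaults to
#'   positional ids.
#' @return A data frame with `sequence`, `multiplicity` and a list column
#'   `read_ids`, in order of first appearance.
#' @export
dereplicate <- function(bases, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- as.character(seq_along(bases))
  b <- toupper(bases)
  first <- !duplicated(b)
  uniq <- b[first]
  grp <- match(b, uniq)
  ids <- split(read_ids, grp)
  df <- data.frame(sequence = uniq,
                   multiplicity = as.integer(tabulate(grp, length(uniq))),
                   stringsAsFactors = FALSE)
  df$read_ids <- ids[as.character(seq_along(uniq))]
  df
}

# Content-based processing order: decreasing multiplicity, then decreasing
# length, then lexicographic sequence. Makes clustering invariant to the
# input read order.
derep_order <- function(derep) {
  order(-derep$multiplicity, -nchar(derep$sequence), derep$sequence,
        method = "radix")
}

#' Cluster pooled reads into de novo taxa
#'
#' Greedy centroid clustering (UCLUST-style): unique sequences are processed
#' in a content-based order (decreasing multiplicity, then decreasing
#' length, then lexicographic), and each sequence joins the first existing
#' centroid it passes the dual criterion against (the member is the
#' alignment query, the centroid the subject); otherwise it founds a new
#' centroid. Clusters are named `"de novo_<k>"` in founding order. With
#' `method = "single"` the pairwise pass/fail graph (an edge when either
#' direction passes) is built instead and clusters are its connected
#' components, numbered by the same content order of their first member.
#'
#' @param pool A read data frame ([reads_frame()]) of unassigned reads.
#' @param scoring An [align_scoring()] object.
#' @param min_cov,min_id Dual-criterion thresholds (percent).
#' @param method `"centroid"` (default) or `"single"` (single linkage).
#' @return A data frame with one row per cluster: `name`,
#'   `centroid_read_id`, `sequence` (centroid sequence), `n_reads`, and a
#'   list column `member_read_ids`.
#' @export
cluster_denovo <- function(pool, scoring = align_scoring(), min_cov = 80,
                           min_id = 97, method = c("centroid", "single")) {
  method <- match.arg(method)
  derep <- dereplicate(pool$bases, pool$read_id)
  ord <- derep_order(derep)
  derep <- derep[ord, , drop = FALSE]
  n <- nrow(derep)
  if (n == 0) {
    out <- data.frame(name = character(), centroid_read_id = character(),
                      sequence = character(), n_reads = integer(),
                      stringsAsFactors = FALSE)
    out$member_read_ids <- list()
    return(out)
  }
  if (method == "centroid") {
    cluster_of <- integer(n)
    centroid_idx <- integer(0)
    for (i in seq_len(n)) {
      joined <- FALSE
      if (length(centroid_idx)) {
        ab <- align_batch(derep$sequence[i], derep$sequence[centroid_idx],
                          scoring)
        ok <- which(passes_criteria(ab$coverage[1, ], ab$identity[1, ],
                                    min_cov, min_id))
        if (length(ok)) {
          cluster_of[i] <- ok[1]
          joined <- TRUE
        }
      }
      if (!joined) {
        centroid_idx <- c(centroid_idx, i)
        cluster_of[i] <- length(centroid_idx)
      }
    }
  } else {
    # single linkage on the symmetrized pass graph, via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ab <- align_batch(derep$sequence, derep$sequence, scoring)
    pass <- passes_criteria(ab$coverage, ab$identity, min_cov, min_id)
    pass <- pass | t(pass)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (pass[i, j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    centroid_idx <- sort(unique(roots))
    cluster_of <- match(roots, centroid_idx)
  }
  k <- length(centroid_idx)
  members <- vector("list", k)
  sizes <- integer(k)
  for (c in seq_len(k)) {
    sel <- which(cluster_of == c)
    members[[c]] <- unlist(derep$read_ids[sel], use.names = FALSE)
    sizes[c] <- sum(derep$multiplicity[sel])
  }
  out <- data.frame(
    name = paste0("de novo_", seq_len(k)),
    centroid_read_id = vapply(derep$read_ids[centroid_idx],
                              `[`, character(1), 1L),
    sequence = derep$sequence[centroid_idx],
    n_reads = sizes, stringsAsFactors = FALSE)
  out$member_read_ids <- members
  out
}

#' Annotate de novo clusters against a local labeled database
#'
#' Each centroid is aligned against the labeled database (a local annotated
#' stand-in for a public nucleotide database); the best hit that satisfies
#' the annotation thresholds provides the label and lineage, otherwise the
#' cluster falls back to `"uncultured Glomeromycota"`. The default identity
#' threshold (90) is looser than the assignment criterion because
#' annotation aims at genus-level naming, not species identity.
#'
#' @param clusters A cluster data frame from [cluster_denovo()].
#' @param labeled_db A reference data frame ([reference_db()]); may be
#'   empty, in which case every cluster gets the fallback label.
#' @param scoring An [align_scoring()] object.
#' @param min_cov,min_id Annotation thresholds (percent).
#' @param fallback Label used when no hit passes.
#' @return `clusters` with added columns `label`, `family`, `genus`,
#'   `species`, `label_status`.
#' @export
annotate_denovo <- function(clusters, labeled_db, scoring = align_scoring(),
                            min_cov = 80, min_id = 90,
                            fallback = "uncultured Glomeromycota") {
  k <- nrow(clusters)
  clusters$label <- rep(fallback, k)
  clusters$family <- clusters$genus <- clusters$species <- rep("", k)
  clusters$label_status <- rep("unlabeled", k)
  if (k == 0 || nrow(labeled_db) == 0) return(clusters)
  ab <- align_batch(clusters$sequence, labeled_db$bases, scoring)
  for (i in seq_len(k)) {
    j <- best_passing_hit(ab$score[i, ], ab$identity[i, ], ab$coverage[i, ],
                          labeled_db$accession, min_cov, min_id)
    if (!is.na(j)) {
      clusters$label[i] <- lineage_label(labeled_db$family[j],
                                         labeled_db$genus[j],
                                         labeled_db$species[j],
                                         labeled_db$status[j])
      clusters$family[i] <- labeled_db$family[j]
      clusters$genus[i] <- labeled_db$genus[j]
      clusters$species[i] <- labeled_db$species[j]
      clusters$label_status <- replace(clusters$label_status, i,
                                       labeled_db$status[j])
    }
  }
  clusters
}

#' Tabulate de novo cluster counts per sample
#'
#' @param clusters A cluster data frame from [cluster_denovo()].
#' @param reads The pooled read data frame the clusters were built from
#'   (supplies the read-to-sample mapping).
#' @param samples Optional character vector fixing column order.
#' @return Integer matrix, clusters x samples.
#' @export
cluster_counts <- function(clusters, reads, samples = NULL) {
  if (is.null(samples)) samples <- unique(reads$sample)
  sample_of <- setNames(reads$sample, reads$read_id)
  counts <- matrix(0L, nrow = nrow(clusters), ncol = length(samples),
                   dimnames = list(clusters$name, samples))
  for (i in seq_len(nrow(clusters))) {
    tb <- table(factor(sample_of[clusters$member_read_ids[[i]]],
                       levels = samples))
    counts[i, ] <- as.integer(tb)
  }
  counts
}
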