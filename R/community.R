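# Abundance tables: rarefaction, presence/median filters, Venn regions and
# the taxonomic rollup.

#' Construct a taxon-by-sample abundance table
#'
#' The central community container: a non-negative integer count matrix with
#' one row per taxon (known reference taxa and/or de novo clusters) and one
#' column per sample, together with taxon lineages and the sample design.
#'
#' @param counts Integer matrix, taxa x samples; non-negative.
#' @param taxa Data frame with columns `name`, `family`, `genus`, `species`,
#'   `origin` (`"known"` or `"de_novo"`); `name` must be unique and match
#'   `rownames(counts)`.
#' @param samples Design data frame with columns `sample_id`, `soil`,
#'   `time`, `replicate` matching `colnames(counts)`.
#' @param flagged Logical per sample: `TRUE` for columns whose total was
#'   below the rarefaction depth and were left unchanged.
#' @return An object of class `amf_table`.
#' @export
abundance_table <- function(counts, taxa, samples,
                            flagged = rep(FALSE, ncol(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (anyDuplicated(taxa$name)) stop("taxa names must be unique")
  if (nrow(counts) != nrow(taxa)) stop("counts rows must match taxa")
  if (ncol(counts) != nrow(samples)) stop("counts columns must match samples")
  if (is.null(rownames(counts))) rownames(counts) <- taxa$name
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  stopifnot(identical(rownames(counts), as.character(taxa$name)),
            identical(colnames(counts), as.character(samples$sample_id)))
  if (!"origin" %in% names(taxa)) taxa$origin <- "known"
  structure(list(counts = counts, taxa = taxa, samples = samples,
                 flagged = as.logical(flagged)),
            class = "amf_table")
}

#' @export
print.amf_table <- function(x, ...) {
  cat(sprintf("AMF abundance table: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  known: %d  de novo: %d  below-depth samples: %d\n",
              sum(x$taxa$origin == "known"), sum(x$taxa$origin == "de_novo"),
              sum(x$flagged)))
  invisible(x)
}

#' Combine known-taxon and de novo counts into one abundance table
#'
#' @param known_counts Integer matrix from [assign_all()] (taxon labels x
#'   samples).
#' @param ref_db The reference data frame the labels came from (supplies
#'   lineages; the first reference carrying each label is used).
#' @param denovo_counts Optional integer matrix from [cluster_counts()].
#' @param clusters Optional annotated cluster data frame
#'   ([annotate_denovo()]) supplying de novo lineages.
#' @param samples Design data frame; its `sample_id` order defines the
#'   columns.
#' @return An `amf_table`.
#' @export
build_table <- function(known_counts, ref_db, denovo_counts = NULL,
                        clusters = NULL, samples = amf_design()) {
  ref_labels <- lineage_label(ref_db$family, ref_db$genus, ref_db$species,
                              ref_db$status)
  ktax <- rownames(known_counts)
  li <- match(ktax, ref_labels)
  taxa <- data.frame(name = ktax,
                     family = ifelse(is.na(li), "", ref_db$family[li]),
                     genus = ifelse(is.na(li), "", ref_db$genus[li]),
                     species = ifelse(is.na(li), "", ref_db$species[li]),
                     origin = rep("known", length(ktax)),
                     stringsAsFactors = FALSE)
  counts <- known_counts[, samples$sample_id, drop = FALSE]
  if (!is.null(denovo_counts) && nrow(denovo_counts) > 0) {
    stopifnot(!is.null(clusters),
              identical(rownames(denovo_counts), clusters$name))
    dtaxa <- data.frame(name = clusters$name, family = clusters$family,
                        genus = clusters$genus, species = clusters$species,
                        origin = rep("de_novo", nrow(clusters)),
                        stringsAsFactors = FALSE)
    dtaxa$label <- clusters$label
    taxa$label <- taxa$name
    taxa <- rbind(taxa, dtaxa)
    counts <- rbind(counts, denovo_counts[, samples$sample_id, drop = FALSE])
  } else {
    taxa$label <- taxa$name
  }
  rownames(counts) <- taxa$name
  abundance_table(counts, taxa, samples)
}

group_columns <- function(x, soil, time) {
  sel <- x$samples$soil == soil & x$samples$time == time
  if (!any(sel)) stop("no samples for group ", soil, " ", time)
  which(sel)
}

#' Rarefy an abundance table to a fixed depth
#'
#' Each sample column is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Columns whose total is below
#' the depth are left unchanged and flagged rather than dropped, matching
#' the retention of under-sequenced replicates in the study design.
#'
#' @param x An `amf_table`.
#' @param depth Target depth (default 8000 reads).
#' @param seed Optional integer seed for reproducible subsampling.
#' @return A rarefied `amf_table` with `flagged` marking below-depth
#'   samples.
#' @export
rarefy <- function(x, depth = 8000, seed = NULL) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  counts <- x$counts
  flagged <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    total <- sum(counts[, j])
    if (total < depth) {
      flagged[j] <- TRUE
    } else if (total > depth) {
      pool <- rep.int(seq_len(nrow(counts)), counts[, j])
      keep <- pool[sample.int(length(pool), depth)]
      counts[, j] <- tabulate(keep, nbins = nrow(counts))
    }
  }
  abundance_table(counts, x$taxa, x$samples, flagged)
}

#' Taxa present in a sample group under the minimum-read rule
#'
#' A taxon counts as present in a (soil, time) group when it has at least
#' `min_reads` reads in at least one of the group's replicates; a taxon
#' present in several replicates is still counted once.
#'
#' @param x An `amf_table`.
#' @param soil,time Group selectors (`"Bs"`/`"Rs"`, `"1S"`/`"2S"`).
#' @param min_reads Presence threshold per replicate (default 10).
#' @return Character vector of taxon names.
#' @export
present_taxa <- function(x, soil, time, min_reads = 10) {
  cols <- group_columns(x, soil, time)
  hit <- apply(x$counts[, cols, drop = FALSE] >= min_reads, 1, any)
  rownames(x$counts)[hit]
}

#' Exclusive Venn regions of 2-4 named sets
#'
#' @param sets A named list of 2 to 4 character vectors.
#' @return A named list mapping each exclusive region (names joined by
#'   `"&"`) to its member set; region sizes sum to the union size.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_regions supports 2 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    sel <- apply(member, 1, function(r) all(r == inset))
    out[[paste(names(sets)[inset], collapse = "&")]] <- universe[sel]
  }
  out
}

#' Taxa with positive median abundance within a group
#'
#' A taxon is retained when the median of its counts over the group's
#' replicates is greater than zero (for the 5-replicate design the median
#' is the third order statistic; with an even number of replicates the
#' midpoint rule applies).
#'
#' @param x An `amf_table`.
#' @param soil,time Group selectors.
#' @return Character vector of taxon names.
#' @export
median_filter <- function(x, soil, time) {
  cols <- group_columns(x, soil, time)
  med <- apply(x$counts[, cols, drop = FALSE], 1, median)
  rownames(x$counts)[med > 0]
}

rollup_bin <- function(family, genus, species) {
  ifelse(nzchar(species), species,
         ifelse(nzchar(genus), genus,
                ifelse(nzchar(family), family, "Glomeromycota (unresolved)")))
}

#' Roll presence sets up to taxonomic groups
#'
#' For each sample group, the supplied taxa (typically the output of
#' [present_taxa()] or [median_filter()]) are binned by their most specific
#' non-empty rank (species, else genus, else family, else an unresolved
#' Glomeromycota bin) and the number of taxa per bin is counted; known and
#' de novo taxa can be tallied jointly or separately.
#'
#' @param x An `amf_table` (supplies lineages and origins).
#' @param groups A named list mapping a group label to a character vector of
#'   taxon names.
#' @param by_origin When `TRUE`, tally known and de novo taxa separately.
#' @return A data frame with columns `group`, `bin`, (`origin`,) `n_taxa`.
#' @export
rollup_taxa <- function(x, groups, by_origin = FALSE) {
  out <- list()
  for (g in names(groups)) {
    idx <- match(groups[[g]], x$taxa$name)
    if (anyNA(idx)) stop("unknown taxon in group ", g)
    if (length(idx) == 0) next
    bin <- rollup_bin(x$taxa$family[idx], x$taxa$genus[idx],
                      x$taxa$species[idx])
    if (by_origin) {
      tb <- as.data.frame(table(bin = bin, origin = x$taxa$origin[idx]),
                          stringsAsFactors = FALSE)
      tb <- tb[tb$Freq > 0, , drop = FALSE]
      out[[g]] <- data.frame(group = g, bin = tb$bin, origin = tb$origin,
                             n_taxa = tb$Freq, stringsAsFactors = FALSE)
    } else {
      tb <- table(bin)
      out[[g]] <- data.frame(group = g, bin = names(tb),
                             n_taxa = as.integer(tb),
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    cols <- if (by_origin) c("group", "bin", "origin", "n_taxa") else
      c("group", "bin", "n_taxa")
    return(setNames(data.frame(character(), character(),
                               if (by_origin) character() else NULL,
                               integer(), stringsAsFactors = FALSE), cols))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an abundance table to TSV
#'
#' @param x An `amf_table`.
#' @param path Output path; taxa in rows with lineage columns, samples in
#'   columns.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  out <- cbind(x$taxa[, c("name", "family", "genus", "species", "origin")],
               as.data.frame(x$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
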