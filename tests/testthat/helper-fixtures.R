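# Shared fixture builders: everything is generated in code at test time.

# Abundance table over the first ncol(counts) samples of the standard design.
toy_table <- function(counts, origin = "known", family = "Glomeraceae",
                      genus = "Glomus", species = "") {
  counts <- as.matrix(counts)
  design <- amf_design()[seq_len(ncol(counts)), , drop = FALSE]
  colnames(counts) <- design$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  }
  n <- nrow(counts)
  taxa <- data.frame(name = rownames(counts),
                     family = rep_len(family, n), genus = rep_len(genus, n),
                     species = rep_len(species, n),
                     origin = rep_len(origin, n), stringsAsFactors = FALSE)
  abundance_table(counts, taxa, design)
}

# Substitute exactly round(rate * nchar) positions with different bases.
mutate_at_rate <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round(rate * length(ch))
  if (k > 0) {
    pos <- sample(length(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# Reads with uniform quality q.
flat_reads <- function(bases, q = 40L, ids = NULL, sample = NA_character_) {
  if (is.null(ids)) ids <- paste0("r", seq_along(bases))
  reads_frame(ids, bases, lapply(nchar(bases), function(n) rep(q, n)), sample)
}
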