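# Experimental design, read containers and the standard file formats.

SOILS <- c("Bs", "Rs")
TIMES <- c("1S", "2S")
REF_STATUSES <- c("known", "uncultured", "de_novo")

#' Experimental design of the two-soil, two-time vineyard survey
#'
#' The survey crosses two soils (`Bs`, bulk soil outside the rows; `Rs`, soil
#' associated with grapevine roots) with two sampling times (`1S`, flowering;
#' `2S`, early fruit development) and five replicates each, for 20 samples.
#'
#' @param replicates Integer vector of replicate numbers, a subset of 1:5.
#' @return A data frame with columns `sample_id`, `soil`, `time`,
#'   `replicate`, one row per sample, in soil/time/replicate order.
#' @examples
#' nrow(amf_design())  # 20
#' @export
amf_design <- function(replicates = 1:5) {
  replicates <- as.integer(replicates)
  if (length(replicates) == 0 || any(replicates < 1L | replicates > 5L)) {
    stop("replicates must be a non-empty subset of 1:5")
  }
  g <- expand.grid(replicate = replicates, time = TIMES, soil = SOILS,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(sample_id = sample_id(g$soil, g$time, g$replicate),
             soil = g$soil, time = g$time, replicate = g$replicate,
             stringsAsFactors = FALSE)
}

#' Build or parse sample identifiers
#'
#' Sample identifiers have the form `"<soil>_<time>_<replicate>"`, e.g.
#' `"Bs_1S_1"`.
#'
#' @param soil `"Bs"` or `"Rs"`.
#' @param time `"1S"` or `"2S"`.
#' @param replicate Integer in 1..5.
#' @return A character vector of sample identifiers.
#' @export
sample_id <- function(soil, time, replicate) {
  if (!all(soil %in% SOILS)) stop("soil must be one of: ", paste(SOILS, collapse = ", "))
  if (!all(time %in% TIMES)) stop("time must be one of: ", paste(TIMES, collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L | replicate > 5L)) {
    stop("replicate must be an integer in 1..5")
  }
  paste(soil, time, replicate, sep = "_")
}

#' Assemble a data frame of sequencing reads
#'
#' The read container used throughout the pipeline: one row per read with the
#' read identifier, the base string over `A`,`C`,`G`,`T`,`N`, a list column of
#' integer Phred quality scores (one per base), and the sample of origin
#' (`NA` before demultiplexing).
#'
#' @param read_id Character vector of unique read identifiers.
#' @param bases Character vector of base strings (uppercased on entry).
#' @param quals List of integer vectors, one per read, each the same length
#'   as the corresponding base string; scores must be non-negative.
#' @param sample Character vector of sample identifiers, recycled; `NA` when
#'   unknown.
#' @return A data frame with columns `read_id`, `bases`, `quals` (list
#'   column), `sample`.
#' @export
reads_frame <- function(read_id = character(), bases = character(),
                        quals = list(), sample = NA_character_) {
  n <- length(read_id)
  if (length(bases) != n || length(quals) != n) {
    stop("read_id, bases and quals must have equal length")
  }
  bases <- toupper(as.character(bases))
  quals <- lapply(quals, as.integer)
  bad <- which(nchar(bases) != lengths(quals))
  if (length(bad)) {
    stop("bases and quality lengths differ for read(s): ",
         paste(utils::head(read_id[bad], 3), collapse = ", "))
  }
  if (any(unlist(quals, use.names = FALSE) < 0L)) {
    stop("quality scores must be non-negative")
  }
  if (anyDuplicated(read_id)) stop("read_id values must be unique")
  df <- data.frame(read_id = as.character(read_id), bases = bases,
                   sample = rep_len(as.character(sample), n),
                   stringsAsFactors = FALSE)
  df$quals <- quals
  df[, c("read_id", "bases", "quals", "sample")]
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Sanger (Phred+33) quality encoding.
#' Records whose base and quality strings differ in length raise an error
#' naming the record index; quality characters below `"!"` raise an encoding
#' error.
#'
#' @param path Path to a FASTQ file.
#' @return A read data frame as produced by [reads_frame()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) return(reads_frame())
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  bases <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  qstr <- lines[seq(4, length(lines), by = 4)]
  if (!all(startsWith(hdr, "@"))) {
    stop("malformed FASTQ: header without '@' at record ",
         which(!startsWith(hdr, "@"))[1])
  }
  if (!all(startsWith(plus, "+"))) {
    stop("malformed FASTQ: separator without '+' at record ",
         which(!startsWith(plus, "+"))[1])
  }
  bad <- which(nchar(bases) != nchar(qstr))
  if (length(bad)) {
    stop("malformed FASTQ: base/quality length mismatch at record ", bad[1])
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  quals <- lapply(qstr, function(qq) utf8ToInt(qq) - 33L)
  low <- which(vapply(quals, function(qq) any(qq < 0L), logical(1)))
  if (length(low)) {
    stop("quality encoding error (character below '!') at record ", low[1])
  }
  reads_frame(ids, bases, quals)
}

#' Write reads to a FASTQ file
#'
#' @param reads A read data frame ([reads_frame()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qstr <- vapply(reads$quals,
                 function(qq) if (length(qq)) intToUtf8(qq + 33L) else "",
                 character(1))
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$bases, "+", qstr))
  writeLines(out, path)
  invisible(path)
}

#' Generate a default MID (barcode) map for the 20-sample design
#'
#' Tags are distinct 8-mers over ACGT; equal length guarantees the mutual
#' non-prefix property that demultiplexing requires.
#'
#' @param design A design data frame ([amf_design()]).
#' @return A data frame with columns `tag`, `sample_id`.
#' @export
default_mid_map <- function(design = amf_design()) {
  alpha <- c("A", "C", "G", "T")
  tag_of <- function(k) {
    d <- integer(8)
    for (p in 8:1) { d[p] <- k %% 4L; k <- k %/% 4L }
    paste(alpha[d + 1L], collapse = "")
  }
  # spread indices so consecutive tags differ in more than the last digit
  tags <- vapply(seq_len(nrow(design)) * 2741L, tag_of, character(1))
  data.frame(tag = tags, sample_id = design$sample_id,
             stringsAsFactors = FALSE)
}

validate_mid_map <- function(mid_map) {
  stopifnot(is.data.frame(mid_map), all(c("tag", "sample_id") %in% names(mid_map)))
  tags <- mid_map$tag
  if (anyDuplicated(tags)) stop("MID tags must be unique")
  if (anyDuplicated(mid_map$sample_id)) stop("MID sample_ids must be unique")
  for (i in seq_along(tags)) {
    pre <- startsWith(tags[-i], tags[i])
    if (any(pre)) {
      stop("MID tag '", tags[i], "' is a prefix of tag '", tags[-i][pre][1], "'")
    }
  }
  invisible(mid_map)
}

#' Prepend MID tags to reads according to their sample of origin
#'
#' The inverse of [demultiplex()]: each read's tag is prepended to its bases
#' with maximal quality scores (Q40) over the tag positions.
#'
#' @param reads A read data frame with the `sample` column filled.
#' @param mid_map A tag-to-sample map ([default_mid_map()]).
#' @return A read data frame with tagged bases and `sample` cleared.
#' @export
attach_mids <- function(reads, mid_map) {
  validate_mid_map(mid_map)
  idx <- match(reads$sample, mid_map$sample_id)
  if (anyNA(idx)) stop("some reads carry a sample not present in the MID map")
  tags <- mid_map$tag[idx]
  reads_frame(reads$read_id, paste0(tags, reads$bases),
              Map(function(tg, qq) c(rep(40L, nchar(tg)), qq), tags, reads$quals),
              NA_character_)
}

#' Demultiplex reads by exact MID prefix
#'
#' A read is assigned to the unique tag that is an exact prefix of its bases
#' (tags are mutually non-prefix, so at most one can match); the tag is then
#' stripped from bases and qualities. Reads matching no tag are returned
#' unmodified in `unmatched`. The output partitions the input.
#'
#' @param reads A read data frame.
#' @param mid_map A tag-to-sample map with columns `tag`, `sample_id`.
#' @return A list with `by_sample` (named list of read data frames, one per
#'   `sample_id` in the map, possibly empty) and `unmatched`.
#' @export
demultiplex <- function(reads, mid_map) {
  validate_mid_map(mid_map)
  hit <- rep(NA_integer_, nrow(reads))
  for (k in seq_len(nrow(mid_map))) {
    m <- is.na(hit) & startsWith(reads$bases, mid_map$tag[k])
    hit[m] <- k
  }
  by_sample <- vector("list", nrow(mid_map))
  names(by_sample) <- mid_map$sample_id
  for (k in seq_len(nrow(mid_map))) {
    sel <- which(hit == k)
    tl <- nchar(mid_map$tag[k])
    by_sample[[k]] <- reads_frame(
      reads$read_id[sel],
      substring(reads$bases[sel], tl + 1L),
      lapply(reads$quals[sel], function(qq) qq[-seq_len(tl)]),
      mid_map$sample_id[k])
  }
  list(by_sample = by_sample, unmatched = reads[is.na(hit), , drop = FALSE])
}

# Reference databases ------------------------------------------------------

#' Assemble a reference sequence database
#'
#' @param accession Unique accession strings.
#' @param bases Sequences over ACGT.
#' @param family,genus,species Lineage fields; empty string when unknown.
#'   A non-empty species requires a non-empty genus.
#' @param status One of `"known"`, `"uncultured"`, `"de_novo"` per entry.
#' @return A data frame with one row per reference sequence.
#' @export
reference_db <- function(accession, bases, family = "", genus = "",
                         species = "", status = "known") {
  n <- length(accession)
  df <- data.frame(accession = as.character(accession),
                   bases = toupper(as.character(bases)),
                   family = rep_len(as.character(family), n),
                   genus = rep_len(as.character(genus), n),
                   species = rep_len(as.character(species), n),
                   status = rep_len(as.character(status), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$accession)) {
    stop("duplicate accession: ",
         df$accession[duplicated(df$accession)][1])
  }
  if (any(!nzchar(df$bases))) stop("reference sequences must be non-empty")
  if (any(grepl("[^ACGT]", df$bases))) {
    stop("reference sequences must be over the ACGT alphabet")
  }
  if (!all(df$status %in% REF_STATUSES)) {
    stop("status must be one of: ", paste(REF_STATUSES, collapse = ", "))
  }
  if (any(nzchar(df$species) & !nzchar(df$genus))) {
    stop("a non-empty species requires a non-empty genus")
  }
  df
}

#' Read a lineage-annotated reference FASTA
#'
#' Headers follow the dialect `accession|family;genus;species|status`, e.g.
#' `>A1|Glomeraceae;Glomus;|uncultured`. Empty lineage fields are allowed;
#' duplicate accessions and unparseable headers are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A reference data frame as produced by [reference_db()].
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  headers <- names(dss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("unparseable reference header at record ", bad[1], ": ", headers[bad[1]])
  }
  lin <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  lin <- lapply(lin, function(x) { length(x) <- 3L; ifelse(is.na(x), "", x) })
  bad <- which(vapply(lin, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("lineage must have three ';'-separated fields at record ", bad[1])
  }
  reference_db(accession = vapply(parts, `[`, character(1), 1L),
               bases = as.character(dss),
               family = vapply(lin, `[`, character(1), 1L),
               genus = vapply(lin, `[`, character(1), 2L),
               species = vapply(lin, `[`, character(1), 3L),
               status = vapply(parts, `[`, character(1), 3L))
}

#' Write a reference database to lineage-annotated FASTA
#'
#' @param db A reference data frame ([reference_db()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  headers <- paste0(db$accession, "|", db$family, ";", db$genus, ";",
                    db$species, "|", db$status)
  seqs <- Biostrings::DNAStringSet(setNames(db$bases, headers))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Human-readable taxon label from a lineage
#'
#' The label is the most specific non-empty rank: the species name when
#' present, otherwise the genus (prefixed with `"uncultured"` for uncultured
#' entries), otherwise the family, otherwise `"Glomeromycota"`.
#'
#' @param family,genus,species Lineage fields (vectors).
#' @param status Entry status (vector).
#' @return Character vector of labels.
#' @export
lineage_label <- function(family, genus, species, status = "known") {
  n <- max(length(family), length(genus), length(species), length(status))
  family <- rep_len(family, n); genus <- rep_len(genus, n)
  species <- rep_len(species, n); status <- rep_len(status, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (nzchar(species[i])) {
      species[i]
    } else if (nzchar(genus[i])) {
      if (status[i] == "uncultured") paste("uncultured", genus[i]) else genus[i]
    } else if (nzchar(family[i])) {
      family[i]
    } else "Glomeromycota"
  }
  out
}

#' Read a sample design table from TSV
#'
#' @param path TSV with columns `sample_id`, `soil`, `time`, `replicate`.
#' @return A validated design data frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "soil", "time", "replicate")
  if (!all(need %in% names(d))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$soil %in% SOILS) || !all(d$time %in% TIMES)) {
    stop("design soil/time values must be Bs/Rs and 1S/2S")
  }
  d$replicate <- as.integer(d$replicate)
  if (any(d$replicate < 1L | d$replicate > 5L)) stop("replicate out of 1..5")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  d[, need]
}
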