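# Ground-truthed synthetic data: mock reference databases, per-sample
# community compositions and error-bearing amplicon reads, so every pipeline
# stage can be exercised and verified without external downloads.

GENUS_POOL <- data.frame(
  genus = c("Glomus", "Rhizophagus", "Septoglomus", "Archaeospora"),
  family = c("Glomeraceae", "Glomeraceae", "Glomeraceae", "Archaeosporaceae"),
  weight = c(0.35, 0.30, 0.10, 0.25),
  stringsAsFactors = FALSE)

SPECIES_POOL <- list(
  Glomus = c("Glomus macrocarpum", "Glomus microcarpum"),
  Rhizophagus = c("Rhizophagus irregularis", "Rhizophagus intraradices",
                  "Rhizophagus diaphanum"),
  Septoglomus = c("Septoglomus viscosum"),
  Archaeospora = c("Archaeospora trappei"))

#' Configuration for the synthetic amplicon study
#'
#' Defaults emulate the study conditions of a 454-style LSU rDNA survey:
#' ~700 bp amplicons, 20 samples (2 soils x 2 times x 5 replicates),
#' per-replicate depths spread over the observed range, a Dirichlet
#' community model with multiplicative soil and time effects on chosen
#' taxa, low per-base error, and small engineered fractions of chimeric,
#' off-target and QC-failing reads.
#'
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param n_ref_taxa Number of mock taxa in the reference world.
#' @param ref_length Length range of reference sequences (bp).
#' @param reads_per_replicate Range the per-replicate read count is drawn
#'   from (uniform), mirroring the spread of real replicate depths.
#' @param substitution_rate,indel_rate Per-base error rates applied to each
#'   read.
#' @param chimera_fraction Probability that an emitted read is a two-parent
#'   chimera.
#' @param offtarget_fraction Probability that an emitted read is an
#'   unrelated random sequence.
#' @param qc_fail_fractions Named fractions (`short`, `lowq`, `ambiguous`)
#'   of reads engineered to fail exactly one QC rule; injected counts are
#'   deterministic (`round(fraction * n)`).
#' @param dirichlet_concentration Concentration of the per-replicate
#'   Dirichlet draw around the group composition (larger = tighter
#'   replicates).
#' @param known_fraction Fraction of taxa with species-level ("known")
#'   reference entries; the rest are uncultured and only reachable through
#'   de novo clustering.
#' @param n_soil_da,soil_fold Number of known taxa given a multiplicative
#'   soil effect, and its fold change.
#' @param n_time_da,time_fold Same for the sampling-time effect.
#' @param read_length_mean,read_length_sd Read length distribution (bp);
#'   reads are 5'-anchored prefixes of their source sequence.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_ref_taxa = 12,
                       ref_length = c(600, 800),
                       reads_per_replicate = c(2000, 12000),
                       substitution_rate = 0.005,
                       indel_rate = 0.0005,
                       chimera_fraction = 0.02,
                       offtarget_fraction = 0.02,
                       qc_fail_fractions = c(short = 0.01, lowq = 0.01,
                                             ambiguous = 0.01),
                       dirichlet_concentration = 200,
                       known_fraction = 0.75,
                       n_soil_da = 3, soil_fold = 4,
                       n_time_da = 2, time_fold = 3,
                       read_length_mean = 700, read_length_sd = 60) {
  if (missing(seed)) stop("seed is mandatory")
  fracs <- c(substitution_rate, indel_rate, chimera_fraction,
             offtarget_fraction, qc_fail_fractions, known_fraction)
  if (any(fracs < 0) || any(c(chimera_fraction, offtarget_fraction,
                              qc_fail_fractions, known_fraction) > 1)) {
    stop("fractions must lie in [0, 1] and rates must be non-negative")
  }
  if (n_ref_taxa < 1) stop("n_ref_taxa must be at least 1")
  if (!all(c("short", "lowq", "ambiguous") %in% names(qc_fail_fractions))) {
    stop("qc_fail_fractions needs entries short, lowq, ambiguous")
  }
  structure(list(
    seed = as.integer(seed), n_ref_taxa = as.integer(n_ref_taxa),
    ref_length = ref_length, reads_per_replicate = reads_per_replicate,
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    chimera_fraction = chimera_fraction,
    offtarget_fraction = offtarget_fraction,
    qc_fail_fractions = qc_fail_fractions,
    dirichlet_concentration = dirichlet_concentration,
    known_fraction = known_fraction,
    n_soil_da = as.integer(n_soil_da), soil_fold = soil_fold,
    n_time_da = as.integer(n_time_da), time_fold = time_fold,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd),
    class = "sim_config")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (sub_rate > 0) {
    hit <- which(runif(length(ch)) < sub_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  }
  if (indel_rate > 0) {
    hit <- which(runif(length(ch)) < indel_rate)
    for (i in rev(hit)) {
      if (runif(1) < 0.5) {
        ch <- ch[-i]
      } else {
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = i)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a mock reference world
#'
#' Generates `n_ref_taxa` random sequences with at least 10% mutual
#' divergence (enforced by rejection against the package's own aligner:
#' a candidate is rejected when it hits an accepted sequence at coverage
#' >= 80 and identity >= 90). Lineages are drawn over the families and
#' genera typical of vineyard AMF communities (Glomeraceae dominating,
#' Archaeosporaceae represented by Archaeospora). A `known_fraction` of
#' taxa receive species-level names and form the assignment reference
#' database; the remainder are uncultured entries reachable only through
#' de novo clustering and annotation.
#'
#' @param config A [sim_config()].
#' @param max_tries Rejection attempts per sequence before giving up.
#' @return A list of class `sim_reference` with `annotation` (all taxa,
#'   a [reference_db()] frame) and `reference` (the known subset).
#' @export
simulate_reference_db <- function(config, max_tries = 50) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_ref_taxa
  gi <- sample(nrow(GENUS_POOL), n, replace = TRUE, prob = GENUS_POOL$weight)
  genus <- GENUS_POOL$genus[gi]
  family <- GENUS_POOL$family[gi]
  n_known <- round(config$known_fraction * n)
  known <- rep(FALSE, n)
  if (n_known > 0) known[sample.int(n, n_known)] <- TRUE
  species <- character(n)
  used <- character(0)
  for (i in which(known)) {
    pool <- setdiff(SPECIES_POOL[[genus[i]]], used)
    species[i] <- if (length(pool)) pool[1] else
      paste0(genus[i], " sp. SYN-", i)
    used <- c(used, species[i])
  }
  scoring <- align_scoring()
  seqs <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(seq(config$ref_length[1], config$ref_length[2]), 1)
      cand <- random_seq(len)
      if (i == 1) { ok <- TRUE }
      else {
        ab <- align_batch(cand, seqs[seq_len(i - 1)], scoring)
        ok <- !any(passes_criteria(ab$coverage[1, ], ab$identity[1, ],
                                   min_cov = 80, min_id = 90))
      }
      if (ok) { seqs[i] <- cand; break }
    }
    if (!ok) stop("could not satisfy the divergence constraint for taxon ", i)
  }
  annotation <- reference_db(
    accession = sprintf("SYN%04d", seq_len(n)),
    bases = seqs, family = family, genus = genus, species = species,
    status = ifelse(known, "known", "uncultured"))
  structure(list(annotation = annotation,
                 reference = annotation[annotation$status == "known", ,
                                        drop = FALSE]),
            class = "sim_reference")
}

#' Simulate error-bearing amplicon reads with full ground truth
#'
#' For every replicate of the 20-sample design, a community composition is
#' drawn from a Dirichlet model centred on seeded per-taxon base weights,
#' with multiplicative soil and time effects applied to the designated
#' differential taxa. Reads are 5'-anchored prefixes of their source taxon
#' sequence, mutated at the configured substitution/indel rates, with
#' quality strings that comfortably pass QC. Engineered defect reads
#' (short, low-quality, ambiguous) are injected in deterministic numbers;
#' chimeras are spliced from two distinct parents at a uniform interior
#' breakpoint, and off-target reads are unrelated random sequences.
#'
#' @param config A [sim_config()].
#' @param db A `sim_reference` from [simulate_reference_db()] (same
#'   config).
#' @return A list with `reads` (a read data frame with `sample` filled)
#'   and `truth`: per-read truth (`read_id`, `sample`, `accession`,
#'   `role`, `qc_fail`), the realized per-replicate composition over clean
#'   on-target reads (`composition`, taxa x samples matrix of counts), and
#'   the designated differential taxa (`da_taxa`).
#' @export
simulate_reads <- function(config, db) {
  stopifnot(inherits(config, "sim_config"), inherits(db, "sim_reference"))
  set.seed(config$seed + 1L)
  design <- amf_design()
  ann <- db$annotation
  n_taxa <- nrow(ann)
  base_w <- sort(rlnorm(n_taxa, meanlog = 0, sdlog = 1), decreasing = TRUE)
  known_idx <- which(ann$status == "known")
  n_sda <- min(config$n_soil_da, length(known_idx))
  soil_da <- if (n_sda > 0) sample(known_idx, n_sda) else integer(0)
  soil_dir <- rep(c("Rs", "Bs"), length.out = n_sda)
  rest <- setdiff(seq_len(n_taxa), soil_da)
  n_tda <- min(config$n_time_da, length(rest))
  time_da <- if (n_tda > 0) sample(rest, n_tda) else integer(0)
  time_dir <- rep(c("2S", "1S"), length.out = n_tda)

  group_weights <- function(soil, time) {
    w <- base_w
    if (n_sda > 0) {
      up <- soil_da[soil_dir == soil]
      w[up] <- w[up] * config$soil_fold
    }
    if (n_tda > 0) {
      up <- time_da[time_dir == time]
      w[up] <- w[up] * config$time_fold
    }
    w / sum(w)
  }

  lab <- lineage_label(ann$family, ann$genus, ann$species, ann$status)
  da_taxa <- rbind(
    if (n_sda > 0) data.frame(accession = ann$accession[soil_da],
                              label = lab[soil_da], factor = "soil",
                              fold = config$soil_fold,
                              enriched_in = soil_dir,
                              stringsAsFactors = FALSE),
    if (n_tda > 0) data.frame(accession = ann$accession[time_da],
                              label = lab[time_da], factor = "time",
                              fold = config$time_fold,
                              enriched_in = time_dir,
                              stringsAsFactors = FALSE))

  alphabet <- c("A", "C", "G", "T")
  min_normal_len <- 250L
  draw_len <- function(ref_len) {
    len <- round(rnorm(1, config$read_length_mean, config$read_length_sd))
    max(min(len, ref_len), min(min_normal_len, ref_len))
  }
  good_quals <- function(len) sample(30:40, len, replace = TRUE)

  all_reads <- vector("list", nrow(design))
  all_truth <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    p_group <- group_weights(design$soil[s], design$time[s])
    alpha <- config$dirichlet_concentration * p_group
    gam <- rgamma(n_taxa, shape = alpha)
    p_rep <- gam / sum(gam)
    n_reads <- as.integer(round(runif(1, config$reads_per_replicate[1],
                                      config$reads_per_replicate[2])))
    n_short <- round(config$qc_fail_fractions[["short"]] * n_reads)
    n_lowq <- round(config$qc_fail_fractions[["lowq"]] * n_reads)
    n_ambig <- round(config$qc_fail_fractions[["ambiguous"]] * n_reads)
    n_main <- n_reads - n_short - n_lowq - n_ambig
    u <- runif(n_main)
    role <- ifelse(u < config$chimera_fraction, "chimera",
                   ifelse(u < config$chimera_fraction +
                            config$offtarget_fraction, "offtarget", "normal"))
    qc_fail <- c(rep("none", n_main), rep("short", n_short),
                 rep("lowq", n_lowq), rep("ambiguous", n_ambig))
    role <- c(role, rep("normal", n_short + n_lowq + n_ambig))
    bases <- character(n_reads)
    quals <- vector("list", n_reads)
    taxon <- rep(NA_character_, n_reads)
    for (r in seq_len(n_reads)) {
      if (role[r] == "offtarget") {
        len <- max(round(rnorm(1, config$read_length_mean,
                               config$read_length_sd)), min_normal_len)
        seq <- random_seq(len)
      } else if (role[r] == "chimera") {
        par <- sample.int(n_taxa, 2)
        taxon[r] <- paste(ann$accession[par], collapse = "+")
        len <- draw_len(min(nchar(ann$bases[par])))
        bp <- round(runif(1, 0.35, 0.65) * len)
        seq <- paste0(substr(ann$bases[par[1]], 1, bp),
                      substr(ann$bases[par[2]], bp + 1, len))
        seq <- mutate_seq(seq, config$substitution_rate, config$indel_rate)
      } else {
        t <- sample.int(n_taxa, 1, prob = p_rep)
        taxon[r] <- ann$accession[t]
        ref <- ann$bases[t]
        if (qc_fail[r] == "short") {
          len <- sample(50:199, 1)
          seq <- substr(ref, 1, len)
        } else {
          len <- draw_len(nchar(ref))
          seq <- substr(ref, 1, len)
          seq <- mutate_seq(seq, config$substitution_rate, config$indel_rate)
          if (qc_fail[r] == "ambiguous") {
            pos <- sample.int(nchar(seq), 1)
            substr(seq, pos, pos) <- "N"
          }
        }
      }
      bases[r] <- seq
      quals[[r]] <- if (qc_fail[r] == "lowq") {
        sample(5:20, nchar(seq), replace = TRUE)
      } else {
        good_quals(nchar(seq))
      }
    }
    ids <- sprintf("%s_r%05d", sid, seq_len(n_reads))
    all_reads[[s]] <- reads_frame(ids, bases, quals, sid)
    all_truth[[s]] <- data.frame(read_id = ids, sample = sid,
                                 accession = taxon, role = role,
                                 qc_fail = qc_fail, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all_reads)
  truth_reads <- do.call(rbind, all_truth)
  rownames(reads) <- rownames(truth_reads) <- NULL
  clean <- truth_reads$role == "normal" & truth_reads$qc_fail == "none"
  composition <- matrix(0L, nrow = n_taxa, ncol = nrow(design),
                        dimnames = list(ann$accession, design$sample_id))
  tb <- table(factor(truth_reads$accession[clean], levels = ann$accession),
              factor(truth_reads$sample[clean], levels = design$sample_id))
  composition[] <- as.integer(tb)
  list(reads = reads,
       truth = list(reads = truth_reads, composition = composition,
                    da_taxa = da_taxa),
       config = config)
}
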