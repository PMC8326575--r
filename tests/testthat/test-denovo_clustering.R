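test_that("dereplication collapses duplicates case-insensitively", {
  d <- dereplicate(c("ACGT", "acgt", "ACGT", "TTTT", "GGGG"),
                   paste0("r", 1:5))
  expect_equal(nrow(d), 3)
  expect_equal(sum(d$multiplicity), 5)
  expect_equal(d$multiplicity[d$sequence == "ACGT"], 3L)
  expect_setequal(d$read_ids[[which(d$sequence == "ACGT")]],
                  c("r1", "r2", "r3"))
  all_distinct <- dereplicate(c("AA", "CC", "GG"))
  expect_equal(all_distinct$multiplicity, rep(1L, 3))
})

test_that("a pool of identical sequences forms a single cluster", {
  pool <- flat_reads(rep("ACGTACGTACGTACGTACGT", 7))
  cl <- cluster_denovo(pool)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$name, "de novo_1")
  expect_equal(cl$n_reads, 7L)
  expect_setequal(cl$member_read_ids[[1]], pool$read_id)
})

planted_pool <- function(n_families = 3, members = 5, len = 300,
                         within = 0.01) {
  ancestor <- random_dna(len)
  founders <- replicate(n_families, mutate_at_rate(ancestor, 0.05))
  bases <- unlist(lapply(founders, function(f) {
    c(f, replicate(members - 1, mutate_at_rate(f, within)))
  }))
  truth <- rep(seq_len(n_families), each = members)
  list(reads = flat_reads(bases), truth = truth)
}

test_that("planted families at 10%/1% divergence cluster exactly", {
  set.seed(51)
  p <- planted_pool()
  cl <- cluster_denovo(p$reads)
  expect_equal(nrow(cl), 3)
  got <- integer(nrow(p$reads))
  for (i in seq_len(nrow(cl))) {
    got[match(cl$member_read_ids[[i]], p$reads$read_id)] <- i
  }
  fam_cluster <- tapply(got, p$truth, function(x) unique(x))
  expect_true(all(lengths(fam_cluster) == 1))  # no family is split
  expect_equal(length(unique(unlist(fam_cluster))), 3)  # no families merged
  # every member passes the criteria against its centroid
  for (i in seq_len(nrow(cl))) {
    for (rid in cl$member_read_ids[[i]]) {
      h <- align_pair(p$reads$bases[p$reads$read_id == rid], cl$sequence[i])
      expect_true(passes_criteria(h$coverage, h$identity))
    }
  }
})

test_that("unrelated random sequences stay singletons", {
  set.seed(52)
  pool <- flat_reads(replicate(12, random_dna(300)))
  cl <- cluster_denovo(pool)
  expect_equal(nrow(cl), 12)
  expect_equal(cl$n_reads, rep(1L, 12))
})

test_that("clustering is invariant to the input read order", {
  set.seed(53)
  p <- planted_pool(2, 4)
  cl1 <- cluster_denovo(p$reads)
  perm <- sample(nrow(p$reads))
  cl2 <- cluster_denovo(p$reads[perm, ])
  expect_equal(cl1$sequence, cl2$sequence)
  expect_equal(lapply(cl1$member_read_ids, sort),
               lapply(cl2$member_read_ids, sort))
})

test_that("greedy clusters sit inside single-linkage components", {
  set.seed(54)
  # a mixed pool: two families plus noise sequences
  p <- planted_pool(2, 4)
  pool <- rbind(p$reads,
                flat_reads(replicate(5, random_dna(300)),
                           ids = paste0("noise", 1:5)))
  greedy <- cluster_denovo(pool, method = "centroid")
  single <- cluster_denovo(pool, method = "single")
  comp_of <- setNames(rep(seq_len(nrow(single)),
                          lengths(single$member_read_ids)),
                      unlist(single$member_read_ids))
  for (i in seq_len(nrow(greedy))) {
    expect_length(unique(comp_of[greedy$member_read_ids[[i]]]), 1)
  }
  # count conservation in both modes
  expect_equal(sum(greedy$n_reads), nrow(pool))
  expect_equal(sum(single$n_reads), nrow(pool))
})

test_that("annotation labels clusters by best passing hit, else fallback", {
  set.seed(55)
  seqs <- replicate(2, random_dna(400))
  db <- reference_db(c("N1", "N2"), seqs,
                     family = c("Archaeosporaceae", "Glomeraceae"),
                     genus = c("Archaeospora", "Rhizophagus"),
                     species = c("", "Rhizophagus irregularis"),
                     status = c("uncultured", "known"))
  pool <- flat_reads(c(seqs[1], mutate_at_rate(seqs[2], 0.02),
                       random_dna(400)))
  cl <- annotate_denovo(cluster_denovo(pool), db)
  lab <- setNames(cl$label, cl$centroid_read_id)
  expect_equal(unname(lab["r1"]), "uncultured Archaeospora")
  expect_equal(unname(lab["r2"]), "Rhizophagus irregularis")
  expect_equal(unname(lab["r3"]), "uncultured Glomeromycota")
  # empty database: everything falls back
  cl0 <- annotate_denovo(cluster_denovo(pool), db[0, ])
  expect_equal(unique(cl0$label), "uncultured Glomeromycota")
})

test_that("cluster counts map members to their samples", {
  pool <- flat_reads(rep("ACGTACGTACGTACGTACGT", 4),
                     sample = c("Bs_1S_1", "Bs_1S_1", "Rs_1S_1", "Rs_2S_1"))
  cl <- cluster_denovo(pool)
  cc <- cluster_counts(cl, pool, samples = c("Bs_1S_1", "Rs_1S_1", "Rs_2S_1"))
  expect_equal(as.vector(cc), c(2L, 1L, 1L))
})
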