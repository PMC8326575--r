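small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_ref_taxa = 5, ref_length = c(300, 400),
             reads_per_replicate = c(20, 30), read_length_mean = 320,
             read_length_sd = 20, ...)
}

test_that("the reference world is seeded, divergent and labeled", {
  cfg <- small_cfg(201)
  db <- simulate_reference_db(cfg)
  expect_equal(nrow(db$annotation), 5)
  expect_equal(nrow(db$reference), round(0.75 * 5))
  expect_true(all(db$reference$status == "known"))
  expect_true(all(nzchar(db$reference$species)))
  # pairwise divergence: no pair passes the 80/90 screen
  ab <- align_batch(db$annotation$bases, db$annotation$bases)
  pass <- passes_criteria(ab$coverage, ab$identity, 80, 90)
  diag(pass) <- FALSE
  expect_false(any(pass))
  # determinism
  db2 <- simulate_reference_db(small_cfg(201))
  expect_identical(db$annotation, db2$annotation)
  expect_error(sim_config(seed = 1, n_ref_taxa = 0), "at least 1")
  expect_error(sim_config(), "mandatory")
})

test_that("read simulation is deterministic and fully ground-truthed", {
  cfg <- small_cfg(202)
  db <- simulate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  sim2 <- simulate_reads(cfg, db)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
  # every emitted read is covered exactly once by the truth
  expect_setequal(sim$reads$read_id, sim$truth$reads$read_id)
  expect_equal(nrow(sim$reads), nrow(sim$truth$reads))
  expect_equal(length(unique(sim$reads$sample)), 20)
})

test_that("injected QC defect counts are recovered exactly", {
  cfg <- small_cfg(203, qc_fail_fractions = c(short = 0.05, lowq = 0.04,
                                              ambiguous = 0.03))
  db <- simulate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  qc <- filter_reads(sim$reads)
  truth_tab <- table(sim$truth$reads$qc_fail)
  expect_equal(qc$report$n_short, unname(truth_tab[["short"]]))
  expect_equal(qc$report$n_lowq, unname(truth_tab[["lowq"]]))
  expect_equal(qc$report$n_ambiguous, unname(truth_tab[["ambiguous"]]))
  expect_equal(qc$report$n_passed, unname(truth_tab[["none"]]))
})

test_that("the noiseless limit passes QC and assigns every on-target read", {
  cfg <- small_cfg(204, substitution_rate = 0, indel_rate = 0,
                   chimera_fraction = 0, offtarget_fraction = 0,
                   qc_fail_fractions = c(short = 0, lowq = 0, ambiguous = 0),
                   known_fraction = 1)
  db <- simulate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  qc <- filter_reads(sim$reads)
  expect_equal(qc$report$n_passed, qc$report$n_input)
  out <- assign_all(qc$passed, db$reference,
                    samples = amf_design()$sample_id)
  expect_equal(nrow(out$pool), 0)
  truth_acc <- setNames(sim$truth$reads$accession, sim$truth$reads$read_id)
  expect_equal(out$assignments$accession,
               unname(truth_acc[out$assignments$read_id]))
})

test_that("the chimera count concentrates around its nominal fraction", {
  cfg <- sim_config(seed = 205, n_ref_taxa = 4, ref_length = c(300, 350),
                    reads_per_replicate = c(100, 100),
                    chimera_fraction = 0.05, read_length_mean = 320,
                    read_length_sd = 10)
  db <- simulate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  n_main <- sum(sim$truth$reads$qc_fail == "none")
  n_chim <- sum(sim$truth$reads$role == "chimera")
  expect_lt(abs(n_chim - 0.05 * n_main), 4 * sqrt(n_main * 0.05 * 0.95))
})

test_that("the realized composition covers clean on-target reads only", {
  cfg <- small_cfg(206)
  db <- simulate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  clean <- sim$truth$reads$role == "normal" & sim$truth$reads$qc_fail == "none"
  expect_equal(sum(sim$truth$composition), sum(clean))
  expect_equal(colnames(sim$truth$composition), amf_design()$sample_id)
  # differential taxa are designated with direction and fold
  expect_true(all(sim$truth$da_taxa$fold > 1))
  expect_true(all(sim$truth$da_taxa$factor %in% c("soil", "time")))
})
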