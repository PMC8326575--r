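test_that("rarefaction subsamples to depth, flags shallow columns", {
  x <- toy_table(cbind(c(16000L, 0L, 0L), c(900L, 800L, 792L),
                       c(5000L, 2000L, 1000L)))
  r <- rarefy(x, depth = 8000, seed = 1)
  expect_equal(unname(r$counts[, 1]), c(8000L, 0L, 0L))
  # column total 2,492 stays unchanged and flagged
  expect_equal(r$counts[, 2], x$counts[, 2])
  expect_true(r$flagged[2])
  expect_equal(sum(r$counts[, 3]), 8000)
  expect_false(r$flagged[3])
  # column whose total equals the depth is untouched and unflagged
  x2 <- toy_table(cbind(c(4000L, 4000L)))
  r2 <- rarefy(x2, depth = 8000)
  expect_equal(r2$counts, x2$counts)
  expect_false(any(r2$flagged))
  expect_error(rarefy(x, depth = 0), "positive")
})

test_that("rarefaction preserves zeros and matches expected proportions", {
  counts <- cbind(c(120L, 60L, 20L, 0L))
  x <- toy_table(counts)
  draws <- vapply(1:200, function(s) rarefy(x, depth = 50, seed = s)$counts[, 1],
                  numeric(4))
  expect_true(all(draws[4, ] == 0))
  expect_true(all(colSums(draws) == 50))
  # hypergeometric mean and 3-sigma band for the first taxon
  n_total <- sum(counts); m <- 50
  mu <- m * counts[1] / n_total
  v <- m * (counts[1] / n_total) * (1 - counts[1] / n_total) *
    (n_total - m) / (n_total - 1)
  expect_lt(abs(mean(draws[1, ]) - mu), 3 * sqrt(v / 200))
})

test_that("presence requires >= 10 reads in at least one replicate, counted once", {
  counts <- rbind(one_rep = c(12, 0, 0, 0, 0),
                  below = c(9, 9, 9, 9, 9),
                  two_reps = c(10, 10, 0, 0, 0))
  x <- toy_table(counts)  # columns are the five Bs 1S replicates
  p <- present_taxa(x, "Bs", "1S")
  expect_setequal(p, c("one_rep", "two_reps"))
  # monotone: adding reads never removes presence
  x2 <- toy_table(counts + 5)
  expect_true(all(p %in% present_taxa(x2, "Bs", "1S")))
  expect_error(present_taxa(x, "Rs", "2S"), "no samples")
})

test_that("venn regions are exclusive, exhaustive and match brute force", {
  v <- venn_regions(list(A = c("x", "y"), B = c("y", "z")))
  expect_setequal(v[["A"]], "x")
  expect_setequal(v[["B"]], "z")
  expect_setequal(v[["A&B"]], "y")

  four <- replicate(4, paste0("t", 1:20), simplify = FALSE)
  names(four) <- c("a", "b", "c", "d")
  v4 <- venn_regions(four)
  expect_equal(length(v4[["a&b&c&d"]]), 20)
  expect_equal(sum(lengths(v4)), 20)

  set.seed(61)
  sets <- lapply(1:4, function(i) sample(paste0("s", 1:300), 100))
  names(sets) <- LETTERS[1:4]
  v <- venn_regions(sets)
  expect_equal(sum(lengths(v)), length(unique(unlist(sets))))
  for (el in unique(unlist(sets))) {
    membership <- names(sets)[vapply(sets, function(s) el %in% s, logical(1))]
    region <- paste(membership, collapse = "&")
    expect_true(el %in% v[[region]])
  }
  expect_error(venn_regions(sets[1]), "2 to 4")
})

test_that("median filter keeps taxa with positive median over replicates", {
  counts <- rbind(kept = c(0, 0, 1, 2, 3),
                  dropped = c(0, 0, 0, 5, 9),
                  flat = c(7, 7, 7, 7, 7))
  x <- toy_table(counts)
  expect_setequal(median_filter(x, "Bs", "1S"), c("kept", "flat"))
})

test_that("taxonomic rollup bins by most specific rank, joint or by origin", {
  counts <- matrix(5L, nrow = 6, ncol = 5,
                   dimnames = list(paste0("t", 1:6), NULL))
  taxa <- data.frame(
    name = paste0("t", 1:6),
    family = c(rep("Glomeraceae", 3), "", "Archaeosporaceae", ""),
    genus = c("Glomus", "Glomus", "Glomus", "", "Archaeospora", ""),
    species = c("", "", "", "", "", ""),
    origin = c("known", "known", "known", "de_novo", "de_novo", "de_novo"),
    stringsAsFactors = FALSE)
  design <- amf_design()[1:5, ]
  colnames(counts) <- design$sample_id
  x <- abundance_table(counts, taxa, design)
  ru <- rollup_taxa(x, list(Bs1S = paste0("t", 1:5)))
  expect_equal(ru$n_taxa[ru$bin == "Glomus"], 3L)
  # Archaeospora reachable only through the de novo side
  by_or <- rollup_taxa(x, list(Bs1S = paste0("t", 1:6)), by_origin = TRUE)
  arch <- by_or[by_or$bin == "Archaeospora", ]
  expect_equal(arch$origin, "de_novo")
  expect_equal(sum(by_or$n_taxa), 6L)
  expect_equal(by_or$n_taxa[by_or$bin == "Glomeromycota (unresolved)"], 2L)
  # empty input gives an empty frame
  expect_equal(nrow(rollup_taxa(x, list())), 0)
})
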