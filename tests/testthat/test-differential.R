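test_that("exact rank-sum p handles complete separation with ties", {
  # 5-vs-5 complete separation: only the two extreme assignments are as
  # deviant as the observed one => p = 2 / C(10,5) = 2/252
  expect_equal(rank_sum_exact_p(rep(100, 5), rep(0, 5)), 2 / 252,
               tolerance = 1e-12)
  # identical groups give p = 1
  expect_equal(rank_sum_exact_p(1:5, 1:5), 1)
})

test_that("exact rank-sum p matches wilcox.test where no ties occur", {
  set.seed(91)
  for (k in 1:20) {
    a <- sample(1:1000, sample(3:6, 1))
    b <- sample(2000:3000, sample(3:6, 1)) + runif(1)
    v <- c(a, b)
    if (anyDuplicated(v)) next
    expect_equal(rank_sum_exact_p(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

diff_table <- function(counts_a, counts_b, genus = "Glomus") {
  counts <- cbind(counts_a, counts_b)
  design <- amf_design()[1:ncol(counts), ]
  colnames(counts) <- design$sample_id
  n <- nrow(counts)
  taxa <- data.frame(name = rownames(counts),
                     family = rep("Glomeraceae", n),
                     genus = rep_len(genus, n), species = rep("", n),
                     origin = rep("known", n), stringsAsFactors = FALSE)
  abundance_table(counts, taxa, design)
}

test_that("heat tree: identical groups give zero effects and no flags", {
  m <- matrix(rpois(10, 20), nrow = 2,
              dimnames = list(c("t1", "t2"), NULL))
  x <- diff_table(m, m)
  ht <- heat_tree_compare(x, "Bs", "1S", "Bs", "2S")
  expect_true(all(ht$effect == 0))
  expect_true(all(ht$flag == 0))
  expect_true(all(c("root", "family", "genus", "leaf") %in% ht$rank))
})

test_that("heat tree: complete separation flags the node at p = 2/252", {
  a <- matrix(100L, 1, 5, dimnames = list("t1", NULL))
  b <- matrix(0L, 1, 5, dimnames = list("t1", NULL))
  x <- diff_table(a, b)
  ht <- heat_tree_compare(x, "Bs", "1S", "Bs", "2S")
  leaf <- ht[ht$rank == "leaf", ]
  expect_equal(leaf$p, 2 / 252, tolerance = 1e-12)
  expect_equal(leaf$flag, 1L)
  expect_equal(leaf$effect, log2(100.5 / 0.5))
})

test_that("heat tree effects are antisymmetric and median-robust", {
  set.seed(92)
  a <- matrix(rpois(15, 30), nrow = 3, dimnames = list(paste0("t", 1:3), NULL))
  b <- matrix(rpois(15, 10), nrow = 3, dimnames = list(paste0("t", 1:3), NULL))
  x <- diff_table(a, b)
  fwd <- heat_tree_compare(x, "Bs", "1S", "Bs", "2S")
  rev <- heat_tree_compare(x, "Bs", "2S", "Bs", "1S")
  expect_equal(fwd$effect, -rev$effect, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  # a difference confined to one replicate does not move the median effect
  b2 <- a; b2[1, 1] <- b2[1, 1] + 1000L
  x2 <- diff_table(a, b2)
  ht2 <- heat_tree_compare(x2, "Bs", "1S", "Bs", "2S")
  expect_equal(ht2$effect[ht2$node == "t1"], 0)
})

test_that("BH adjustment reproduces a hand-computed toy set", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042)
  # by hand: p * 5/i, then running minimum from the largest rank
  expect_equal(p.adjust(p, method = "BH"),
               c(0.005, 0.020, 0.042, 0.042, 0.042), tolerance = 1e-12)
})

test_that("lefse screens with KW+BH and scores separations on the cpm scale", {
  set.seed(93)
  base <- matrix(rpois(40, 1000), nrow = 2,
                 dimnames = list(c("flat", "boosted"), NULL))
  # ~10-fold boost in the Rs samples of the 'boosted' taxon
  counts <- base
  design <- amf_design()
  rs <- design$soil == "Rs"
  counts["boosted", rs] <- counts["boosted", rs] * 10L
  filler <- matrix(rpois(40, 5000), nrow = 2,
                   dimnames = list(c("f1", "f2"), NULL))
  counts <- rbind(counts, filler)
  colnames(counts) <- design$sample_id
  taxa <- data.frame(name = rownames(counts), family = "Glomeraceae",
                     genus = "Glomus", species = "", origin = "known",
                     stringsAsFactors = FALSE)
  x <- abundance_table(counts, taxa, design)
  res <- lefse(x, group = "soil", seed = 7)
  boosted <- res[res$taxon == "boosted", ]
  expect_true(boosted$significant)
  expect_equal(boosted$top_group, "Rs")
  expect_gt(boosted$lda_score, 4)  # ~4e5 cpm separation => score ~5.6
  # the boosted taxon carries the largest separation of all features
  # (compositional coupling makes the others shift too, with smaller scores)
  expect_equal(res$taxon[which.max(res$lda_score)], "boosted")

  # features identical across all samples are excluded with kw_p = 1
  counts2 <- matrix(rep(c(100L, 300L, 600L), 20), nrow = 3,
                    dimnames = list(paste0("c", 1:3), design$sample_id))
  taxa2 <- data.frame(name = paste0("c", 1:3), family = "Glomeraceae",
                      genus = "Glomus", species = "", origin = "known",
                      stringsAsFactors = FALSE)
  res2 <- lefse(abundance_table(counts2, taxa2, design), group = "soil")
  expect_equal(res2$kw_p, rep(1, 3))
  expect_false(any(res2$significant))
})

test_that("lefse score grows with the planted separation (ordering)", {
  set.seed(94)
  design <- amf_design()
  rs <- design$soil == "Rs"
  counts <- matrix(rpois(60, 2000), nrow = 3,
                   dimnames = list(c("small", "mid", "large"), NULL))
  counts["small", rs] <- counts["small", rs] * 3L
  counts["mid", rs] <- counts["mid", rs] * 6L
  counts["large", rs] <- counts["large", rs] * 12L
  colnames(counts) <- design$sample_id
  taxa <- data.frame(name = rownames(counts), family = "Glomeraceae",
                     genus = "Glomus", species = "", origin = "known",
                     stringsAsFactors = FALSE)
  res <- lefse(abundance_table(counts, taxa, design), group = "soil",
               seed = 11)
  sc <- setNames(res$lda_score, res$taxon)
  expect_true(sc[["large"]] > sc[["mid"]])
  # the largest group-mean separation receives the highest score
  expect_equal(names(which.max(sc)), "large")
})
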