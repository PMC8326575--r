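# Differential abundance: heat-tree style per-node two-group comparison and
# a single-level LEfSe.

#' Exact two-sided rank-sum permutation p-value
#'
#' Enumerates all assignments of the pooled observations to the two groups
#' and compares the midrank sum of group A against its permutation
#' distribution: `p` is the proportion of assignments whose rank sum
#' deviates from the null mean at least as much as the observed one.
#' Midranks make the test exact in the presence of ties (which the usual
#' exact rank-sum tables do not handle). Falls back to the normal
#' approximation of [stats::wilcox.test()] when the enumeration exceeds
#' `max_enum` assignments.
#'
#' @param a,b Numeric vectors (the two groups).
#' @param max_enum Largest number of assignments to enumerate exactly.
#' @return The two-sided p-value.
#' @export
rank_sum_exact_p <- function(a, b, max_enum = 50000) {
  v <- c(a, b)
  n <- length(v)
  na <- length(a)
  if (na < 1 || length(b) < 1) stop("both groups must be non-empty")
  r <- rank(v)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (choose(n, na) <= max_enum) {
    sel <- combn(n, na)
    w_perm <- colSums(matrix(r[sel], nrow = na))
    mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
}

# Build the taxonomy tree implied by the taxa of an abundance table:
# root -> family -> genus -> leaf (taxon name). Empty ranks are skipped, so
# a lineage-less taxon hangs directly off the root. Returns one row per
# node with the taxa aggregated under it.
taxonomy_nodes <- function(taxa) {
  nodes <- list(list(name = "Glomeromycota", rank = "root",
                     taxa = taxa$name))
  fam <- unique(taxa$family[nzchar(taxa$family)])
  for (f in fam) {
    nodes[[length(nodes) + 1L]] <-
      list(name = f, rank = "family", taxa = taxa$name[taxa$family == f])
  }
  gen <- unique(taxa$genus[nzchar(taxa$genus)])
  for (g in gen) {
    nodes[[length(nodes) + 1L]] <-
      list(name = g, rank = "genus", taxa = taxa$name[taxa$genus == g])
  }
  for (i in seq_len(nrow(taxa))) {
    nodes[[length(nodes) + 1L]] <-
      list(name = taxa$name[i], rank = "leaf", taxa = taxa$name[i])
  }
  nodes
}

#' Heat-tree style comparison of two sample groups
#'
#' For every node of the taxonomy tree (root, families, genera and leaf
#' taxa), per-replicate counts are aggregated over the taxa below the node;
#' the effect is `log2((median_A + eps) / (median_B + eps))` on the
#' replicate medians, and the p-value comes from the exact two-sided
#' Wilcoxon rank-sum test on the replicate values. Nodes with `p < alpha`
#' are flagged with the sign of the effect.
#'
#' @param x An `amf_table`.
#' @param soil_a,time_a Group A selectors.
#' @param soil_b,time_b Group B selectors.
#' @param eps Pseudo-count added to both medians before the log ratio
#'   (default 0.5), bounding effects when a median is zero.
#' @param alpha Flagging threshold on the p-value (default 0.05).
#' @return A data frame with one row per node: `node`, `rank`, `effect`,
#'   `p`, `flag` (-1, 0 or +1).
#' @export
heat_tree_compare <- function(x, soil_a, time_a, soil_b, time_b,
                              eps = 0.5, alpha = 0.05) {
  ca <- group_columns(x, soil_a, time_a)
  cb <- group_columns(x, soil_b, time_b)
  if (length(ca) < 2 || length(cb) < 2) {
    stop("each group needs at least two replicates")
  }
  nodes <- taxonomy_nodes(x$taxa)
  out <- data.frame(node = vapply(nodes, `[[`, character(1), "name"),
                    rank = vapply(nodes, `[[`, character(1), "rank"),
                    effect = NA_real_, p = NA_real_, flag = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(nodes)) {
    rows <- match(nodes[[i]]$taxa, rownames(x$counts))
    va <- colSums(x$counts[rows, ca, drop = FALSE])
    vb <- colSums(x$counts[rows, cb, drop = FALSE])
    out$effect[i] <- log2((median(va) + eps) / (median(vb) + eps))
    out$p[i] <- rank_sum_exact_p(va, vb)
    if (out$p[i] < alpha && out$effect[i] != 0) {
      out$flag[i] <- sign(out$effect[i])
    }
  }
  out
}

#' Single-level LEfSe differential abundance
#'
#' Counts are converted to relative abundances scaled to one million per
#' sample. Each taxon is screened with a Kruskal-Wallis test across the
#' groups and the p-values are Benjamini-Hochberg adjusted; taxa that
#' survive the adjusted cutoff receive an LDA effect size: over `n_boot`
#' stratified bootstrap rounds (a fraction `boot_frac` of each group,
#' without replacement), a linear discriminant is fitted on the single
#' feature, its direction normalized to unit length, and the effect is the
#' absolute difference between the two extreme group means on that axis
#' (i.e. on the original abundance scale). The reported score is
#' `log10(max(mean effect, 1))`. Degenerate features (identical values
#' everywhere) are excluded with `kw_p = 1`.
#'
#' @param x An `amf_table`.
#' @param group Either the name of a design column (`"soil"`, `"time"`) or
#'   a vector of group labels, one per sample; at least two groups with at
#'   least three replicates each.
#' @param p_cutoff Adjusted p-value cutoff (default 0.05).
#' @param lda_cutoff Minimum log10 LDA score to report (default 1.0).
#' @param n_boot Bootstrap rounds for the effect size (default 30).
#' @param boot_frac Fraction of each group subsampled per round.
#' @param seed Optional integer seed for the bootstrap.
#' @return A data frame with one row per taxon: `taxon`, `kw_p`,
#'   `kw_p_adj`, `lda_score` (`NA` unless both cutoffs are met),
#'   `top_group` and `significant`.
#' @export
lefse <- function(x, group = "soil", p_cutoff = 0.05, lda_cutoff = 1.0,
                  n_boot = 30, boot_frac = 2 / 3, seed = NULL) {
  g <- if (length(group) == 1 && group %in% names(x$samples)) {
    factor(x$samples[[group]])
  } else {
    factor(rep_len(group, ncol(x$counts)))
  }
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 3)) stop("every group needs at least three replicates")
  rel <- sweep(x$counts, 2, colSums(x$counts), "/") * 1e6
  n_taxa <- nrow(rel)
  kw_p <- numeric(n_taxa)
  for (i in seq_len(n_taxa)) {
    vals <- rel[i, ]
    kw_p[i] <- if (length(unique(vals)) == 1) 1 else
      suppressWarnings(kruskal.test(vals, g)$p.value)
  }
  kw_p_adj <- p.adjust(kw_p, method = "BH")
  top_group <- levels(g)[apply(
    vapply(levels(g), function(l) rowMeans(rel[, g == l, drop = FALSE]),
           numeric(n_taxa)), 1, which.max)]
  lda_score <- rep(NA_real_, n_taxa)
  if (!is.null(seed)) set.seed(seed)
  cand <- which(kw_p_adj <= p_cutoff & kw_p < 1)
  for (i in cand) {
    effs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(g), function(l) {
        w <- which(g == l)
        w[sample.int(length(w), max(2L, ceiling(boot_frac * length(w))))]
      }), use.names = FALSE)
      vals <- rel[i, idx]
      gb <- droplevels(g[idx])
      w_dir <- tryCatch({
        fit <- MASS::lda(data.frame(v = vals), grouping = gb)
        sgn <- sign(fit$scaling[1, 1])
        if (sgn == 0) 1 else sgn
      }, error = function(e) 1)
      proj <- vals * w_dir
      gm <- tapply(proj, gb, mean)
      effs[b] <- max(gm) - min(gm)
    }
    lda_score[i] <- log10(max(mean(effs), 1))
  }
  significant <- !is.na(lda_score) & lda_score >= lda_cutoff
  lda_score[!significant] <- NA_real_
  data.frame(taxon = rownames(rel), kw_p = kw_p, kw_p_adj = kw_p_adj,
             lda_score = lda_score, top_group = top_group,
             significant = significant, stringsAsFactors = FALSE)
}
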