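# Beta diversity: Bray-Curtis distances, principal coordinate analysis and
# PERMANOVA.

#' Bray-Curtis distance matrix between samples
#'
#' `d(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i)`, zero for identical
#' columns and one for disjoint supports.
#'
#' @param x An `amf_table` or a non-negative count matrix with samples in
#'   columns (at least two, none all-zero).
#' @return A symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   labeled by sample.
#' @export
bray_curtis <- function(x) {
  counts <- if (inherits(x, "amf_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("need at least two samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero sample column")
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      num <- sum(abs(counts[, i] - counts[, j]))
      den <- sum(counts[, i] + counts[, j])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-0.5 * D^2`
#' followed by eigendecomposition. Axes are ordered by decreasing
#' eigenvalue; axes with non-positive eigenvalues are dropped from the
#' coordinates but all eigenvalues are reported. When `D` is
#' Euclidean-embeddable, pairwise distances between the returned
#' coordinates reproduce `D`.
#'
#' @param d A symmetric distance matrix (at least 3 points).
#' @return A list with `points` (samples x positive axes), `eig` (all
#'   eigenvalues) and `prop_explained` (share of the positive eigenvalue
#'   total per retained axis).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  keep <- seq_len(ncol(fit$points))
  pos <- eig[keep] > .Machine$double.eps^0.5 * max(abs(eig))
  points <- fit$points[, pos, drop = FALSE]
  colnames(points) <- paste0("Axis", seq_len(ncol(points)))
  pos_total <- sum(eig[eig > 0])
  list(points = points, eig = eig,
       prop_explained = eig[keep][pos] / pos_total)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance in the
#' sums-of-squared-distances formulation: with total sum of squares
#' `SS_T = sum_{i<j} d_ij^2 / n` and within-group `SS_W` computed the same
#' way inside each group, the pseudo-F is
#' `((SS_T - SS_W)/(a - 1)) / (SS_W/(n - a))` and `R^2 = 1 - SS_W/SS_T`.
#' The p-value is `(1 + #{permuted F >= observed F}) / (1 + n_perm)` under
#' random permutation of the group labels.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, one per row of `d`; at least two groups with
#'   at least two members each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list of class `permanova_result` with `F`, `R2`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups must match the distance matrix")
  a <- nlevels(groups)
  if (a < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  d2 <- d^2
  up <- upper.tri(d2)
  ss_total <- sum(d2[up]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  ssw <- ss_within(groups)
  ssa <- ss_total - ssw
  f_obs <- (ssa / (a - 1)) / (ssw / (n - a))
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    sswp <- ss_within(gp)
    fp <- ((ss_total - sswp) / (a - 1)) / (sswp / (n - a))
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  structure(list(F = f_obs, R2 = ssa / ss_total,
                 p = (1 + exceed) / (1 + n_perm), n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}
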