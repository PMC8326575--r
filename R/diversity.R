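# Alpha diversity: rarefaction curves, Shannon/Simpson indices, and
# group-difference tests.

#' Analytic rarefaction curve
#'
#' Expected richness at depth m for a sample with taxon counts `counts`
#' (total N): `E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))`, evaluated with
#' log binomial coefficients for numerical stability. At `m = N` the curve
#' equals the observed richness; at `m = 1` it equals 1.
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param depths Integer vector of subsampling depths, each between 1 and
#'   `sum(counts)`.
#' @return A data frame with columns `depth`, `richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  depths <- as.integer(round(depths))
  if (any(depths < 1) || any(depths > n_total)) {
    stop("depths must lie in [1, total count]")
  }
  rich <- vapply(depths, function(m) {
    sum(1 - exp(lchoose(n_total - counts, m) - lchoose(n_total, m)))
  }, numeric(1))
  data.frame(depth = depths, richness = rich)
}

#' Alpha diversity indices per sample
#'
#' Observed richness (taxa with positive count), Shannon entropy in natural
#' log units `H = -sum p_i ln p_i`, and the Gini-Simpson index
#' `1 - sum p_i^2`, with `p_i` the within-sample relative abundances. A
#' sample containing a single taxon has `H = 0` and Simpson 0.
#'
#' @param x An `amf_table`.
#' @return A data frame with one row per sample: the design columns plus
#'   `observed`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(x) {
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("all-zero sample column: ", colnames(x$counts)[totals == 0][1])
  }
  p <- sweep(x$counts, 2, totals, "/")
  shannon <- apply(p, 2, function(pi) { pi <- pi[pi > 0]; -sum(pi * log(pi)) })
  cbind(x$samples,
        data.frame(observed = colSums(x$counts > 0),
                   shannon = shannon,
                   simpson = 1 - colSums(p^2)))
}

#' Test an alpha-diversity index across groups
#'
#' Parametric mode is a one-way ANOVA F test; nonparametric mode is the
#' tie-corrected Kruskal-Wallis rank-sum test.
#'
#' @param values Numeric vector of per-replicate index values.
#' @param groups Group labels, same length as `values`; at least two groups
#'   with at least two values each.
#' @param mode `"parametric"` or `"nonparametric"`.
#' @return A list with `statistic`, `p` and `method`.
#' @export
alpha_group_test <- function(values, groups,
                             mode = c("parametric", "nonparametric")) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  if (mode == "parametric") {
    a <- anova(lm(values ~ groups))
    f <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
    ss <- a[["Sum Sq"]]
    # identical group means (up to rounding noise): no effect by definition
    tol <- 1e-12 * (sum(ss) + sum(values^2) + 1)
    if (ss[1] <= tol) { f <- 0; p <- 1 }
    list(statistic = f, p = p, method = "one-way ANOVA")
  } else {
    k <- kruskal.test(values, groups)
    list(statistic = unname(k$statistic), p = k$p.value,
         method = "Kruskal-Wallis")
  }
}
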