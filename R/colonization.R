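# Trouvelot scoring of mycorrhizal root colonization.

MYC_WEIGHTS <- c(0, 1, 5, 30, 70, 95)   # colonization class 0..5
ARB_WEIGHTS <- c(0, 10, 50, 100)        # arbuscule/vesicle class 0..3

#' Trouvelot colonization indices for one root system
#'
#' Thirty (or any number of) 1-cm root fragments are each scored with a
#' colonization class 0-5 (`myc_class`; class 5 means more than 90% of the
#' cortex colonized) and arbuscule and vesicle richness classes 0-3
#' (`arb_class`, `ves_class`). With `n_k` fragments in colonization class k
#' and N fragments in total, the indices are:
#' frequency `F = 100 (N - n_0) / N`;
#' intensity of colonization in the root system
#' `M = (95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1) / N`;
#' intensity in the colonized fragments `m = M N / (N - n_0)`;
#' arbuscule richness in the colonized parts
#' `a = (100 mA3 + 50 mA2 + 10 mA1) / 100`, where `mAj` is the percentage
#' of `m` contributed by fragments of arbuscule class j; and arbuscule
#' abundance in the root system `A = a M / 100`. Vesicle indices `v`, `V`
#' use the same machinery on `ves_class`. All indices lie in `[0, 100]`
#' and `M` is capped at 95 by the class-5 weight.
#'
#' @param fragments Data frame with integer columns `myc_class` (0-5),
#'   `arb_class` and `ves_class` (0-3); a fragment with `myc_class = 0`
#'   must have both other classes 0.
#' @return A list of class `colonization_result` with `F_pct`, `M_pct`,
#'   `m_pct`, `a_pct`, `A_pct`, `v_pct`, `V_pct`, `n_fragments`.
#' @examples
#' all5 <- data.frame(myc_class = rep(5, 30), arb_class = 3, ves_class = 0)
#' colonization_indices(all5)$M_pct  # 95
#' @export
colonization_indices <- function(fragments) {
  if (nrow(fragments) == 0) stop("need at least one fragment")
  myc <- as.integer(fragments$myc_class)
  arb <- as.integer(fragments$arb_class)
  ves <- as.integer(fragments$ves_class)
  if (any(myc < 0L | myc > 5L)) stop("myc_class must be in 0..5")
  if (any(arb < 0L | arb > 3L) || any(ves < 0L | ves > 3L)) {
    stop("arb_class and ves_class must be in 0..3")
  }
  if (any(myc == 0L & (arb > 0L | ves > 0L))) {
    stop("an uncolonized fragment (myc_class 0) cannot carry arbuscules or vesicles")
  }
  n <- length(myc)
  n0 <- sum(myc == 0L)
  w <- MYC_WEIGHTS[myc + 1L]
  f_pct <- 100 * (n - n0) / n
  m_big <- sum(w) / n
  m_small <- if (n > n0) m_big * n / (n - n0) else 0
  richness <- function(cls) {
    if (m_small == 0) return(0)
    m_contrib <- vapply(1:3, function(j) {
      100 * sum(w[cls == j]) / (n - n0) / m_small
    }, numeric(1))
    sum(ARB_WEIGHTS[2:4] * m_contrib) / 100
  }
  a_pct <- richness(arb)
  v_pct <- richness(ves)
  structure(list(F_pct = f_pct, M_pct = m_big, m_pct = m_small,
                 a_pct = a_pct, A_pct = a_pct * m_big / 100,
                 v_pct = v_pct, V_pct = v_pct * m_big / 100,
                 n_fragments = n),
            class = "colonization_result")
}

#' @export
print.colonization_result <- function(x, ...) {
  cat(sprintf(
    "Colonization (%d fragments): F = %.1f%%  M = %.1f%%  m = %.1f%%  A = %.1f%%  V = %.1f%%\n",
    x$n_fragments, x$F_pct, x$M_pct, x$m_pct, x$A_pct, x$V_pct))
  invisible(x)
}

#' Tabulate per-plant colonization results
#'
#' @param results A list of `colonization_result` objects (one per plant).
#' @param plant_id Optional plant identifiers.
#' @return A data frame with one row per plant and the index columns.
#' @export
colonization_table <- function(results, plant_id = NULL) {
  if (is.null(plant_id)) plant_id <- paste0("plant_", seq_along(results))
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(F_pct = r$F_pct, M_pct = r$M_pct, m_pct = r$m_pct,
               a_pct = r$a_pct, A_pct = r$A_pct, v_pct = r$v_pct,
               V_pct = r$V_pct)
  }))
  cbind(data.frame(plant_id = plant_id, stringsAsFactors = FALSE), df)
}

#' Compare colonization indices between two groups of plants
#'
#' One-way ANOVA per index (frequency F, intensity M, arbuscule abundance
#' A, vesicle abundance V) across the two groups, typically the two
#' sampling times, with group means and standard deviations.
#'
#' @param results_a,results_b Data frames from [colonization_table()], one
#'   row per plant; at least two plants per group.
#' @param indices Index columns to compare.
#' @return A data frame with one row per index: means, SDs, the ANOVA F
#'   statistic and its p-value.
#' @export
colonization_compare <- function(results_a, results_b,
                                 indices = c("F_pct", "M_pct", "A_pct", "V_pct")) {
  if (nrow(results_a) < 2 || nrow(results_b) < 2) {
    stop("need at least two plants per group")
  }
  out <- lapply(indices, function(ix) {
    va <- results_a[[ix]]; vb <- results_b[[ix]]
    vals <- c(va, vb)
    grp <- factor(rep(c("A", "B"), c(length(va), length(vb))))
    a <- anova(lm(vals ~ grp))
    f <- a[["F value"]][1]; p <- a[["Pr(>F)"]][1]
    ss <- a[["Sum Sq"]]
    tol <- 1e-12 * (sum(ss) + sum(vals^2) + 1)
    if (ss[1] <= tol) { f <- 0; p <- 1 }
    data.frame(index = ix, mean_a = mean(va), sd_a = sd(va),
               mean_b = mean(vb), sd_b = sd(vb),
               F = f, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
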