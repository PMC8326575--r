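# Read quality control: the three discard rules, applied in fixed order.

#' Quality-filter reads
#'
#' A read passes when all three hold: length at least `min_len`, arithmetic
#' mean Phred score at least `min_mean_q`, and no base outside `A,C,G,T`.
#' Discarded reads are attributed to the first failing rule in the order
#' length, quality, ambiguity, so the per-reason counts sum to the input
#' count. Thresholds use strict "less than" for discarding: a read of
#' length exactly `min_len` or mean quality exactly `min_mean_q` passes.
#'
#' @param reads A read data frame ([reads_frame()]).
#' @param min_len Minimum read length in bases (default 200).
#' @param min_mean_q Minimum mean Phred score (default 25).
#' @return A list with `passed` (read data frame) and `report`, a
#'   `qc_report` with fields `n_input`, `n_passed`, `n_short`, `n_lowq`,
#'   `n_ambiguous`.
#' @export
filter_reads <- function(reads, min_len = 200, min_mean_q = 25) {
  if (min_len < 0 || min_mean_q < 0) stop("QC thresholds must be non-negative")
  len <- nchar(reads$bases)
  mean_q <- vapply(reads$quals,
                   function(qq) if (length(qq)) mean(qq) else 0, numeric(1))
  ambiguous <- grepl("[^ACGT]", toupper(reads$bases))
  short <- len < min_len
  lowq <- !short & mean_q < min_mean_q
  ambig <- !short & !lowq & ambiguous
  passed <- !(short | lowq | ambig)
  report <- qc_report(n_input = nrow(reads), n_passed = sum(passed),
                      n_short = sum(short), n_lowq = sum(lowq),
                      n_ambiguous = sum(ambig))
  list(passed = reads[passed, , drop = FALSE], report = report)
}

#' @rdname filter_reads
#' @param n_input,n_passed,n_short,n_lowq,n_ambiguous Non-negative counts;
#'   `n_input` must equal the sum of the other four.
#' @export
qc_report <- function(n_input, n_passed, n_short, n_lowq, n_ambiguous) {
  r <- list(n_input = as.integer(n_input), n_passed = as.integer(n_passed),
            n_short = as.integer(n_short), n_lowq = as.integer(n_lowq),
            n_ambiguous = as.integer(n_ambiguous))
  if (any(unlist(r) < 0L)) stop("QC counts must be non-negative")
  if (r$n_input != r$n_passed + r$n_short + r$n_lowq + r$n_ambiguous) {
    stop("QC counts do not sum to n_input")
  }
  structure(r, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC report\n")
  cat(sprintf("  input: %d  passed: %d\n", x$n_input, x$n_passed))
  cat(sprintf("  discarded - short: %d  low quality: %d  ambiguous: %d\n",
              x$n_short, x$n_lowq, x$n_ambiguous))
  invisible(x)
}
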