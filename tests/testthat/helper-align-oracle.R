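# Independent brute-force local-alignment oracle: full O(nm) affine-gap
# dynamic program in plain R, with the documented tie-break contract
# (earliest best end cell; diagonal predecessor preference M > X > Y >
# local start; gap opening preferred over extension on ties).

sw_oracle <- function(query, subject, scoring = align_scoring()) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(s)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1)
  Y <- matrix(neg, n + 1, m + 1)
  go <- scoring$gap_open + scoring$gap_extend
  ge <- scoring$gap_extend
  best <- 0; bi <- 0; bj <- 0; bst <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (q[i] == s[j]) scoring$match else scoring$mismatch
      db <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- db + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] + go, X[i, j + 1] + ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go, Y[i + 1, j] + ge)
      v <- max(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
      if (v > best) {
        best <- v; bi <- i; bj <- j
        bst <- which(c(M[i + 1, j + 1], X[i + 1, j + 1],
                       Y[i + 1, j + 1]) == v)[1]
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, q_start = 0, q_end = 0, s_start = 0, s_end = 0,
                matches = 0, columns = 0, identity = 0, coverage = 0))
  }
  i <- bi; j <- bj; st <- bst
  matches <- 0L; columns <- 0L; q_start <- NA; s_start <- NA
  repeat {
    if (st == 1) {
      columns <- columns + 1L
      if (q[i] == s[j]) matches <- matches + 1L
      sub <- if (q[i] == s[j]) scoring$match else scoring$mismatch
      db <- M[i + 1, j + 1] - sub
      p <- if (db == M[i, j]) 1 else if (db == X[i, j]) 2 else
        if (db == Y[i, j]) 3 else 0
      i <- i - 1; j <- j - 1
      if (p == 0) { q_start <- i + 1; s_start <- j + 1; break }
      st <- p
    } else if (st == 2) {
      columns <- columns + 1L
      st <- if (X[i + 1, j + 1] == M[i, j + 1] + go) 1 else 2
      i <- i - 1
    } else {
      columns <- columns + 1L
      st <- if (Y[i + 1, j + 1] == M[i + 1, j] + go) 1 else 3
      j <- j - 1
    }
  }
  list(score = best, q_start = q_start, q_end = bi, s_start = s_start,
       s_end = bj, matches = matches, columns = columns,
       identity = 100 * matches / columns,
       coverage = 100 * (bi - q_start + 1) / n)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
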