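# Independent oracles used across the suite. Everything here is deliberately
# naive (brute force, full-matrix DP, exhaustive enumeration) and shares no
# code with the package internals it checks.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# all 1-based start positions of `pattern` in `text` (overlapping, exact)
naive_occurrences <- function(text, pattern) {
  if (nchar(pattern) == 0L) return(seq_len(nchar(text)))
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# suffix array by sorting explicit suffix strings (1-based)
naive_suffix_array <- function(text) {
  n <- nchar(text)
  suf <- vapply(seq_len(n), function(i) substr(text, i, n), character(1))
  order(suf, method = "radix")
}

# BWT as the last column of the sorted rotations
rotation_bwt <- function(text) {
  n <- nchar(text)
  dbl <- paste0(text, text)
  rot <- vapply(seq_len(n), function(i) substr(dbl, i, i + n - 1L), character(1))
  paste(substr(sort(rot, method = "radix"), n, n), collapse = "")
}

# invert a BWT via the LF mapping: stable-sorting the last column gives the
# first column, and LF(i) is the first-column row of the character at last-
# column row i; walking LF from the sentinel row spells the text backwards
lf_inverse_bwt <- function(bwt) {
  ch <- strsplit(bwt, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ord <- order(ch, method = "radix")   # stable: preserves occurrence ranks
  LF <- integer(n)
  LF[ord] <- seq_len(n)
  out <- character(n)
  out[n] <- "$"
  r <- 1L  # the rotation starting with '$' sorts first
  for (k in seq(n - 1L, 1L)) {
    out[k] <- ch[r]
    r <- LF[r]
  }
  paste(out, collapse = "")
}

# maximal l such that substr(query, start, start+l-1) occurs in text
naive_longest_match <- function(text, query, start) {
  m <- nchar(query)
  l <- 0L
  while (start + l <= m) {
    p <- substr(query, start, start + l)
    if (length(naive_occurrences(text, p)) == 0L) break
    l <- l + 1L
  }
  l
}

# Full-matrix Gotoh oracle, unbanded, same cost model and tie preference
# (match/mismatch over read-insertion over deletion) as the package, with
# optional cost-free reference overhang at either end. Rows vectorised; the
# in-row dependence of the deletion state is solved with a cummin recurrence.
oracle_gotoh <- function(a, b, mis = 1, go = 1, ge = 1,
                         free_lead = FALSE, free_trail = FALSE) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A); lb <- length(B)
  INF <- 1e9
  M <- matrix(INF, la + 1, lb + 1)
  X <- matrix(INF, la + 1, lb + 1)
  Y <- matrix(INF, la + 1, lb + 1)
  M[1, 1] <- 0
  if (la > 0) X[seq(2, la + 1), 1] <- go + seq_len(la) * ge
  if (lb > 0) {
    if (free_lead) M[1, seq(2, lb + 1)] <- 0
    else Y[1, seq(2, lb + 1)] <- go + seq_len(lb) * ge
  }
  if (la > 0) for (i in seq(2, la + 1)) {
    if (lb > 0) {
      sub <- ifelse(A[i - 1] == B, 0, mis)
      prev <- pmin(M[i - 1, seq_len(lb)], X[i - 1, seq_len(lb)], Y[i - 1, seq_len(lb)])
      M[i, seq(2, lb + 1)] <- ifelse(prev < INF, prev + sub, INF)
    }
    xo <- pmin(M[i - 1, ], Y[i - 1, ])
    X[i, ] <- pmin(ifelse(xo < INF, xo + go + ge, INF),
                   ifelse(X[i - 1, ] < INF, X[i - 1, ] + ge, INF))
    w <- pmin(M[i, ], X[i, ])
    # Y[i, j] = go + (j - j') * ge + w[j'] minimised over j' < j
    shifted <- c(INF, (w - (0:lb) * ge)[seq_len(lb)])
    Y[i, ] <- pmin(go + (0:lb) * ge + cummin(shifted), INF)
  }
  ej <- lb + 1L
  if (free_trail) {
    fin <- pmin(M[la + 1, ], X[la + 1, ], Y[la + 1, ])
    ej <- which.min(fin)  # smallest j on ties
  }
  vals <- c(M[la + 1, ej], X[la + 1, ej], Y[la + 1, ej])
  state <- which.min(vals)  # preference M, X, Y
  cost <- vals[state]
  # traceback
  ops <- character(0)
  i <- la + 1L; j <- ej
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      if (i == 1L) break  # free leading overhang
      sub <- if (A[i - 1] == B[j - 1]) 0 else mis
      ops <- c(if (sub == 0) "=" else "X", ops)
      want <- M[i, j] - sub
      i <- i - 1L; j <- j - 1L
      state <- which(c(M[i, j], X[i, j], Y[i, j]) == want)[1]
      if (i == 1L && j > 1L && state == 1L && free_lead) break
    } else if (state == 2L) {
      ops <- c("I", ops)
      want <- X[i, j]
      i <- i - 1L
      state <- if (M[i, j] < INF && M[i, j] + go + ge == want) 1L
               else if (X[i, j] < INF && X[i, j] + ge == want) 2L else 3L
    } else {
      ops <- c("D", ops)
      want <- Y[i, j]
      j <- j - 1L
      state <- if (M[i, j] < INF && M[i, j] + go + ge == want) 1L
               else if (X[i, j] < INF && X[i, j] + ge == want) 2L else 3L
    }
  }
  ops <- paste(ops, collapse = "")
  list(cost = cost, ops = ops,
       errors = sum(strsplit(ops, "")[[1]] %in% c("X", "I", "D")))
}

# exhaustive consecutive-partition chaining: every way of cutting the sorted
# occurrence list into consecutive blocks; a partition is valid when every
# adjacent pair inside every block is coherent; the greedy (leftmost-maximal)
# valid partition is returned
enumerate_greedy_partition <- function(n, coherent_pair) {
  # coherent_pair(i, j): occurrences i and j (adjacent in sorted order)
  blocks <- list()
  start <- 1L
  k <- 1L
  while (k <= n) {
    if (k < n && coherent_pair(k, k + 1L)) {
      k <- k + 1L
    } else {
      blocks[[length(blocks) + 1L]] <- seq(start, k)
      k <- k + 1L
      start <- k
    }
  }
  blocks
}

all_consecutive_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  recurse <- function(start, acc) {
    if (start > n) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (end in start:n) recurse(end + 1L, c(acc, list(seq(start, end))))
  }
  recurse(1L, list())
  out
}

expect_valid_edit_path <- function(ops, read_len) {
  o <- strsplit(ops, "")[[1]]
  testthat::expect_equal(sum(o %in% c("=", "X", "I")), read_len)
}
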