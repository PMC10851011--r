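# Independent affine-gap alignment oracle: exhaustive recursion over the
# three alignment states with memoisation, sharing only the scoring
# convention (gap of length L costs gap_open + (L - 1) * gap_extend) with
# the package implementation, not its code path.
oracle_align_score <- function(ref, read, match = 2, mismatch = -3,
                               gap_open = -8, gap_extend = -1) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(read, "")[[1]]
  m <- length(r)
  n <- length(q)
  memo <- array(NA_real_, dim = c(m + 1L, n + 1L, 3L))
  rec <- function(i, j, s) {
    v <- memo[i + 1L, j + 1L, s]
    if (!is.na(v)) return(v)
    val <-
      if (s == 1L) {            # diagonal: consume one base of each
        if (i < 1L || j < 1L) -Inf
        else (if (r[i] == q[j]) match else mismatch) + best(i - 1L, j - 1L)
      } else if (s == 2L) {     # gap consuming ref
        if (i < 1L) -Inf
        else max(rec(i - 1L, j, 2L) + gap_extend,
                 best_except(i - 1L, j, 2L) + gap_open)
      } else {                  # gap consuming read
        if (j < 1L) -Inf
        else max(rec(i, j - 1L, 3L) + gap_extend,
                 best_except(i, j - 1L, 3L) + gap_open)
      }
    memo[i + 1L, j + 1L, s] <<- val
    val
  }
  best <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    max(rec(i, j, 1L), rec(i, j, 2L), rec(i, j, 3L))
  }
  best_except <- function(i, j, s) {
    if (i == 0L && j == 0L) return(0)
    out <- -Inf
    for (t in (1:3)[-s]) out <- max(out, rec(i, j, t))
    out
  }
  best(m, n)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
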