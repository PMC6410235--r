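# Independent alignment oracles, deliberately implemented along different
# routes than the package aligner: a bottom-up *global* affine DP applied
# to every subject substring (semi-global = best fully-consumed substring),
# and, for very small inputs, full enumeration of alignment paths.

oracle_subst <- function(a, b, scheme) {
  if (a == "N" || b == "N") return(0L)
  if (a == b) scheme$match else scheme$mismatch
}

# global affine alignment score, both sequences consumed end to end
oracle_global_score <- function(p, s, scheme) {
  n <- nchar(p); m <- nchar(s)
  pb <- strsplit(p, "", fixed = TRUE)[[1]]
  sb <- strsplit(s, "", fixed = TRUE)[[1]]
  NEG <- -1e9
  gap <- function(L) if (L == 0) 0 else scheme$gap_open +
    (L - 1) * scheme$gap_extend
  if (n == 0) return(gap(m))
  if (m == 0) return(gap(n))
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap(i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- gap(j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- oracle_subst(pb[i - 1], sb[j - 1], scheme)
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] + scheme$gap_open,
                     X[i - 1, j] + scheme$gap_extend,
                     Y[i - 1, j] + scheme$gap_open)
      Y[i, j] <- max(M[i, j - 1] + scheme$gap_open,
                     Y[i, j - 1] + scheme$gap_extend,
                     X[i, j - 1] + scheme$gap_open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# semi-global score = best global score over all subject substrings
# (including the empty substring: the all-gap alignment)
oracle_semiglobal_score <- function(p, s, scheme) {
  m <- nchar(s)
  best <- oracle_global_score(p, "", scheme)
  for (a in 1:m) for (b in a:m) {
    sc <- oracle_global_score(p, substr(s, a, b), scheme)
    if (sc > best) best <- sc
  }
  best
}

# exhaustive enumeration of all alignment paths (tiny inputs only)
enum_global_score <- function(p, s, scheme) {
  n <- nchar(p); m <- nchar(s)
  pb <- strsplit(p, "", fixed = TRUE)[[1]]
  sb <- strsplit(s, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      v <- oracle_subst(pb[i], sb[j], scheme) + rec(i + 1, j + 1, "M")
      if (v > best) best <- v
    }
    if (i <= n) {
      cost <- if (last == "X") scheme$gap_extend else scheme$gap_open
      v <- cost + rec(i + 1, j, "X")
      if (v > best) best <- v
    }
    if (j <= m) {
      cost <- if (last == "Y") scheme$gap_extend else scheme$gap_open
      v <- cost + rec(i, j + 1, "Y")
      if (v > best) best <- v
    }
    best
  }
  rec(1, 1, "M")
}

enum_semiglobal_score <- function(p, s, scheme) {
  m <- nchar(s)
  best <- enum_global_score(p, "", scheme)
  for (a in 1:m) for (b in a:m) {
    sc <- enum_global_score(p, substr(s, a, b), scheme)
    if (sc > best) best <- sc
  }
  best
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
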