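# Independent oracles used to verify the package implementations.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force global alignment score by quadratic DP with an explicit gap
# length function (no affine three-state shortcut): a gap of length k costs
# gap_open + k * gap_extend. Supports free end gaps.
oracle_align_score <- function(a, b, match = 5, mismatch = -4, gap_open = 12,
                               gap_extend = 3, free_end_gaps = TRUE) {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  gapc <- function(k) gap_open + k * gap_extend
  G <- matrix(-Inf, n + 1, m + 1)
  G[1, 1] <- 0
  for (i in 1:(n + 1)) for (j in 1:(m + 1)) {
    if (i == 1 && j == 1) next
    best <- -Inf
    if (i > 1 && j > 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      best <- max(best, G[i - 1, j - 1] + s)
    }
    if (i > 1) for (k in 1:(i - 1)) {
      pen <- if (free_end_gaps && (j == 1 || j == m + 1)) 0 else gapc(k)
      best <- max(best, G[i - k, j] - pen)
    }
    if (j > 1) for (k in 1:(j - 1)) {
      pen <- if (free_end_gaps && (i == 1 || i == n + 1)) 0 else gapc(k)
      best <- max(best, G[i, j - k] - pen)
    }
    G[i, j] <- best
  }
  G[n + 1, m + 1]
}

# Direct Jensen-Shannon divergence by summation over the feature union.
oracle_jsd <- function(counts_a, counts_b) {
  feats <- union(names(counts_a), names(counts_b))
  pa <- setNames(numeric(length(feats)), feats)
  pb <- pa
  pa[names(counts_a)] <- counts_a / sum(counts_a)
  pb[names(counts_b)] <- counts_b / sum(counts_b)
  m <- (pa + pb) / 2
  s <- 0
  for (f in feats) {
    if (pa[f] > 0) s <- s + 0.5 * pa[f] * log(pa[f] / m[f])
    if (pb[f] > 0) s <- s + 0.5 * pb[f] * log(pb[f] / m[f])
  }
  unname(s)
}

# Exhaustive minimum-cost perfect matching (all permutations), n <= 7.
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# Exhaustive Matching Splits between two split matrices (rows = splits over
# a common sorted leaf order), with dummy padding at the smaller side size.
oracle_matching_splits <- function(s1, s2, n) {
  n1 <- nrow(s1); n2 <- nrow(s2)
  k <- max(n1, n2)
  if (k == 0) return(0)
  cost <- matrix(0, k, k)
  if (n1 && n2) {
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      d <- sum(xor(s1[i, ], s2[j, ]))
      cost[i, j] <- min(d, n - d)
    }
  }
  minside <- function(m) pmin(rowSums(m), n - rowSums(m))
  if (n1 < k) for (j in seq_len(n2)) cost[(n1 + 1):k, j] <- minside(s2)[j]
  if (n2 < k) for (i in seq_len(n1)) cost[i, (n2 + 1):k] <- minside(s1)[i]
  oracle_assignment(cost)
}

# realise one concrete instance of a degenerate IUPAC string (first base of
# each degeneracy set)
realise_iupac <- function(s) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
               W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A",
               N = "A")
  paste(unlist(sets[strsplit(s, "")[[1]]]), collapse = "")
}
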