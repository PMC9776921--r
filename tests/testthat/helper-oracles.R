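# Independent brute-force oracles. Each is a direct transcription of the
# defining formula, kept deliberately naive (loops, enumerations) and
# separate from the package's implementation paths.

# O(n^3) topological overlap by triple loop
bf_tom <- function(adj) {
  n <- nrow(adj)
  out <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(adj[i, ])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + adj[i, u] * adj[u, j]
    out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# BH adjustment as min over tails of p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# GSEA running-sum ES by explicit position-by-position walk; on a
# magnitude tie the positive extremum is reported (the stated convention)
bf_es <- function(gene_ids, metric, members, weight) {
  N <- length(gene_ids)
  hit <- gene_ids %in% members
  nh <- sum(hit)
  w <- abs(metric)^weight
  tot <- sum(w[hit])
  rs <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    rs <- if (hit[i]) {
      rs + (if (tot > 0) w[i] / tot else 1 / nh)
    } else rs - 1 / (N - nh)
    if (rs > hi) hi <- rs
    if (rs < lo) lo <- rs
  }
  if (hi + lo >= -1e-9) hi else lo
}

# hypergeometric upper tail P[X >= k] via explicit choose() summation
bf_hyper_tail <- function(N, K, n, k) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  total <- 0
  for (x in k:kmax) {
    if (n - x > N - K) next
    total <- total + choose(K, x) * choose(N - K, n - x)
  }
  total / choose(N, n)
}

# AUC by all-pairs concordance with half credit for ties
bf_auc <- function(scores, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
    else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
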