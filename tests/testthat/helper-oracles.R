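# Independent brute-force oracles. These deliberately share no code with
# the implementation: explicit loops, table()-based counting, full
# enumeration.

# quantile normalization by explicit sort/argsort bookkeeping (no ties)
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Shannon entropy of a window via table()
oracle_entropy <- function(chars) {
  chars <- chars[chars != "X"]
  if (!length(chars)) return(NA_real_)
  p <- as.vector(table(chars)) / length(chars)
  -sum(p * log2(p))
}

# low-complexity detection by exhaustive per-trigger scanning: every
# trigger window is extended one window at a time; spans merged pairwise
oracle_seg <- function(seq, W = 12, locut = 2.2, hicut = 2.5) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < W) return(cbind(start = integer(0), end = integer(0)))
  h <- sapply(1:(L - W + 1), function(i) oracle_entropy(chars[i:(i + W - 1)]))
  spans <- NULL
  for (i in which(!is.na(h) & h <= locut)) {
    lo <- i
    while (lo > 1 && !is.na(h[lo - 1]) && h[lo - 1] <= hicut) lo <- lo - 1
    hi <- i
    while (hi < length(h) && !is.na(h[hi + 1]) && h[hi + 1] <= hicut) hi <- hi + 1
    spans <- rbind(spans, c(lo - 1L, hi - 1L + W))
  }
  if (is.null(spans)) return(cbind(start = integer(0), end = integer(0)))
  spans <- unique(spans)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    k <- nrow(merged)
    if (spans[i, 1] < merged[k, 2]) merged[k, 2] <- max(merged[k, 2], spans[i, 2])
    else merged <- rbind(merged, spans[i, ])
  }
  colnames(merged) <- c("start", "end")
  merged
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
oracle_mw_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[1:m]) - m * (m + 1) / 2
  combos <- combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(sort(r)[idx]) - m * (m + 1) / 2)
  lo <- min(u_obs, m * n - u_obs)
  min(1, 2 * mean(u_all <= lo))
}

# permutation p for the Welch t statistic
oracle_t_perm <- function(x, y, n_perm = 1e4, seed = 99) {
  set.seed(seed)
  welch <- function(a, b)
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  t_obs <- abs(welch(x, y))
  pooled <- c(x, y); m <- length(x)
  hits <- replicate(n_perm, {
    idx <- sample(length(pooled), m)
    abs(welch(pooled[idx], pooled[-idx])) >= t_obs
  })
  mean(hits)
}

# upper-tail hypergeometric p by summing pmf terms
oracle_hyper_upper <- function(k, set_size, universe_size, query_size) {
  i <- k:min(set_size, query_size)
  sum(choose(set_size, i) * choose(universe_size - set_size, query_size - i)) /
    choose(universe_size, query_size)
}

# Benjamini-Hochberg by direct step-up minimization
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[o[i]] <- min(1, min(p[o[j]] * m / j))
  }
  q
}

# rank-based AUROC
auroc <- function(score, is_pos) {
  r <- rank(score)
  (sum(r[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2) /
    (sum(is_pos) * sum(!is_pos))
}
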