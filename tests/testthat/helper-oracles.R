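# Independent brute-force oracles; deliberately naive and separate from the
# implementation paths they check.

# position-by-position rescoring of one sequence, both strands
naive_scan <- function(seq_string, pwm, background, cutoff) {
  bases <- strsplit(seq_string, "")[[1]]
  lo <- log2(sweep(pwm$probs, 2, background, "/"))
  L <- nrow(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  res <- list()
  for (p in seq_len(length(bases) - L + 1)) {
    win <- bases[p:(p + L - 1)]
    if (any(!win %in% names(comp))) next
    s_fwd <- sum(lo[cbind(seq_len(L), match(win, colnames(lo)))])
    rc <- rev(unname(comp[win]))
    s_rev <- sum(lo[cbind(seq_len(L), match(rc, colnames(lo)))])
    if (s_fwd >= cutoff)
      res[[length(res) + 1]] <- data.frame(start = p - 1L, strand = "+",
                                           score = s_fwd)
    if (s_rev >= cutoff)
      res[[length(res) + 1]] <- data.frame(start = p - 1L, strand = "-",
                                           score = s_rev)
  }
  if (!length(res))
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, res)
}

# exhaustive max log-odds score over all 4^L words
brute_max_score <- function(pwm, background) {
  lo <- log2(sweep(pwm$probs, 2, background, "/"))
  L <- nrow(lo)
  words <- do.call(expand.grid, rep(list(1:4), L))
  max(apply(words, 1, function(w) sum(lo[cbind(seq_len(L), w)])))
}

# connected components of the 1-bp-overlap interval graph (brute force)
interval_components <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (start[i] < end[j] && start[j] < end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# exact two-sided rank-sum p-value by bitmask enumeration
ranksum_exact_oracle <- function(x, y) {
  n <- length(x) + length(y)
  nA <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nA)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != nA) next
    ws <- c(ws, sum(r[sel]))
  }
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# squared Mahalanobis distance from the column mean (covariance oracle)
mahalanobis_t2 <- function(X) {
  stats::mahalanobis(X, colMeans(X), stats::cov(X))
}
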