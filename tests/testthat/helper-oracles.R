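# Independent oracle implementations, deliberately written in the most
# literal (slow) form so they share no code with the package internals.

# Exact two-sided paired Wilcoxon signed-rank p-value by exhaustive
# enumeration of all 2^n sign assignments (n = nonzero differences).
wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.numeric(signs %*% r)
  p_le <- mean(V <= v)
  p_ge <- mean(V >= v)
  min(1, 2 * min(p_le, p_ge))
}

# Literal Benjamini-Hochberg step-up recomputation.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Brute-force k-nearest-neighbour imputation: per-pair distance is the root
# mean squared difference over jointly observed samples; the k nearest CpGs
# observed at the target sample contribute an inverse-distance-weighted
# average; ties broken by CpG index; fallback = column mean.
knn_bruteforce <- function(m, k) {
  out <- m
  p <- ncol(m)
  cm <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(p)) {
    rows <- which(is.na(m[, j]))
    if (length(rows) == 0) next
    d <- rep(NA_real_, p)
    for (l in seq_len(p)) {
      if (l == j) next
      sh <- which(!is.na(m[, j]) & !is.na(m[, l]))
      if (length(sh) == 0) next
      d[l] <- sqrt(mean((m[sh, j] - m[sh, l])^2))
    }
    ord <- setdiff(order(d, seq_len(p), na.last = NA), j)
    for (i in rows) {
      cand <- ord[!is.na(m[i, ord])]
      if (length(cand) == 0) {
        out[i, j] <- cm[j]
      } else {
        nb <- cand[seq_len(min(k, length(cand)))]
        w <- 1 / pmax(d[nb], 1e-12)
        out[i, j] <- sum(w * m[i, nb]) / sum(w)
      }
    }
  }
  out
}

# A beta-scale matrix with values strictly inside (0, 1).
random_beta_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  methyl_matrix(matrix(runif(n * p, 0.02, 0.98), n, p), scale = "beta")
}

# Rank-1 positive fixture inside the beta range with `n_mask` masked entries.
rank1_fixture <- function(n = 20, p = 30, n_mask = 3, seed = 1) {
  set.seed(seed)
  u <- runif(n, 0.6, 1)
  v <- runif(p, 0.5, 0.9)
  full <- outer(u, v)
  idx <- sample.int(n * p, n_mask)
  masked <- full
  masked[idx] <- NA
  list(full = full, masked = methyl_matrix(masked, scale = "beta"), idx = idx)
}
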