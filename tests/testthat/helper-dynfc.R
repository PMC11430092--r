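# Shared fixtures and independent oracles, all built in code.

# small 21-parcel atlas (3 parcels per network) for fast simulations
small_atlas <- function() parcel_atlas(21L, network_sizes = rep(3L, 7L))

# independent Gaussian-HMM sampler (oracle-side generator for state-model
# tests; deliberately not using the package's envelope generator)
sample_gauss_hmm <- function(T, pi0, A, means, sds, seed) {
  set.seed(seed)
  K <- length(pi0)
  d <- ncol(means)
  s <- integer(T)
  s[1] <- sample.int(K, 1, prob = pi0)
  for (t in 2:T) s[t] <- sample.int(K, 1, prob = A[s[t - 1], ])
  X <- matrix(rnorm(T * d), T, d) * sds[s] + means[s, , drop = FALSE]
  list(X = X, states = s)
}

# map decoded labels onto true labels by majority vote and return accuracy
label_match_accuracy <- function(decoded, truth) {
  tab <- table(factor(decoded, levels = sort(unique(decoded))), truth)
  sum(apply(tab, 2, max)) / length(truth)
}

# brute-force temporal-feature oracles (straight counting loops)
bf_occupancy <- function(s, K) {
  out <- numeric(K)
  for (x in s) out[x] <- out[x] + 1
  out / length(s)
}
bf_lifetime <- function(s, K, fs) {
  runs <- list()
  start <- 1
  for (t in seq_along(s)[-1]) {
    if (s[t] != s[t - 1]) {
      runs[[length(runs) + 1]] <- c(s[start], t - start)
      start <- t
    }
  }
  runs[[length(runs) + 1]] <- c(s[start], length(s) - start + 1)
  out <- rep(NA_real_, K)
  for (k in 1:K) {
    lens <- vapply(runs, function(r) if (r[1] == k) r[2] else NA_real_,
                   numeric(1))
    lens <- lens[!is.na(lens)]
    if (length(lens)) out[k] <- mean(lens) / fs
  }
  out
}
bf_interval <- function(s, K, fs) {
  out <- rep(NA_real_, K)
  for (k in 1:K) {
    inside <- s == k
    starts <- which(inside & !c(FALSE, inside[-length(inside)]))
    ends <- which(inside & !c(inside[-1], FALSE))
    if (length(starts) >= 2)
      out[k] <- mean(starts[-1] - ends[-length(ends)] - 1) / fs
  }
  out
}
bf_transitions <- function(s, K, include_self = TRUE) {
  m <- matrix(0, K, K)
  for (t in seq_along(s)[-1]) m[s[t - 1], s[t]] <- m[s[t - 1], s[t]] + 1
  if (!include_self) diag(m) <- 0
  rs <- rowSums(m)
  out <- m / rs
  out[rs == 0, ] <- NA_real_
  out
}

# direct Benjamini-Hochberg step-up oracle
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided Mann-Whitney p by exhaustive enumeration (n1 + n2 small)
bf_exact_p <- function(U, n1, n2) {
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  lo <- min(U, n1 * n2 - U)
  min(1, 2 * mean(us <= lo))
}
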