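# Naive reference implementations, written independently of the package
# internals (plain loops, no shared vectorization), used as oracles.

# bare components of a hypervector, attributes stripped
comps <- function(x) as.vector(unclass(x))

naive_nearest <- function(mat, query, mode) {
  d <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    d[i] <- if (mode == "hamming") sum(mat[i, ] != query) else sum(mat[i, ] * query)
  }
  best <- if (mode == "hamming") min(d) else max(d)
  list(best_index = which(d == best)[1], best_distance = best,
       is_tie = sum(d == best) > 1)
}

naive_top_ma <- function(addresses, address, m_a) {
  d <- integer(nrow(addresses))
  for (i in seq_len(nrow(addresses))) d[i] <- sum(addresses[i, ] != address)
  # explicit stable selection: sort by (distance, index)
  ord <- order(d, seq_along(d))
  ord[seq_len(m_a)]
}

# A from-scratch SDM (binary A1 flavour) used to oracle the analytic
# per-bit error: store k random address/data pairs, recall pair 1, count
# bit errors against the stored data.
naive_sdm_bit_errors <- function(m, m_a, n_c, k, seed) {
  set.seed(seed)
  A <- matrix(sample(0:1, m * n_c, replace = TRUE), m, n_c)
  addr <- matrix(sample(0:1, k * n_c, replace = TRUE), k, n_c)
  data <- matrix(sample(0:1, k * n_c, replace = TRUE), k, n_c)
  contents <- matrix(0, m, n_c)
  for (i in seq_len(k)) {
    rows <- naive_top_ma(A, addr[i, ], m_a)
    for (r in rows) contents[r, ] <- contents[r, ] + (2 * data[i, ] - 1)
  }
  rows <- naive_top_ma(A, addr[1, ], m_a)
  sums <- numeric(n_c)
  for (r in rows) sums <- sums + contents[r, ]
  recalled <- as.integer(sums > 0)
  sum(recalled != data[1, ])
}

# Empirical dimension search: smallest-granularity m whose measured count
# error is closest to the target in log10, by bisection on simulations.
empirical_dimension <- function(variant, target, seed, trials = 100L,
                                lo = 8L, hi = 512L) {
  cache <- new.env(parent = emptyenv())
  measure <- function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]])) {
      rep <- run_recall_experiment(variant, m, trials = trials, seed = seed)
      cache[[key]] <- max(rep$count_error_rate, 0.5 / rep$n_recalls)
    }
    cache[[key]]
  }
  p_lo <- measure(lo)
  p_hi <- measure(hi)
  stopifnot(p_lo > target, p_hi < target)
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (measure(mid) > target) lo <- mid else hi <- mid
  }
  if (abs(log10(measure(lo)) - log10(target)) <
      abs(log10(measure(hi)) - log10(target))) lo else hi
}
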