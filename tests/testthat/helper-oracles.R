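# Independent oracles used across tests. Each is a deliberately naive
# implementation (exhaustive enumeration or closed form) kept separate from
# the package's own code paths.

# Exhaustive DTW: enumerate every monotone warping path from (1,1) to
# (n,m) with steps (1,0), (0,1), (1,1); a diagonal step pays the local
# |a_i - b_j| cost `diag_weight` times (the entry into (1,1) counts as
# diagonal), other steps once. Returns the minimum path cost.
brute_dtw <- function(a, b, diag_weight = 2) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best) return()
    if (i == n && j == m) {
      best <<- acc
      return()
    }
    if (i < n && j < m)
      recurse(i + 1, j + 1, acc + diag_weight * abs(a[i + 1] - b[j + 1]))
    if (i < n) recurse(i + 1, j, acc + abs(a[i + 1] - b[j]))
    if (j < m) recurse(i, j + 1, acc + abs(a[i] - b[j + 1]))
  }
  recurse(1, 1, diag_weight * abs(a[1] - b[1]))
  best
}

# Hypergeometric upper-tail probability by exhaustive enumeration over all
# draws: P(overlap >= q) when drawing `k` genes from a background of size
# `N` containing `K` set genes.
enum_hyper_tail <- function(q, K, N, k) {
  sum(vapply(q:min(k, K), function(x)
    choose(K, x) * choose(N - K, k - x), numeric(1))) / choose(N, k)
}

# Adjusted Rand index (mclust provides one; fall back to a direct
# contingency-table computation if the suggested package is unavailable).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Shared small simulated dataset reused by several test files (cached per
# session to keep the suite fast).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1, n_cells = 2000) {
  key <- paste0("s", seed, "_", n_cells)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_trajectory_dataset(n_cells = n_cells,
                                                     seed = seed)
  .sim_cache[[key]]
}

true_modules <- function(truth) {
  with(truth$gene_table, setNames(module, gene))
}
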