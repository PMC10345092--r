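# Independent brute-force oracles. Each one takes a different algebraic or
# enumerative route than the package implementation, so agreement is a real
# cross-check rather than the same code twice.

# Kruskal-Wallis through the rank-variance identity:
# H = sum n_i (Rbar_i - Rbar)^2 / S^2 with S^2 the empirical variance of the
# pooled ranks (equals the tie-corrected classic formula).
oracle_kw <- function(values, groups) {
  r <- rank(values)
  n <- length(r)
  rbar <- mean(r)
  s2 <- sum((r - rbar)^2) / (n - 1)
  if (s2 == 0) return(0)
  means <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  sum(ns * (means - rbar)^2) / s2
}

# Dunn z through the same empirical rank variance
oracle_dunn_z <- function(values, groups, a, b) {
  r <- rank(values)
  n <- length(r)
  s2 <- (sum(r^2) - n * ((n + 1) / 2)^2) / (n - 1)
  ra <- mean(r[groups == a])
  rb <- mean(r[groups == b])
  na <- sum(groups == a)
  nb <- sum(groups == b)
  (ra - rb) / sqrt(s2 * (1 / na + 1 / nb))
}

# Friedman through the centered rank-sum form
# 12 / (n k (k+1)) * sum (R_j - n(k+1)/2)^2
oracle_friedman <- function(m) {
  ranks <- t(apply(m, 1, rank))
  n <- nrow(m)
  k <- ncol(m)
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum((rj - n * (k + 1) / 2)^2)
}

# BH by scanning every candidate threshold in the sorted p list
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  sorted <- sort(p)
  critical <- 0
  for (i in seq_len(m)) {
    if (sorted[i] <= i / m * q) critical <- sorted[i]
  }
  list(critical_p = critical,
       significant = if (critical > 0) p <= critical else rep(FALSE, m))
}

# Holm by the literal step-down max rule on sorted p values
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# hypergeometric upper tail P(X >= k) by explicit term enumeration
oracle_hyper_tail <- function(k, N, K, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small helper: expression matrix from a plain matrix
mk_matrix <- function(values, state = "counts",
                      cells = sprintf("c%d", seq_len(nrow(values))),
                      genes = sprintf("g%d", seq_len(ncol(values)))) {
  expr_matrix(values, cells, genes, state = state)
}

# compact single-type screen config used across simulation tests
mk_screen_config <- function(seed, n_planted = 20, target_r = 0.5,
                             n_cells = 150, n_genes = 1000) {
  synthetic_config(
    t_types = data.frame(name = "FREM3", depth_min = 0, depth_max = 1),
    n_cells_per_type = n_cells, type_effects = c(FREM3 = 0),
    n_genes = n_genes,
    sets = list(names = "S", sizes = n_genes, pairwise_overlap = NULL,
                triple_overlap = NULL),
    planted = list(n_per_set = n_planted, target_r = target_r,
                   prop_positive = 0.7, baseline_range = c(1, 2.5),
                   bias_set = NULL, bias_factor = 1),
    seed = seed
  )
}
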