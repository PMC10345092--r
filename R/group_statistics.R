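# Two-level group comparisons used throughout the analysis: cell-level
# Kruskal-Wallis with Dunn post-hoc tests under Holm correction, and a
# donor-level Friedman test on per-donor medians (complete block design).
# The rank statistics are implemented here from their defining formulas; the
# test suite cross-checks them against base R and brute-force oracles.

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    ps_stop("values and groups must have equal length")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    ps_stop("values must be finite and non-missing")
  }
  groups <- as.character(groups)
  if (anyNA(groups)) ps_stop("group labels must be non-missing")
  if (length(unique(groups)) < 2L) {
    ps_stop("need at least 2 groups, got %d", length(unique(groups)))
  }
  groups
}

# sum of t^3 - t over tie groups, the shared tie-correction term
tie_term <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with average ranks:
#' `H = [(12 / (N (N+1))) * sum n_i (Rbar_i - Rbar)^2] / (1 - sum(t^3 - t) / (N^3 - N))`,
#' with p from the chi-square distribution on k-1 degrees of freedom. When all
#' values are identical the statistic is 0 and p is 1.
#'
#' @param values numeric vector of observations (e.g. per-cell set scores).
#' @param groups group label per observation (e.g. t-type).
#' @return A list of class `group_test`: `statistic` (H), `df`, `p`,
#'   `group_ns` (named counts), `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_groups(values, groups)
  n <- length(values)
  r <- rank(values)
  sums <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  k <- length(sums)
  h_raw <- 12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  correction <- 1 - tie_term(values) / (n^3 - n)
  h <- if (correction <= 0) 0 else h_raw / correction
  # guard tiny negative fp residue when groups are near-identical
  h <- max(h, 0)
  p <- if (correction <= 0) 1 else pchisq(h, df = k - 1, lower.tail = FALSE)
  structure(
    list(statistic = h, df = k - 1L, p = p,
         group_ns = setNames(as.integer(ns), names(ns)),
         method = "Kruskal-Wallis rank sum test (tie-corrected)"),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s\nH = %.6g, df = %d, p = %.4g\n", x$method, x$statistic,
              x$df, x$p))
  cat("n per group:", paste(names(x$group_ns), x$group_ns, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons with Holm correction
#'
#' For each pair of groups,
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_a + 1/n_b))`
#' with pooled average ranks and tie term `T = sum(t^3 - t)`; two-sided raw
#' p values are Holm step-down adjusted over the pair family.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param reference optional character vector of reference group labels: when
#'   given, only pairs involving a reference group are tested (the restricted
#'   family); default all `k(k-1)/2` pairs.
#' @return A `data.frame` with `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_holm <- function(values, groups, reference = NULL) {
  groups <- check_groups(values, groups)
  n <- length(values)
  r <- rank(values)
  means <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  labs <- names(means)
  if (!is.null(reference)) {
    missing_ref <- setdiff(reference, labs)
    if (length(missing_ref)) {
      ps_stop("reference group(s) not present: %s", ps_list_some(missing_ref))
    }
  }
  var_term <- n * (n + 1) / 12 - tie_term(values) / (12 * (n - 1))
  pairs <- utils::combn(labs, 2L)
  if (!is.null(reference)) {
    keep <- pairs[1L, ] %in% reference | pairs[2L, ] %in% reference
    pairs <- pairs[, keep, drop = FALSE]
  }
  a <- pairs[1L, ]
  b <- pairs[2L, ]
  se <- sqrt(var_term * (1 / ns[a] + 1 / ns[b]))
  z <- ifelse(se > 0, (means[a] - means[b]) / se, 0)
  p_raw <- 2 * pnorm(-abs(z))
  data.frame(group_a = a, group_b = b, z = unname(z),
             p_raw = unname(p_raw),
             p_adjusted = unname(holm_adjust(p_raw)),
             stringsAsFactors = FALSE)
}

# Holm step-down adjustment; equals stats::p.adjust(method = "holm"),
# written out so the rule is explicit and testable against it
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Collapse observations to a donors-by-conditions median matrix
#'
#' Each donor contributes one median per condition. Donors missing any
#' condition are dropped with a warning (complete block design; no
#' imputation).
#'
#' @param values numeric vector of observations.
#' @param donors donor label per observation.
#' @param conditions condition label per observation (e.g. brain area or
#'   t-type).
#' @param statistic collapsing statistic, default [stats::median].
#' @return A numeric matrix, donors in rows, conditions in columns.
#' @export
donor_collapse <- function(values, donors, conditions, statistic = median) {
  if (length(values) != length(donors) || length(values) != length(conditions)) {
    ps_stop("values, donors and conditions must have equal length")
  }
  donors <- as.character(donors)
  conditions <- as.character(conditions)
  tab <- tapply(values, list(donors, conditions), statistic)
  complete <- rowSums(is.na(tab)) == 0L
  if (any(!complete)) {
    ps_warn("dropping donor(s) with missing conditions: %s",
            ps_list_some(rownames(tab)[!complete]))
    tab <- tab[complete, , drop = FALSE]
  }
  if (nrow(tab) < 2L) {
    ps_stop("fewer than 2 complete donors (%d)", nrow(tab))
  }
  tab
}

#' Friedman test on a complete donors-by-conditions matrix
#'
#' Within-donor average ranks, then the classic chi-square statistic
#' `12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` with p from chi-square on
#' k-1 degrees of freedom. For small designs an exact permutation p
#' (all `(k!)^n` within-donor orderings) is available.
#'
#' @param m numeric matrix, donors in rows, conditions in columns (e.g. from
#'   [donor_collapse()]).
#' @param exact compute the exact permutation p value as well (requires
#'   `factorial(k)^n <= 1e6`, e.g. n <= 5 donors with few conditions).
#' @return A list of class `donor_test`: `statistic` (Friedman chi-square),
#'   `df`, `p`, `p_exact` (NA unless `exact`), `n_donors`, `n_conditions`,
#'   `donor_medians` (the input matrix).
#' @export
friedman <- function(m, exact = FALSE) {
  m <- as.matrix(m)
  if (anyNA(m)) ps_stop("incomplete donors-by-conditions matrix")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L) ps_stop("need >= 2 donors, got %d", n)
  if (k < 3L) ps_stop("need >= 3 conditions, got %d", k)
  stat <- friedman_stat(m)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  p_exact <- NA_real_
  if (exact) {
    total <- factorial(k)^n
    if (total > 1e6) {
      ps_stop("exact permutation infeasible: %d donors x %d conditions", n, k)
    }
    p_exact <- friedman_exact_p(m)
  }
  structure(
    list(statistic = stat, df = k - 1L, p = p, p_exact = p_exact,
         n_donors = n, n_conditions = k, donor_medians = m),
    class = "donor_test"
  )
}

friedman_stat <- function(m) {
  ranks <- t(apply(m, 1L, rank))
  n <- nrow(m)
  k <- ncol(m)
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

# exact permutation null: every within-donor ordering equally likely
friedman_exact_p <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  observed <- friedman_stat(m)
  perms <- all_permutations(k)
  n_perm <- nrow(perms)
  idx <- rep(1L, n)
  count <- 0L
  total <- n_perm^n
  for (step in seq_len(total)) {
    pm <- m
    for (d in seq_len(n)) pm[d, ] <- m[d, perms[idx[d], ]]
    if (friedman_stat(pm) >= observed - 1e-12) count <- count + 1L
    # odometer increment over donor-wise permutation indices
    d <- 1L
    while (d <= n) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= n_perm) break
      idx[d] <- 1L
      d <- d + 1L
    }
  }
  count / total
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

#' @export
print.donor_test <- function(x, ...) {
  cat(sprintf(
    "Friedman test: chi-square = %.6g, df = %d, p = %.4g (%d donors x %d conditions)\n",
    x$statistic, x$df, x$p, x$n_donors, x$n_conditions))
  if (!is.na(x$p_exact)) cat(sprintf("exact permutation p = %.4g\n", x$p_exact))
  invisible(x)
}
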