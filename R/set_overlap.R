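# Venn decomposition of two or three gene sets, and one-sided Fisher
# enrichment of reference-set membership (e.g. HAR genes) among the
# phenotype-correlated subset of a GWAS gene set.

#' Disjoint Venn region counts for 2 or 3 gene sets
#'
#' @param sets a list of 2 or 3 [gene_set()] objects (or character vectors).
#' @return A list: `regions` (named disjoint counts: `only_<name>`, pairwise
#'   `<a>_<b>`, and `<a>_<b>_<c>` for 3 sets), `totals` (input set sizes),
#'   `union_size`.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    ps_stop("venn_counts handles 2 or 3 sets, got %d", length(sets))
  }
  members <- lapply(sets, as_members)
  names(members) <- vapply(seq_along(sets), function(i) {
    if (is_gene_set(sets[[i]])) sets[[i]]$name else paste0("set", i)
  }, character(1))
  if (any(!lengths(members))) ps_stop("sets must be nonempty")
  nm <- names(members)
  universe <- unique(unlist(members))
  inset <- vapply(members, function(m) universe %in% m, logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1L)

  regions <- list()
  if (length(members) == 2L) {
    regions[[paste0("only_", nm[1])]] <- sum(inset[, 1] & !inset[, 2])
    regions[[paste0("only_", nm[2])]] <- sum(!inset[, 1] & inset[, 2])
    regions[[paste(nm[1], nm[2], sep = "_")]] <- sum(inset[, 1] & inset[, 2])
  } else {
    a <- inset[, 1]; b <- inset[, 2]; c <- inset[, 3]
    regions[[paste0("only_", nm[1])]] <- sum(a & !b & !c)
    regions[[paste0("only_", nm[2])]] <- sum(!a & b & !c)
    regions[[paste0("only_", nm[3])]] <- sum(!a & !b & c)
    regions[[paste(nm[1], nm[2], sep = "_")]] <- sum(a & b & !c)
    regions[[paste(nm[1], nm[3], sep = "_")]] <- sum(a & !b & c)
    regions[[paste(nm[2], nm[3], sep = "_")]] <- sum(!a & b & c)
    regions[[paste(nm[1], nm[2], nm[3], sep = "_")]] <- sum(a & b & c)
  }
  list(regions = regions,
       totals = setNames(lengths(members), nm),
       union_size = length(universe))
}

# upper-tail hypergeometric probability P(X >= k) for k successes in a sample
# of n from N with K successes; equals the one-sided (greater) Fisher exact p
hypergeom_tail <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0) || K > N || n > N || k > min(K, n)) {
    ps_stop("invalid hypergeometric parameters (k=%g, N=%g, K=%g, n=%g)",
            k, N, K, n)
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' One-sided Fisher enrichment of reference-set membership in a subset
#'
#' Tests whether the phenotype-correlated members of a full gene set (e.g.
#' the TDL/AP-correlated subset of the IQ set) belong to a reference set
#' (e.g. HAR genes) more often than the remaining members. The 2x2 table has
#' rows = correlated vs non-correlated members of `full_set`, columns =
#' in/not-in `reference_set`; p is the exact hypergeometric upper tail
#' (alternative: greater). Genes outside `full_set` never enter the table, so
#' the result is invariant to them.
#'
#' @param full_set the complete gene set ([gene_set()] or character).
#' @param correlated_subset the correlated members; must be a subset of
#'   `full_set`.
#' @param reference_set the reference membership set.
#' @return A list of class `enrichment_result`: `table` (2x2 integer matrix),
#'   `odds_ratio` (sample OR, `Inf` allowed), `p_one_sided`,
#'   `percent_subset` and `percent_full` (reference-membership percentages).
#' @export
overlap_enrichment <- function(full_set, correlated_subset, reference_set) {
  full <- as_members(full_set)
  sub <- as_members(correlated_subset)
  ref <- as_members(reference_set)
  outside <- setdiff(sub, full)
  if (length(outside)) {
    ps_stop("correlated subset not contained in the full set: %s",
            ps_list_some(outside))
  }
  rest <- setdiff(full, sub)
  a <- sum(sub %in% ref)
  b <- length(sub) - a
  c <- sum(rest %in% ref)
  d <- length(rest) - c
  tab <- matrix(as.integer(c(a, b, c, d)), nrow = 2L, byrow = TRUE,
                dimnames = list(c("correlated", "not_correlated"),
                                c("in_reference", "not_in_reference")))
  p <- hypergeom_tail(a, N = length(full), K = a + c, n = length(sub))
  odds_ratio <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(
    list(table = tab, odds_ratio = odds_ratio, p_one_sided = p,
         percent_subset = 100 * a / length(sub),
         percent_full = 100 * (a + c) / length(full)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Overlap enrichment: %.1f%% of subset vs %.1f%% of full set in reference; OR = %.3g, one-sided p = %.3g\n",
    x$percent_subset, x$percent_full, x$odds_ratio, x$p_one_sided))
  print(x$table)
  invisible(x)
}

#' Genes of interest across both phenotype screens
#'
#' The union of genes flagged significant in either the TDL or the AP
#' rise-speed screen, restricted to genes belonging to at least two of the
#' three input gene sets (the cross-set intersection rule).
#'
#' @param tdl_records,ap_records screen `data.frame`s with `significant`
#'   flags (either may be NULL).
#' @param sets a list of exactly 3 [gene_set()] objects.
#' @param min_sets minimum number of sets a gene must belong to, default 2.
#' @return A [gene_set()] named `"genes_of_interest"`; NULL when empty.
#' @export
genes_of_interest <- function(tdl_records, ap_records, sets, min_sets = 2L) {
  if (length(sets) != 3L) ps_stop("expected exactly 3 gene sets, got %d",
                                  length(sets))
  sig <- character()
  for (records in list(tdl_records, ap_records)) {
    if (!is.null(records)) {
      sig <- c(sig, records$gene[records$significant %in% TRUE])
    }
  }
  sig <- unique(sig)
  if (!length(sig)) return(NULL)
  membership <- Reduce(`+`, lapply(sets, function(s) {
    as.integer(sig %in% as_members(s))
  }))
  keep <- sig[membership >= min_sets]
  if (!length(keep)) return(NULL)
  gene_set("genes_of_interest", sort(keep))
}
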