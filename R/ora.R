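# Over-representation analysis of a foreground gene list against GO-style
# annotation terms: hypergeometric upper-tail p per term, BH adjustment
# across terms, and a Storey-style positive-FDR q value. Significance uses
# the triple rule: p, adjusted p and q all below the cutoff.

#' Annotation catalog
#'
#' A mapping from term name to member genes plus the size of the annotated
#' universe.
#'
#' @param terms a named list of character vectors, or a list of [gene_set()]
#'   objects (e.g. from [read_gene_sets()] on a GMT file).
#' @param universe_size optional count of all annotated genes; defaults to
#'   the size of the union of all terms, and must be at least that.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, universe_size = NULL) {
  if (length(terms) && all(vapply(terms, is_gene_set, logical(1)))) {
    nm <- vapply(terms, function(s) s$name, character(1))
    terms <- setNames(lapply(terms, function(s) s$members), nm)
  }
  if (!length(terms)) ps_stop("empty annotation catalog")
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    ps_stop("annotation terms must be named")
  }
  terms <- lapply(terms, function(m) unique(trimws(as.character(m))))
  empty <- names(terms)[!lengths(terms)]
  if (length(empty)) ps_stop("empty term(s): %s", ps_list_some(empty))
  union_size <- length(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe_size)) universe_size <- union_size
  if (universe_size < union_size) {
    ps_stop("universe_size (%d) smaller than the union of terms (%d)",
            universe_size, union_size)
  }
  structure(list(terms = terms, universe_size = as.integer(universe_size)),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("<annotation_catalog> %d terms over a universe of %d genes\n",
              length(x$terms), x$universe_size))
  invisible(x)
}

# Storey-style positive-FDR q value with pi0 estimated at lambda = 0.5,
# capped to [0, 1]; with fewer than `min_terms` tests pi0 is fixed at 1, so
# q reduces to the BH-adjusted p.
storey_q <- function(p, lambda = 0.5, min_terms = 20L) {
  m <- length(p)
  pi0 <- if (m < min_terms) 1 else
    min(1, max(0, sum(p > lambda) / (m * (1 - lambda))))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(pi0 * m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# BH-adjusted p values (step-up); equals stats::p.adjust(method = "BH")
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Over-representation analysis against an annotation catalog
#'
#' For each term, the one-sided hypergeometric test `P(X >= k)` of drawing
#' `k` term members in a foreground of size `n` from a universe of size `N`
#' containing `K` term members; every term and the foreground are intersected
#' with the universe first. Terms with no foreground hit are reported with
#' p = 1. BH adjustment and the Storey q run across all tested terms;
#' `significant` requires p, adjusted p and q all below `alpha`.
#'
#' @param foreground the gene list of interest ([gene_set()] or character).
#' @param catalog an [annotation_catalog()] (or named list of terms).
#' @param universe the annotated gene universe ([gene_set()] or character
#'   vector). When NULL, the catalog's term union is used and `N` is the
#'   catalog's `universe_size`.
#' @param alpha cutoff for the triple significance rule, default 0.05.
#' @param min_term_size,max_term_size optional term-size filters applied
#'   after universe intersection; defaults keep every nonempty term.
#' @return A `data.frame` with one row per tested term: `term`, `k`
#'   (foreground hits), `n` (foreground size in universe), `K` (universe
#'   hits), `N` (universe size), `percent_foreground`, `percent_universe`,
#'   `p`, `p_adjusted`, `q`, `significant`, `genes` (comma-separated hits),
#'   ordered by p ascending.
#' @export
over_representation <- function(foreground, catalog, universe = NULL,
                                alpha = 0.05, min_term_size = 1L,
                                max_term_size = Inf) {
  if (!inherits(catalog, "annotation_catalog")) {
    catalog <- annotation_catalog(catalog)
  }
  fg <- unique(as_members(foreground))
  if (is.null(universe)) {
    uni <- unique(unlist(catalog$terms, use.names = FALSE))
    N <- catalog$universe_size
    # foreground genes are part of the annotated universe by assumption
    fg_in <- intersect(fg, uni)
    if (!length(fg_in)) ps_stop("foreground disjoint from the catalog universe")
    n <- length(fg_in)
    terms <- catalog$terms
  } else {
    uni <- unique(as_members(universe))
    N <- length(uni)
    fg_in <- intersect(fg, uni)
    if (!length(fg_in)) ps_stop("foreground disjoint from the universe")
    n <- length(fg_in)
    terms <- lapply(catalog$terms, intersect, uni)
  }

  sizes <- lengths(terms)
  keep <- sizes >= max(1L, min_term_size) & sizes <= max_term_size
  terms <- terms[keep]
  if (!length(terms)) ps_stop("no terms left after universe intersection")

  K <- lengths(terms)
  hits <- lapply(terms, intersect, fg_in)
  k <- lengths(hits)
  p <- vapply(seq_along(terms), function(i) {
    hypergeom_tail(k[i], N = N, K = K[i], n = n)
  }, numeric(1))
  p_adj <- bh_adjust(p)
  q <- storey_q(p)

  out <- data.frame(
    term = names(terms), k = as.integer(k), n = n, K = as.integer(K), N = N,
    percent_foreground = 100 * k / n,
    percent_universe = 100 * K / N,
    p = p, p_adjusted = p_adj, q = q,
    significant = p < alpha & p_adj < alpha & q < alpha,
    genes = vapply(hits, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Over-representation against a restricted background
#'
#' Identical statistic with the universe replaced by a restricted background
#' (e.g. brain-expressed genes for synaptic-annotation testing): `N` is the
#' background size, `K` each term's overlap with the background, `n` the
#' foreground's overlap with the background.
#'
#' @param foreground the gene list of interest.
#' @param catalog an [annotation_catalog()] (or named list of terms).
#' @param background the background gene set.
#' @param ... passed to [over_representation()].
#' @return As [over_representation()].
#' @export
restricted_background_ora <- function(foreground, catalog, background, ...) {
  bg <- unique(as_members(background))
  if (!length(intersect(as_members(foreground), bg))) {
    ps_stop("foreground disjoint from the background")
  }
  over_representation(foreground, catalog, universe = bg, ...)
}
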