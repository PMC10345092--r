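# Normalization, the zero-prevalence gene filter, per-cell gene-set scores,
# and the FREM3 depth split. Working scale throughout the analysis is
# log10(CPM + 1): reads per gene divided by the cell's total mapped reads,
# times 1e6, then log-transformed.

#' Counts-per-million normalization
#'
#' `value[c, g] = counts[c, g] / total_counts[c] * 1e6`. When the matrix holds
#' the full gene universe every cell's CPM values sum to 1e6 by construction.
#'
#' @param x an [expr_matrix()] in state `"counts"`.
#' @return An [expr_matrix()] in state `"cpm"` with identical ids.
#' @export
cpm_normalize <- function(x) {
  assert_state(x, "counts")
  totals <- rowSums(x$values)
  zero <- x$cell_ids[totals == 0]
  if (length(zero)) {
    ps_stop("cells with zero total counts: %s", ps_list_some(zero))
  }
  expr_matrix(x$values / totals * 1e6, x$cell_ids, x$gene_ids, state = "cpm")
}

#' Log-transform a CPM matrix
#'
#' Elementwise `log10(CPM + 1)`; monotone, so rank-based downstream statistics
#' are unaffected by the transform.
#'
#' @param x an [expr_matrix()] in state `"cpm"`.
#' @return An [expr_matrix()] in state `"log10cpm1"`.
#' @export
log_transform <- function(x) {
  assert_state(x, "cpm")
  expr_matrix(log10(x$values + 1), x$cell_ids, x$gene_ids,
              state = "log10cpm1")
}

#' Zero-prevalence gene filter
#'
#' Excludes a gene when it has zero expression in *more than*
#' `threshold` of the reference cells (strict inequality: with 276 reference
#' cells and threshold 0.95, a gene zero in 263 cells is excluded because
#' 263 > 262.2, while one zero in 262 cells is retained). "Zero" is tested on
#' the stored value regardless of normalization state, since 0 counts, 0 CPM
#' and 0 log10(CPM+1) coincide. Genes absent from the matrix are excluded and
#' counted separately.
#'
#' @param x an [expr_matrix()] in any state.
#' @param set a [gene_set()] (or character vector of symbols).
#' @param threshold zero-fraction above which a gene is excluded, in (0, 1].
#' @param reference_cells optional cell ids on which prevalence is computed
#'   (e.g. a smaller Patch-seq reference dataset); default all cells.
#' @return A list with `retained` (a [gene_set()]), and a `report` list:
#'   `n_input`, `n_retained`, `excluded` (symbols failing the filter),
#'   `absent` (symbols not in the matrix), `threshold`, `n_reference_cells`.
#' @export
prevalence_filter <- function(x, set, threshold = 0.95,
                              reference_cells = NULL) {
  if (!is_expr_matrix(x)) ps_stop("expected an expr_matrix")
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) ps_stop("threshold must be in (0, 1]")
  members <- as_members(set)
  set_name <- if (is_gene_set(set)) set$name else deparse(substitute(set))

  if (is.null(reference_cells)) {
    ref_idx <- seq_along(x$cell_ids)
  } else {
    missing_ref <- setdiff(reference_cells, x$cell_ids)
    if (length(missing_ref)) {
      ps_stop("reference cells not in matrix: %s", ps_list_some(missing_ref))
    }
    ref_idx <- match(reference_cells, x$cell_ids)
  }
  n_ref <- length(ref_idx)

  present <- intersect(members, x$gene_ids)
  absent <- setdiff(members, x$gene_ids)
  if (!length(present)) {
    ps_stop("no genes of set '%s' are present in the matrix", set_name)
  }

  zeros <- colSums(x$values[ref_idx, present, drop = FALSE] == 0)
  # excluded iff zero in MORE THAN threshold * n_ref cells
  excluded <- present[zeros > threshold * n_ref]
  retained <- setdiff(present, excluded)
  if (!length(retained)) {
    ps_stop("prevalence filter removed every gene of set '%s'", set_name)
  }
  list(
    retained = gene_set(set_name, retained,
                        description = if (is_gene_set(set)) set$description),
    report = list(n_input = length(members), n_retained = length(retained),
                  excluded = excluded, absent = absent,
                  threshold = threshold, n_reference_cells = n_ref)
  )
}

#' Per-cell gene-set score
#'
#' Collapses a gene set to one value per cell: the arithmetic mean of
#' log10(CPM + 1) over the retained set genes. Cells where every retained
#' gene is zero score 0, not `NA`.
#'
#' @param x an [expr_matrix()] in state `"log10cpm1"`.
#' @param retained a [gene_set()] whose members are all present in `x`
#'   (run [prevalence_filter()] first).
#' @return A `data.frame` with columns `cell_id`, `set_name`, `score`,
#'   `n_genes_used`.
#' @export
gene_set_score <- function(x, retained) {
  assert_state(x, "log10cpm1")
  members <- as_members(retained)
  if (!length(members)) ps_stop("retained gene set is empty")
  missing <- setdiff(members, x$gene_ids)
  if (length(missing)) {
    ps_stop("retained genes absent from matrix: %s", ps_list_some(missing))
  }
  name <- if (is_gene_set(retained)) retained$name else "gene_set"
  scores <- rowMeans(x$values[, members, drop = FALSE])
  data.frame(cell_id = x$cell_ids, set_name = name, score = unname(scores),
             n_genes_used = length(members), stringsAsFactors = FALSE)
}

#' Split FREM3 cells into L2 and L3 subtypes by cortical depth
#'
#' FREM3 spans layers 2 and 3; cells are relabeled by their soma's relative
#' depth within L2/L3: depth > `boundary` becomes `"L3 FREM3"` (lowest 70%
#' at the default 0.3), depth < `boundary` becomes `"L2 FREM3"`. A cell at
#' exactly the boundary goes to L2, because L3 is defined by the strict
#' inequality.
#'
#' @param metadata cell-metadata `data.frame` (see [read_table()]).
#' @param boundary relative-depth split point, default 0.3.
#' @param label the t-type label to split, default `"FREM3"`.
#' @return The metadata with relabeled `t_type`; non-FREM3 rows untouched.
#' @export
assign_frem3_layer <- function(metadata, boundary = 0.3, label = "FREM3") {
  stopifnot_scalar_number(boundary, "boundary")
  is_target <- metadata$t_type == label
  missing_depth <- metadata$cell_id[is_target & is.na(metadata$relative_depth)]
  if (length(missing_depth)) {
    ps_stop("%s cell(s) lack relative_depth: %s", label,
            ps_list_some(missing_depth))
  }
  deep <- is_target & metadata$relative_depth > boundary
  metadata$t_type[is_target] <- paste("L2", label)
  metadata$t_type[deep] <- paste("L3", label)
  metadata
}
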