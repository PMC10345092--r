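# Per-gene association of expression with a cellular phenotype (total
# dendritic length or AP rise speed), Benjamini-Hochberg FDR control with
# critical-p reporting, and the heatmap/summary constructions over the
# significant genes.

#' Per-gene expression-phenotype association screen
#'
#' For each retained set gene, ordinary least squares of expression
#' (log10(CPM+1), the dependent variable) on the phenotype. The two-sided p
#' value for zero slope is the Pearson correlation t-test with n-2 degrees of
#' freedom (`t = r sqrt(n-2) / sqrt(1-r^2)`); the two formulations are the
#' same test. Cells lacking the phenotype are excluded from this screen only;
#' genes with zero expression variance over the screened cells are dropped
#' and reported.
#'
#' @param x an [expr_matrix()] in state `"log10cpm1"`.
#' @param phenotypes phenotype `data.frame` (see [read_table()]).
#' @param which phenotype column: `"tdl"` or `"ap_rise_speed"`.
#' @param set a [gene_set()] (or character vector); only members present in
#'   the matrix are screened.
#' @return A `data.frame` of class `gene_screen` with one row per screened
#'   gene: `gene`, `n`, `slope` (expression units per phenotype unit),
#'   `intercept`, `r`, `p`, `sign` (`"+"`/`"-"`), plus attributes
#'   `dropped_constant` (genes with zero variance) and `absent` (set members
#'   not in the matrix).
#' @export
per_gene_association <- function(x, phenotypes,
                                 which = c("tdl", "ap_rise_speed"), set) {
  assert_state(x, "log10cpm1")
  which <- match.arg(which)
  if (!which %in% names(phenotypes)) {
    ps_stop("phenotype table lacks column '%s'", which)
  }
  members <- as_members(set)
  present <- intersect(members, x$gene_ids)
  absent <- setdiff(members, x$gene_ids)
  if (!length(present)) ps_stop("no set genes present in the matrix")

  keep <- !is.na(phenotypes[[which]])
  ph <- phenotypes[keep, , drop = FALSE]
  common <- intersect(x$cell_ids, ph$cell_id)
  if (!length(common)) {
    ps_stop("no cells shared between the matrix and the '%s' phenotype", which)
  }
  n <- length(common)
  if (n < 3L) ps_stop("need >= 3 cells with expression and phenotype, got %d", n)
  pheno <- ph[[which]][match(common, ph$cell_id)]
  if (sd(pheno) == 0) ps_stop("phenotype '%s' is constant over screened cells",
                              which)

  y <- x$values[common, present, drop = FALSE]
  sd_y <- apply(y, 2L, sd)
  constant <- present[sd_y == 0]
  tested <- present[sd_y > 0]
  if (!length(tested)) ps_stop("every set gene is constant over screened cells")
  y <- y[, tested, drop = FALSE]
  sd_y <- sd_y[sd_y > 0]

  r <- as.vector(cor(pheno, y))
  # exact fits: keep |r| <= 1 against fp rounding before the t transform
  r <- pmin(1, pmax(-1, r))
  slope <- r * sd_y / sd(pheno)
  intercept <- colMeans(y) - slope * mean(pheno)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(is.finite(tt), 2 * pt(-abs(tt), df = n - 2), 0)

  out <- data.frame(
    gene = tested, n = n, slope = unname(slope),
    intercept = unname(intercept), r = r, p = p,
    sign = ifelse(r >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped_constant") <- constant
  attr(out, "absent") <- absent
  attr(out, "phenotype") <- which
  class(out) <- c("gene_screen", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR with critical p
#'
#' Sorts the m p values ascending and finds the largest index i with
#' `p_(i) <= (i/m) q`; `critical_p` is that `p_(i)` (0 when no index
#' qualifies) and every p `<=` critical_p is flagged significant. The
#' comparison at `p_(i)` itself is `<=` as the step-up definition requires.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param q target false discovery rate, default 0.05.
#' @return A list of class `fdr_result`: `q`, `m`, `critical_p`,
#'   `n_significant`, `significant` (logical flags in input order).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (!length(p)) ps_stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) ps_stop("p values must lie in [0, 1]")
  stopifnot_scalar_number(q, "q")
  if (q <= 0 || q >= 1) ps_stop("q must be in (0, 1)")
  m <- length(p)
  sorted <- sort(p)
  passing <- which(sorted <= seq_len(m) / m * q)
  critical_p <- if (length(passing)) sorted[max(passing)] else 0
  significant <- p <= critical_p & length(passing) > 0
  structure(
    list(q = q, m = m, critical_p = critical_p,
         n_significant = sum(significant), significant = significant),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("BH step-up at q = %g over m = %d tests: %d significant, critical p = %.4g\n",
              x$q, x$m, x$n_significant, x$critical_p))
  invisible(x)
}

#' Run the full per-gene screen with FDR control
#'
#' Convenience wrapper: prevalence filter, [per_gene_association()], then
#' [benjamini_hochberg()] over the screened genes, attaching `significant`
#' flags to the records.
#'
#' @param x an [expr_matrix()] in state `"log10cpm1"`.
#' @param phenotypes phenotype table.
#' @param which `"tdl"` or `"ap_rise_speed"`.
#' @param set a [gene_set()].
#' @param fdr_q target FDR, default 0.05.
#' @param filter_threshold zero-prevalence threshold, default 0.95; `NULL`
#'   skips the filter.
#' @param reference_cells optional prevalence reference cells.
#' @return A list: `records` (the screen `data.frame` with a `significant`
#'   column, ranked by p ascending), `fdr` (the [benjamini_hochberg()]
#'   result), `filter_report` (or NULL).
#' @export
run_screen <- function(x, phenotypes, which = c("tdl", "ap_rise_speed"), set,
                       fdr_q = 0.05, filter_threshold = 0.95,
                       reference_cells = NULL) {
  which <- match.arg(which)
  filter_report <- NULL
  screened_set <- set
  if (!is.null(filter_threshold)) {
    flt <- prevalence_filter(x, set, threshold = filter_threshold,
                             reference_cells = reference_cells)
    screened_set <- flt$retained
    filter_report <- flt$report
  }
  records <- per_gene_association(x, phenotypes, which, screened_set)
  fdr <- benjamini_hochberg(records$p, q = fdr_q)
  records$significant <- fdr$significant
  records <- records[order(records$p, records$gene), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, fdr = fdr, filter_report = filter_report)
}

#' Heatmap bundle of significant genes
#'
#' Z-scores each significant gene across the screened cells (population SD),
#' orders cells by phenotype ascending (ties broken by cell id), orders genes
#' by raw p ascending, and partitions genes into positive/negative panels by
#' correlation sign.
#'
#' @param x an [expr_matrix()] in state `"log10cpm1"`.
#' @param phenotypes phenotype table.
#' @param records screen records (rows with `significant == TRUE` are used).
#' @param which phenotype column used for the column ordering; defaults to
#'   the phenotype recorded on `records`.
#' @return A list of class `heatmap_bundle`: `matrix` (genes x cells,
#'   z-scored), `cell_order`, `gene_order`, `partition` (list with
#'   `positive`/`negative` gene vectors), `phenotype`.
#' @export
build_heatmap_bundle <- function(x, phenotypes, records, which = NULL) {
  assert_state(x, "log10cpm1")
  if (is.null(which)) which <- attr(records, "phenotype")
  if (is.null(which)) ps_stop("phenotype not recorded on records; pass 'which'")
  sig <- records[records$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig)) ps_stop("no significant genes to display")

  keep <- !is.na(phenotypes[[which]])
  ph <- phenotypes[keep, , drop = FALSE]
  cells <- intersect(x$cell_ids, ph$cell_id)
  pheno <- ph[[which]][match(cells, ph$cell_id)]
  cell_order <- cells[order(pheno, cells)]
  gene_order <- sig$gene[order(sig$p, sig$gene)]

  vals <- t(x$values[cell_order, gene_order, drop = FALSE])
  mu <- rowMeans(vals)
  sd_pop <- sqrt(rowMeans((vals - mu)^2))
  z <- (vals - mu) / sd_pop

  structure(
    list(matrix = z, cell_order = cell_order, gene_order = gene_order,
         partition = list(
           positive = sig$gene[sig$sign == "+"],
           negative = sig$gene[sig$sign == "-"]
         ),
         phenotype = which),
    class = "heatmap_bundle"
  )
}

#' Per-cell summary of sign-selected significant genes
#'
#' Mean expression per cell over the significant genes of one correlation
#' sign, with a Kruskal-Wallis comparison across t-types. With zero genes of
#' the requested sign the summary is empty (not an error).
#'
#' @param x an [expr_matrix()] in state `"log10cpm1"`.
#' @param records screen records with `significant` flags.
#' @param metadata cell metadata (provides `t_type`).
#' @param sign `"+"` or `"-"`.
#' @return A list: `summary` (`data.frame` with `cell_id`, `t_type`,
#'   `mean_expression`; zero rows when no genes match), `genes`, `test`
#'   (a [kruskal_wallis()] result or NULL).
#' @export
correlated_gene_summary <- function(x, records, metadata, sign = c("+", "-")) {
  assert_state(x, "log10cpm1")
  sign <- match.arg(sign)
  genes <- records$gene[records$significant %in% TRUE & records$sign == sign]
  if (!length(genes)) {
    return(list(summary = data.frame(cell_id = character(),
                                     t_type = character(),
                                     mean_expression = numeric(),
                                     stringsAsFactors = FALSE),
                genes = character(), test = NULL))
  }
  cells <- intersect(x$cell_ids, metadata$cell_id)
  if (!length(cells)) ps_stop("no cells shared between matrix and metadata")
  mean_expr <- rowMeans(x$values[cells, genes, drop = FALSE])
  t_type <- metadata$t_type[match(cells, metadata$cell_id)]
  summary <- data.frame(cell_id = cells, t_type = t_type,
                        mean_expression = unname(mean_expr),
                        stringsAsFactors = FALSE)
  test <- if (length(unique(t_type)) >= 2L) {
    kruskal_wallis(summary$mean_expression, summary$t_type)
  }
  list(summary = summary, genes = genes, test = test)
}
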