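#' Expression matrix container
#'
#' A light cells-by-genes expression container carrying its normalization
#' state. Values are held as a dense base matrix (sparse input is densified on
#' read; the datasets this package targets are a few hundred Patch-seq cells).
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param cell_ids character vector of unique cell identifiers.
#' @param gene_ids character vector of unique gene symbols.
#' @param state normalization state: `"counts"`, `"cpm"` (counts per million)
#'   or `"log10cpm1"` (log10(CPM + 1)).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values),
                        state = c("counts", "cpm", "log10cpm1")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids) || is.null(gene_ids)) {
    ps_stop("cell_ids and gene_ids are required (or set dimnames on 'values')")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    ps_stop("dimension mismatch: %d x %d values vs %d cell ids, %d gene ids",
            nrow(values), ncol(values), length(cell_ids), length(gene_ids))
  }
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) ps_stop("duplicate cell ids: %s", ps_list_some(dup_c))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) ps_stop("duplicate gene ids: %s", ps_list_some(dup_g))
  if (anyNA(values)) ps_stop("expression values contain NA")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)
    ps_stop("negative expression values, first at cell '%s', gene '%s'",
            cell_ids[bad[1, 1]], gene_ids[bad[1, 2]])
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         state = state),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, state = %s\n",
              length(x$cell_ids), length(x$gene_ids), x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

is_expr_matrix <- function(x) inherits(x, "expr_matrix")

assert_state <- function(x, state) {
  if (!is_expr_matrix(x)) ps_stop("expected an expr_matrix")
  if (!identical(x$state, state)) {
    ps_stop("expression matrix must be in state '%s' but is '%s'",
            state, x$state)
  }
  invisible(x)
}

#' Gene set container
#'
#' @param name set name.
#' @param members character vector of gene symbols; whitespace is trimmed.
#'   Duplicate symbols (case-sensitive, after trimming) are an error here;
#'   [read_gene_sets()] instead drops them with a warning.
#' @param description optional free-text description.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = NULL) {
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members)) ps_stop("gene set '%s' has no members", name)
  dup <- unique(members[duplicated(members)])
  if (length(dup)) {
    ps_stop("gene set '%s' has duplicate members: %s", name, ps_list_some(dup))
  }
  structure(
    list(name = as.character(name), members = members,
         description = if (is.null(description)) NA_character_
                       else as.character(description)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

is_gene_set <- function(x) inherits(x, "gene_set")

as_members <- function(x) {
  if (is_gene_set(x)) x$members else trimws(as.character(x))
}
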