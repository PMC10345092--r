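# Readers and writers for every external artifact: expression matrices
# (delimited or MatrixMarket triplet), gene sets (plain list or GMT), cell
# metadata, phenotype tables, and result tables. All delimited IO is UTF-8,
# comma for .csv and tab otherwise; decimal point only.

VALID_STATES <- c("counts", "cpm", "log10cpm1")
VALID_CLASSES <- c("glutamatergic", "GABAergic", "non-neuronal")

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# leading "#key: value" directive lines (e.g. "#state: cpm")
read_directives <- function(path) {
  lines <- character()
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    lines <- c(lines, ln)
  }
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' Read an expression matrix
#'
#' Delimited files carry cell/gene identifiers in the header and first column;
#' an optional leading `#state: <counts|cpm|log10cpm1>` directive records the
#' normalization state. MatrixMarket triplet files need companion
#' one-name-per-line row and column files (defaults: `<path>.rows`,
#' `<path>.cols`).
#'
#' @param path file path.
#' @param format `"delimited"` or `"mtx_triplet"`.
#' @param orientation layout of the file on disk; matrices are returned
#'   cells-by-genes regardless. Auto-detection is deliberately refused (a
#'   square matrix would be ambiguous).
#' @param state normalization state; overrides any header directive. Default
#'   when neither is present: `"counts"`.
#' @param row_names_file,col_names_file companion name files for
#'   `mtx_triplet`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   format = c("delimited", "mtx_triplet"),
                                   orientation = c("cells_x_genes",
                                                   "genes_x_cells"),
                                   state = NULL,
                                   row_names_file = paste0(path, ".rows"),
                                   col_names_file = paste0(path, ".cols")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) ps_stop("file not found: %s", path)

  if (format == "delimited") {
    directives <- read_directives(path)
    if (is.null(state) && !is.null(directives$state)) state <- directives$state
    dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                            skip = length(directives), data.table = FALSE)
    if (ncol(dt) < 2L) ps_stop("expression table needs an id column plus data")
    row_ids <- as.character(dt[[1L]])
    values <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(values)) {
      ps_stop("non-numeric expression values in %s", path)
    }
    rownames(values) <- row_ids
  } else {
    if (!file.exists(row_names_file)) {
      ps_stop("row-name file not found: %s", row_names_file)
    }
    if (!file.exists(col_names_file)) {
      ps_stop("column-name file not found: %s", col_names_file)
    }
    m <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(row_names_file, encoding = "UTF-8")
    col_ids <- readLines(col_names_file, encoding = "UTF-8")
    row_ids <- row_ids[nzchar(row_ids)]
    col_ids <- col_ids[nzchar(col_ids)]
    if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m)) {
      ps_stop(paste0("dimension mismatch: matrix is %d x %d but name files ",
                     "list %d rows and %d columns"),
              nrow(m), ncol(m), length(row_ids), length(col_ids))
    }
    dimnames(m) <- list(row_ids, col_ids)
    values <- m
    state_file <- paste0(path, ".state")
    if (is.null(state) && file.exists(state_file)) {
      state <- trimws(readLines(state_file, n = 1L))
    }
  }

  if (orientation == "genes_x_cells") values <- t(values)
  if (is.null(state)) state <- "counts"
  if (!state %in% VALID_STATES) {
    ps_stop("unknown normalization state '%s' (expected one of %s)",
            state, paste(VALID_STATES, collapse = ", "))
  }
  expr_matrix(values, state = state)
}

#' Write an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param path output path.
#' @param format `"delimited"` (with a `#state:` directive) or
#'   `"mtx_triplet"` (plus `<path>.rows` / `<path>.cols` name files).
#' @param row_names_file,col_names_file companion name files for
#'   `mtx_triplet`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    format = c("delimited", "mtx_triplet"),
                                    row_names_file = paste0(path, ".rows"),
                                    col_names_file = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!is_expr_matrix(x)) ps_stop("expected an expr_matrix")
  if (format == "delimited") {
    sep <- delim_for(path)
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(sprintf("#state: %s", x$state), con)
    close(con)
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = sep, append = TRUE, col.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(x$cell_ids, row_names_file, useBytes = TRUE)
    writeLines(x$gene_ids, col_names_file, useBytes = TRUE)
    # record state in a sidecar directive so round-trips preserve it
    writeLines(x$state, paste0(path, ".state"))
  }
  invisible(path)
}

#' Read gene sets from a plain list or GMT file
#'
#' A plain list yields one set named after the file (extension stripped); a
#' GMT file yields one set per line (`name<TAB>description<TAB>members...`).
#' Member symbols are trimmed; duplicates within a line are dropped with a
#' warning that counts them.
#'
#' @param path file path.
#' @param format `"gmt"` or `"plain_list"`.
#' @return A list of [gene_set()] objects (a single-element list for
#'   `plain_list`), in file order.
#' @export
read_gene_sets <- function(path, format = c("gmt", "plain_list")) {
  format <- match.arg(format)
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")

  if (format == "plain_list") {
    members <- trimws(lines)
    members <- members[nzchar(members)]
    if (!length(members)) ps_stop("empty gene list: %s", path)
    n_dup <- sum(duplicated(members))
    if (n_dup > 0L) {
      ps_warn("%d duplicate symbol(s) dropped from %s", n_dup, basename(path))
      members <- unique(members)
    }
    name <- sub("\\.[^.]*$", "", basename(path))
    return(list(gene_set(name, members)))
  }

  keep <- nzchar(trimws(lines))
  sets <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      ps_stop("GMT line %d has %d tab-separated field(s); need >= 3 (%s)",
              i, length(fields), path)
    }
    members <- trimws(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      ps_stop("GMT line %d ('%s') has an empty member list", i, fields[1L])
    }
    n_dup <- sum(duplicated(members))
    if (n_dup > 0L) {
      ps_warn("%d duplicate symbol(s) dropped from set '%s' (line %d)",
              n_dup, fields[1L], i)
      members <- unique(members)
    }
    j <- j + 1L
    sets[[j]] <- gene_set(fields[1L], members, description = fields[2L])
  }
  if (j == 0L) ps_stop("no gene sets in %s", path)
  sets[seq_len(j)]
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  if (is_gene_set(sets)) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (is.na(s$description)) "na" else s$description
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

numeric_or_na <- function(x, column, path) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
  if (length(bad)) {
    ps_stop("unparseable numeric '%s' in column '%s', data row %d of %s",
            raw[bad[1L]], column, bad[1L], path)
  }
  out
}

#' Read a cell-metadata or phenotype table
#'
#' `cell_metadata` requires columns `cell_id, donor_id, area, cell_class,
#' t_type` with optional `relative_depth` (fraction of L2/L3 depth in
#' \[0, 1\]). `phenotypes` requires `cell_id` with optional `tdl` (total
#' dendritic length, um) and `ap_rise_speed` (V/s). Empty cells in optional
#' numeric columns are kept as `NA` (absent), never as zero.
#'
#' @param path delimited file with a header row.
#' @param schema `"cell_metadata"` or `"phenotypes"`.
#' @return A `data.frame` with typed, validated columns.
#' @export
read_table <- function(path, schema = c("cell_metadata", "phenotypes")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          data.table = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  required <- if (schema == "cell_metadata") {
    c("cell_id", "donor_id", "area", "cell_class", "t_type")
  } else {
    "cell_id"
  }
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    ps_stop("missing required column(s) in %s: %s", path,
            paste(missing_cols, collapse = ", "))
  }
  dup <- unique(dt$cell_id[duplicated(dt$cell_id)])
  if (length(dup)) ps_stop("duplicate cell ids in %s: %s", path,
                           ps_list_some(dup))

  if (schema == "cell_metadata") {
    out <- data.frame(
      cell_id = as.character(dt$cell_id),
      donor_id = as.character(dt$donor_id),
      area = as.character(dt$area),
      cell_class = as.character(dt$cell_class),
      t_type = as.character(dt$t_type),
      stringsAsFactors = FALSE
    )
    bad_class <- setdiff(unique(out$cell_class), VALID_CLASSES)
    if (length(bad_class)) {
      ps_stop("unknown cell_class value(s) in %s: %s (expected %s)", path,
              ps_list_some(bad_class), paste(VALID_CLASSES, collapse = ", "))
    }
    if ("relative_depth" %in% names(dt)) {
      depth <- numeric_or_na(dt$relative_depth, "relative_depth", path)
      bad <- which(!is.na(depth) & (depth < 0 | depth > 1))
      if (length(bad)) {
        ps_stop("relative_depth outside [0, 1] (value %g, data row %d of %s)",
                depth[bad[1L]], bad[1L], path)
      }
      out$relative_depth <- depth
    } else {
      out$relative_depth <- NA_real_
    }
    return(out)
  }

  out <- data.frame(cell_id = as.character(dt$cell_id),
                    stringsAsFactors = FALSE)
  for (col in c("tdl", "ap_rise_speed")) {
    if (col %in% names(dt)) {
      v <- numeric_or_na(dt[[col]], col, path)
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad)) {
        ps_stop("%s must be > 0 when present (value %g, data row %d of %s)",
                col, v[bad[1L]], bad[1L], path)
      }
      out[[col]] <- v
    } else {
      out[[col]] <- NA_real_
    }
  }
  out
}

#' Write a result table
#'
#' Writes any rectangular result collection with a deterministic column
#' order; numeric columns are serialized with 10 significant digits so a
#' read-back reproduces the written values.
#'
#' @param records a `data.frame` (possibly with zero rows).
#' @param path output path.
#' @param format `"delimited"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("delimited", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) ps_stop("unwritable path (no such directory): %s", dir)
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = 10,
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
    return(invisible(path))
  }
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 10)
  }
  data.table::fwrite(out, path, sep = delim_for(path), col.names = TRUE,
                     na = "NA")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file path.
#' @param format `"delimited"` or `"json"`.
#' @return A `data.frame`.
#' @export
read_results <- function(path, format = c("delimited", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  if (format == "json") {
    return(jsonlite::fromJSON(path))
  }
  data.table::fread(path, sep = delim_for(path), header = TRUE,
                    data.table = FALSE, na.strings = "NA")
}
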