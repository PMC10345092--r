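# End-to-end orchestration: score -> compare-groups -> per-phenotype screens
# -> genes-of-interest -> overlap enrichment -> ORA, from one config, with a
# log and a hashed output manifest. Stages run in order; a failure aborts
# with the stage name, leaves earlier outputs intact and drops a FAILED
# marker in the output directory.

#' Pipeline configuration
#'
#' @param matrix path to the expression matrix.
#' @param metadata path to the cell-metadata table.
#' @param phenotypes path to the phenotype table.
#' @param gene_sets path to a GMT file with the gene sets to score/screen.
#' @param annotations optional path to a GO-style GMT catalog for ORA.
#' @param background optional path to a plain-list restricted background
#'   (e.g. brain-expressed genes).
#' @param universe_size optional annotated-universe size for ORA when the
#'   catalog union under-counts it.
#' @param out_dir output directory (created if missing).
#' @param matrix_format,matrix_orientation,matrix_state passed to
#'   [read_expression_matrix()].
#' @param filter_threshold zero-prevalence threshold, default 0.95.
#' @param reference_cells optional cell ids for the prevalence reference.
#' @param fdr_q screen FDR level, default 0.05.
#' @param frem3_boundary FREM3 depth split, default 0.3; `NULL` disables the
#'   split.
#' @param reference_set name of the gene set used as the overlap reference
#'   (default the last set in the GMT, the HAR-style set).
#' @param seed seed recorded for any resampling step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, metadata, phenotypes, gene_sets,
                            annotations = NULL, background = NULL,
                            universe_size = NULL, out_dir = "phenoscreen_out",
                            matrix_format = "delimited",
                            matrix_orientation = "cells_x_genes",
                            matrix_state = NULL,
                            filter_threshold = 0.95, reference_cells = NULL,
                            fdr_q = 0.05, frem3_boundary = 0.3,
                            reference_set = NULL, seed = 1) {
  required <- c(matrix = matrix, metadata = metadata,
                phenotypes = phenotypes, gene_sets = gene_sets)
  missing_files <- required[!file.exists(required)]
  if (length(missing_files)) {
    ps_stop("input file(s) not found: %s",
            paste(names(missing_files), "=", missing_files, collapse = ", "))
  }
  if (fdr_q <= 0 || fdr_q >= 1) ps_stop("fdr_q must be in (0, 1)")
  structure(
    list(matrix = matrix, metadata = metadata, phenotypes = phenotypes,
         gene_sets = gene_sets, annotations = annotations,
         background = background, universe_size = universe_size,
         out_dir = out_dir, matrix_format = matrix_format,
         matrix_orientation = matrix_orientation,
         matrix_state = matrix_state,
         filter_threshold = filter_threshold,
         reference_cells = reference_cells, fdr_q = fdr_q,
         frem3_boundary = frem3_boundary, reference_set = reference_set,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys match the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ps_stop("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("matrix", "metadata", "phenotypes", "gene_sets",
                "annotations", "background", "out_dir")) {
    if (!is.null(raw[[key]]) && !grepl("^(/|[A-Za-z]:)", raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param force overwrite an existing output directory.
#' @return The output manifest, invisibly: a list with `outputs`
#'   (`data.frame` of file, md5), `log` (character lines), `n_summary`
#'   (cells/genes surviving each stage).
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    ps_stop("expected a pipeline_config or a YAML path")
  }
  out_dir <- config$out_dir
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    ps_stop("output directory %s is non-empty; use force = TRUE", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  outputs <- character()
  emit <- function(records, name, format = "delimited") {
    path <- file.path(out_dir, name)
    write_results(records, path, format = format)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed_marker)
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
      ps_stop("pipeline aborted at stage '%s': %s", name,
              conditionMessage(e))
    })
  }

  say("parameters: filter_threshold=%g fdr_q=%g frem3_boundary=%s seed=%d",
      config$filter_threshold, config$fdr_q,
      ifelse(is.null(config$frem3_boundary), "off",
             format(config$frem3_boundary)),
      config$seed)

  # --- load ---------------------------------------------------------------
  inputs <- stage("load", {
    m <- read_expression_matrix(config$matrix, format = config$matrix_format,
                                orientation = config$matrix_orientation,
                                state = config$matrix_state)
    meta <- read_table(config$metadata, "cell_metadata")
    ph <- read_table(config$phenotypes, "phenotypes")
    sets <- read_gene_sets(config$gene_sets, "gmt")
    list(m = m, meta = meta, ph = ph, sets = sets)
  })
  m <- inputs$m
  say("loaded %d cells x %d genes (state %s), %d gene sets",
      nrow(m$values), ncol(m$values), m$state, length(inputs$sets))

  # --- normalize ----------------------------------------------------------
  m <- stage("normalize", {
    if (m$state == "counts") m <- cpm_normalize(m)
    if (m$state == "cpm") m <- log_transform(m)
    m
  })

  meta <- inputs$meta
  if (!is.null(config$frem3_boundary) && any(meta$t_type == "FREM3")) {
    meta <- stage("frem3_split",
                  assign_frem3_layer(meta, config$frem3_boundary))
    say("FREM3 split at depth %g: %d L2, %d L3", config$frem3_boundary,
        sum(meta$t_type == "L2 FREM3"), sum(meta$t_type == "L3 FREM3"))
  }
  emit(meta, "metadata_resolved.tsv")

  # --- score + compare-groups --------------------------------------------
  scored <- stage("score", {
    filters <- list()
    score_rows <- list()
    for (s in inputs$sets) {
      flt <- prevalence_filter(m, s, threshold = config$filter_threshold,
                               reference_cells = config$reference_cells)
      filters[[s$name]] <- flt
      say("set %s: %d/%d genes retained (%d absent)", s$name,
          flt$report$n_retained, flt$report$n_input,
          length(flt$report$absent))
      score_rows[[s$name]] <- gene_set_score(m, flt$retained)
    }
    list(filters = filters, score_rows = score_rows)
  })
  filters <- scored$filters
  score_rows <- scored$score_rows
  scores <- do.call(rbind, score_rows)
  emit(scores, "scores.tsv")

  group_rows <- stage("compare_groups", {
    rows <- list()
    for (s in names(score_rows)) {
      sc <- score_rows[[s]]
      t_type <- meta$t_type[match(sc$cell_id, meta$cell_id)]
      donor <- meta$donor_id[match(sc$cell_id, meta$cell_id)]
      kw <- kruskal_wallis(sc$score, t_type)
      ph <- dunn_holm(sc$score, t_type)
      fr <- tryCatch({
        dm <- suppressWarnings(donor_collapse(sc$score, donor, t_type))
        friedman(dm)
      }, error = function(e) {
        say("set %s: donor-level Friedman skipped (%s)", s,
            conditionMessage(e))
        NULL
      })
      rows[[s]] <- list(
        set = s, kruskal_wallis = list(H = kw$statistic, df = kw$df,
                                       p = kw$p),
        friedman = if (!is.null(fr)) list(chisq = fr$statistic, df = fr$df,
                                          p = fr$p, n_donors = fr$n_donors),
        posthoc = ph
      )
      say("set %s: K-W H=%.3f p=%.3g%s", s, kw$statistic, kw$p,
          if (!is.null(fr)) sprintf("; Friedman chisq=%.3f p=%.3g",
                                    fr$statistic, fr$p) else "")
    }
    rows
  })
  path <- file.path(out_dir, "group_stats.json")
  jsonlite::write_json(group_rows, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  outputs <- c(outputs, path)

  # --- screens ------------------------------------------------------------
  screens <- stage("screen", {
    screens <- list(tdl = list(), ap_rise_speed = list())
    for (which in c("tdl", "ap_rise_speed")) {
      if (all(is.na(inputs$ph[[which]]))) {
        say("phenotype %s absent; screen skipped", which)
        next
      }
      for (s in names(filters)) {
        res <- run_screen(m, inputs$ph, which, filters[[s]]$retained,
                          fdr_q = config$fdr_q, filter_threshold = NULL)
        res$records$set_name <- s
        screens[[which]][[s]] <- res
        emit(res$records, sprintf("screen_%s_%s.tsv", which, s))
        emit(data.frame(set_name = s, phenotype = which, q = res$fdr$q,
                        m = res$fdr$m, critical_p = res$fdr$critical_p,
                        n_significant = res$fdr$n_significant),
             sprintf("fdr_%s_%s.json", which, s), format = "json")
        say("screen %s/%s: %d genes, critical p = %.3g, %d significant",
            which, s, res$fdr$m, res$fdr$critical_p, res$fdr$n_significant)
      }
    }
    screens
  })

  # --- genes of interest + overlap ----------------------------------------
  goi <- NULL
  if (length(inputs$sets) == 3L) {
    goi <- stage("genes_of_interest", {
      bind <- function(lst) if (length(lst)) {
        do.call(rbind, lapply(lst, `[[`, "records"))
      }
      genes_of_interest(bind(screens$tdl), bind(screens$ap_rise_speed),
                        inputs$sets)
    })
    if (!is.null(goi)) {
      emit(data.frame(gene = goi$members), "genes_of_interest.tsv")
      say("genes of interest (>= 2 of 3 sets): %d", length(goi$members))
    } else {
      say("genes of interest: none")
    }

    stage("overlap", {
      ref_name <- if (is.null(config$reference_set)) {
        inputs$sets[[length(inputs$sets)]]$name
      } else config$reference_set
      ref <- NULL
      for (s in inputs$sets) if (s$name == ref_name) ref <- s
      if (is.null(ref)) ps_stop("reference set '%s' not in GMT", ref_name)
      rows <- list()
      for (s in inputs$sets) {
        if (s$name == ref_name) next
        sig <- unique(unlist(lapply(c(screens$tdl[s$name],
                                      screens$ap_rise_speed[s$name]),
                                    function(r) {
          r$records$gene[r$records$significant]
        })))
        if (!length(sig)) next
        enr <- overlap_enrichment(s, intersect(sig, s$members), ref)
        rows[[s$name]] <- data.frame(
          set = s$name, reference = ref_name,
          n_correlated = length(sig),
          percent_subset = enr$percent_subset,
          percent_full = enr$percent_full,
          odds_ratio = enr$odds_ratio, p_one_sided = enr$p_one_sided
        )
        say("overlap %s vs %s: %.1f%% of correlated vs %.1f%% overall, p=%.3g",
            s$name, ref_name, enr$percent_subset, enr$percent_full,
            enr$p_one_sided)
      }
      if (length(rows)) emit(do.call(rbind, rows), "overlap_enrichment.tsv")
    })
  }

  # --- ORA ----------------------------------------------------------------
  if (!is.null(config$annotations)) {
    stage("ora", {
      if (!file.exists(config$annotations)) {
        ps_stop("annotation file not found: %s", config$annotations)
      }
      if (is.null(goi)) ps_stop("no genes of interest to test")
      catalog <- annotation_catalog(
        read_gene_sets(config$annotations, "gmt"),
        universe_size = config$universe_size
      )
      ora <- over_representation(goi, catalog)
      emit(ora[, setdiff(names(ora), "genes")], "ora_full_universe.tsv")
      say("ORA (full universe): %d terms, %d significant", nrow(ora),
          sum(ora$significant))
      if (!is.null(config$background)) {
        bg <- read_gene_sets(config$background, "plain_list")[[1]]
        ora_bg <- restricted_background_ora(goi, catalog, bg)
        emit(ora_bg[, setdiff(names(ora_bg), "genes")],
             "ora_restricted_background.tsv")
        say("ORA (restricted background): %d terms, %d significant",
            nrow(ora_bg), sum(ora_bg$significant))
      }
    })
  }

  # --- manifest -----------------------------------------------------------
  log_path <- file.path(out_dir, "pipeline.log")
  writeLines(log_lines, log_path)
  manifest <- list(
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE),
    log = log_lines,
    seed = config$seed
  )
  jsonlite::write_json(manifest["outputs"], file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
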