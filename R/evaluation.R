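# Ground-truth evaluation of the screen on generated data: one call
# generates a dataset, runs the CPM -> log10 -> prevalence-filter -> per-gene
# screen chain, and scores discoveries against the planted truth.

#' Simulate one dataset and evaluate the phenotype screen against truth
#'
#' Generates a dataset from `config`, normalizes, screens the given gene set
#' (default: the whole gene universe) against the chosen phenotype with BH
#' control, and compares flagged genes to the planted truth.
#'
#' @param config a [synthetic_config()].
#' @param which phenotype screened, default `"ap_rise_speed"` (the linear
#'   phenotype the planted correlation is calibrated against).
#' @param fdr_q BH level, default 0.05.
#' @param filter_threshold zero-prevalence threshold, default 0.95.
#' @param set optional [gene_set()] to screen; default all genes.
#' @return A list: `fdp` (false positives over flagged, 0 when none
#'   flagged), `sensitivity` (flagged planted over planted tested; NA with no
#'   planted genes), `n_flagged`, `n_false`, `n_tested`, `critical_p`,
#'   `records`, `truth`.
#' @export
simulate_screen <- function(config, which = "ap_rise_speed", fdr_q = 0.05,
                            filter_threshold = 0.95, set = NULL) {
  data <- generate_dataset(config)
  m <- log_transform(cpm_normalize(data$matrix))
  if (is.null(set)) set <- gene_set("universe", data$matrix$gene_ids)
  res <- run_screen(m, data$phenotypes, which, set, fdr_q = fdr_q,
                    filter_threshold = filter_threshold)
  flagged <- res$records$gene[res$records$significant]
  planted <- data$truth$planted$gene
  n_false <- sum(!flagged %in% planted)
  fdp <- if (length(flagged)) n_false / length(flagged) else 0
  tested_planted <- intersect(planted, res$records$gene)
  sensitivity <- if (length(tested_planted)) {
    mean(tested_planted %in% flagged)
  } else {
    NA_real_
  }
  list(fdp = fdp, sensitivity = sensitivity, n_flagged = length(flagged),
       n_false = n_false, n_tested = nrow(res$records),
       critical_p = res$fdr$critical_p, records = res$records,
       truth = data$truth)
}
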