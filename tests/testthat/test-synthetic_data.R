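test_that("generation is deterministic and keyed substreams isolate components", {
  cfg <- mk_screen_config(42, n_planted = 5, n_cells = 30, n_genes = 100)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$planted, b$truth$planted)

  # adding cells leaves existing cells' draws untouched
  cfg_more <- mk_screen_config(42, n_planted = 5, n_cells = 40, n_genes = 100)
  c <- generate_dataset(cfg_more)
  shared <- a$matrix$cell_ids
  expect_identical(c$matrix$values[shared, ], a$matrix$values[shared, ])
})

test_that("gene sets realize the configured overlap structure", {
  sets <- generate_gene_sets(n_genes = 2000, sizes = c(100, 100, 100),
                             pairwise_overlap = c(0.14, 0.25, 0.19),
                             triple_overlap = 0.05, seed = 3)
  ab <- length(intersect(sets[[1]]$members, sets[[2]]$members))
  ac <- length(intersect(sets[[1]]$members, sets[[3]]$members))
  bc <- length(intersect(sets[[2]]$members, sets[[3]]$members))
  expect_equal(ab, 14)
  expect_equal(ac, 25)
  expect_equal(bc, 19)
  expect_equal(lengths(lapply(sets, `[[`, "members")),
               c(100L, 100L, 100L))

  # zero overlap: pairwise disjoint
  disj <- generate_gene_sets(n_genes = 500, sizes = c(50, 50, 50),
                             pairwise_overlap = c(0, 0, 0),
                             triple_overlap = 0, seed = 1)
  expect_length(intersect(disj[[1]]$members, disj[[2]]$members), 0L)
  expect_length(intersect(disj[[1]]$members, disj[[3]]$members), 0L)

  # full overlap with equal sizes: identical sets
  same <- generate_gene_sets(n_genes = 500, sizes = c(40, 40, 40),
                             pairwise_overlap = c(1, 1, 1),
                             triple_overlap = 1, seed = 1)
  expect_setequal(same[[1]]$members, same[[2]]$members)
  expect_setequal(same[[1]]$members, same[[3]]$members)

  expect_error(generate_gene_sets(n_genes = 100, sizes = c(80, 80, 80),
                                  pairwise_overlap = c(0, 0, 0),
                                  triple_overlap = 0, seed = 1),
               "universe")
})

test_that("planted correlations hit their target on average", {
  # mean |empirical r| across planted genes and replicates within 0.1 of the
  # target (20 replicates x 10 genes)
  rs <- unlist(lapply(1:20, function(s) {
    cfg <- mk_screen_config(s, n_planted = 10, target_r = 0.6,
                            n_cells = 120, n_genes = 300)
    d <- generate_dataset(cfg)
    m <- log_transform(cpm_normalize(d$matrix))
    vapply(seq_len(nrow(d$truth$planted)), function(i) {
      abs(cor(m$values[, d$truth$planted$gene[i]],
              d$phenotypes$ap_rise_speed))
    }, numeric(1))
  }))
  expect_lt(abs(mean(rs) - 0.6), 0.1)
})

test_that("an unattainable target correlation errors with the bound", {
  cfg <- mk_screen_config(1, n_planted = 5, target_r = 0.95,
                          n_cells = 50, n_genes = 100)
  expect_error(generate_dataset(cfg), "caps the gene-phenotype correlation")
})

test_that("a fully null dataset yields (almost) no discoveries", {
  sim <- simulate_screen(mk_screen_config(202, n_planted = 0,
                                          n_cells = 150, n_genes = 500))
  expect_lte(sim$n_flagged, 3L)
  expect_true(is.na(sim$sensitivity))
})

test_that("the coupled latent factor reproduces the L3-type expression pattern", {
  # planted module + elevated latent factor in one deep-L3-like type: that
  # type shows the highest set score and the K-W test sees it clearly
  cfg <- synthetic_config(
    t_types = data.frame(name = c("LTK", "GLP2R", "CARM1P1"),
                         depth_min = c(0, 0.3, 0.6),
                         depth_max = c(0.3, 0.6, 1)),
    n_cells_per_type = 40,
    type_effects = c(LTK = -0.6, GLP2R = -0.2, CARM1P1 = 0.9),
    n_genes = 600,
    sets = list(names = c("IQ", "EA", "HAR"), sizes = c(60, 60, 60),
                pairwise_overlap = c(0.2, 0.15, 0.2), triple_overlap = 0.05),
    planted = list(n_per_set = 15, target_r = 0.6, prop_positive = 1,
                   baseline_range = c(1, 2.5), bias_set = NULL,
                   bias_factor = 1),
    seed = 11
  )
  d <- generate_dataset(cfg)
  m <- log_transform(cpm_normalize(d$matrix))
  flt <- prevalence_filter(m, d$gene_sets[[1]])
  sc <- gene_set_score(m, flt$retained)
  t_type <- d$metadata$t_type[match(sc$cell_id, d$metadata$cell_id)]
  med <- tapply(sc$score, t_type, median)
  expect_equal(names(which.max(med)), "CARM1P1")
  expect_lt(kruskal_wallis(sc$score, t_type)$p, 0.01)

  # TDL and AP rise speed co-vary through the shared latent factor
  expect_gt(cor(d$phenotypes$tdl, d$phenotypes$ap_rise_speed), 0.3)
  # and the positively-correlated-gene summary peaks in the same type
  scr <- run_screen(m, d$phenotypes, "ap_rise_speed", flt$retained)
  pos <- correlated_gene_summary(m, scr$records, d$metadata, "+")
  if (nrow(pos$summary)) {
    med_pos <- tapply(pos$summary$mean_expression, pos$summary$t_type, median)
    expect_equal(names(which.max(med_pos)), "CARM1P1")
  }
})

test_that("HAR-biased planting is detected by the overlap enrichment chain", {
  # planted genes drawn from the IQ-like set with 2x weight on HAR members:
  # the enrichment of HAR membership among screen hits is detected in most
  # replicates (scaled-down version of the full study conditions)
  hits <- vapply(1:50, function(s) {
    cfg <- synthetic_config(
      t_types = data.frame(name = "FREM3", depth_min = 0, depth_max = 1),
      n_cells_per_type = 150, type_effects = c(FREM3 = 0), n_genes = 1200,
      # default set structure; planting weighted so planted genes land in
      # the HAR-like set at twice the 14% baseline rate
      planted = list(n_per_set = 20, target_r = 0.6, prop_positive = 0.7,
                     baseline_range = c(1, 2.5), bias_set = "HAR",
                     bias_factor = 2.4),
      seed = s
    )
    d <- generate_dataset(cfg)
    m <- log_transform(cpm_normalize(d$matrix))
    iq <- d$gene_sets[[1]]
    har <- d$gene_sets[[3]]
    scr <- run_screen(m, d$phenotypes, "ap_rise_speed", iq)
    sig <- scr$records$gene[scr$records$significant]
    if (length(sig) < 2) return(NA)
    enr <- overlap_enrichment(iq, sig, har)
    enr$p_one_sided < 0.05
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.7)
})
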