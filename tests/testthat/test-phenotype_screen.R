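test_that("per-gene association handles exact fits, constants and the t formula", {
  set.seed(3)
  pheno_vals <- rnorm(10, 5000, 800)
  v <- cbind(linear = 0.001 * pheno_vals + 2, # exact linear gene
             flat = rep(1, 10),
             noisy = rnorm(10, mean = 5))
  m <- mk_matrix(v, genes = colnames(v), state = "log10cpm1")
  ph <- data.frame(cell_id = m$cell_ids, tdl = pheno_vals,
                   ap_rise_speed = NA_real_)
  rec <- per_gene_association(m, ph, "tdl", c("linear", "flat", "noisy"))
  lin <- rec[rec$gene == "linear", ]
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-12)
  expect_identical(attr(rec, "dropped_constant"), "flat")
  expect_equal(lin$sign, "+")
  expect_equal(lin$slope, 0.001, tolerance = 1e-12)
})

test_that("the slope test equals the Pearson t-test and the lm oracle", {
  # engineered r = 0.5 at n = 20: t = 0.5 sqrt(18)/sqrt(0.75), p ~ 0.0249
  n <- 20
  set.seed(8)
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  e <- e / sd(e) * sd(x)
  y <- 0.5 * x + sqrt(1 - 0.25) * e
  m <- mk_matrix(cbind(g = y - min(y)), genes = "g", state = "log10cpm1")
  ph <- data.frame(cell_id = m$cell_ids, tdl = x + 10,
                   ap_rise_speed = NA_real_)
  rec <- per_gene_association(m, ph, "tdl", "g")
  expect_equal(rec$r, 0.5, tolerance = 1e-10)
  expect_equal(rec$p, 2 * pt(-0.5 * sqrt(18) / sqrt(0.75), 18),
               tolerance = 1e-12)
  expect_equal(rec$p, 0.0249, tolerance = 1e-2)

  # OLS equivalence on 200 random instances
  for (i in 1:200) {
    set.seed(i)
    n_i <- sample(5:40, 1)
    pheno <- rnorm(n_i)
    expr <- rnorm(n_i) + 0.3 * pheno
    mi <- mk_matrix(cbind(g = expr - min(expr)), genes = "g",
                    state = "log10cpm1")
    phi <- data.frame(cell_id = mi$cell_ids, tdl = pheno,
                      ap_rise_speed = NA_real_)
    rec <- per_gene_association(mi, phi, "tdl", "g")
    fit <- summary(lm((expr - min(expr)) ~ pheno))$coefficients
    expect_equal(rec$slope, fit["pheno", "Estimate"], tolerance = 1e-10)
    expect_equal(rec$p, fit["pheno", "Pr(>|t|)"], tolerance = 1e-10)
  }

  expect_error(per_gene_association(m, data.frame(cell_id = "zz",
                                                  tdl = 1,
                                                  ap_rise_speed = NA_real_),
                                    "tdl", "g"), "no cells shared")
  ph$tdl <- 7
  expect_error(per_gene_association(m, ph, "tdl", "g"), "constant")
})

test_that("BH step-up finds the critical p and flags by p <= critical", {
  bh <- benjamini_hochberg(c(0.001, 0.01, 0.02, 0.03, 0.04))
  expect_equal(bh$critical_p, 0.04)
  expect_equal(bh$n_significant, 5L)

  none <- benjamini_hochberg(c(0.9, 0.95, 1.0))
  expect_equal(none$critical_p, 0)
  expect_equal(none$n_significant, 0L)

  single <- benjamini_hochberg(0.04)
  expect_equal(single$critical_p, 0.04)
  expect_true(single$significant)

  expect_error(benjamini_hochberg(numeric()), "empty")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force threshold-scan oracle and p.adjust cross-check
  for (i in 1:100) {
    set.seed(i)
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    bh_i <- benjamini_hochberg(p, 0.05)
    orc <- oracle_bh(p, 0.05)
    expect_equal(bh_i$critical_p, orc$critical_p, tolerance = 1e-14)
    expect_identical(bh_i$significant, orc$significant)
    expect_identical(bh_i$significant, unname(p.adjust(p, "BH") <= 0.05))
  }
})

test_that("heatmap bundles are z-scored and deterministically ordered", {
  set.seed(21)
  n <- 12
  v <- matrix(rexp(n * 3), n, 3, dimnames = list(sprintf("c%02d", 1:n),
                                                 c("g1", "g2", "g3")))
  m <- mk_matrix(v, cells = rownames(v), genes = colnames(v),
                 state = "log10cpm1")
  pheno <- c(rep(100, 2), seq(200, 1100, length.out = n - 2))
  ph <- data.frame(cell_id = m$cell_ids, tdl = pheno,
                   ap_rise_speed = NA_real_)
  rec <- data.frame(gene = c("g1", "g2", "g3"),
                    p = c(1e-3, 1e-5, 1e-4),
                    sign = c("+", "+", "-"),
                    significant = TRUE, stringsAsFactors = FALSE)
  attr(rec, "phenotype") <- "tdl"
  hb <- build_heatmap_bundle(m, ph, rec)
  expect_equal(hb$gene_order, c("g2", "g3", "g1")) # by raw p ascending
  expect_equal(hb$cell_order[1:2], c("c01", "c02")) # tie broken by cell id
  expect_equal(unname(rowMeans(hb$matrix)), rep(0, 3), tolerance = 1e-9)
  pop_sd <- sqrt(rowMeans(hb$matrix^2))
  expect_equal(unname(pop_sd), rep(1, 3), tolerance = 1e-9)
  expect_identical(hb$partition$negative, "g3")
})

test_that("sign-selected summaries collapse to per-cell means across t-types", {
  v <- cbind(pos1 = c(1, 2, 3, 4), pos2 = c(3, 4, 5, 6), neg = c(9, 8, 7, 6))
  m <- mk_matrix(v, genes = colnames(v), state = "log10cpm1")
  meta <- data.frame(cell_id = m$cell_ids, donor_id = "d1", area = "MTG",
                     cell_class = "glutamatergic",
                     t_type = c("A", "A", "B", "B"),
                     relative_depth = NA_real_, stringsAsFactors = FALSE)
  rec <- data.frame(gene = colnames(v), sign = c("+", "+", "-"),
                    significant = c(TRUE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  pos <- correlated_gene_summary(m, rec, meta, "+")
  expect_equal(pos$summary$mean_expression, c(2, 3, 4, 5))
  expect_s3_class(pos$test, "group_test")

  # a single selected gene reduces to that gene's expression
  rec1 <- rec[rec$gene == "neg", ]
  neg <- correlated_gene_summary(m, rec1, meta, "-")
  expect_equal(neg$summary$mean_expression, unname(v[, "neg"]))

  # no genes of the requested sign: empty summary, not an error
  none <- correlated_gene_summary(m, rec1, meta, "+")
  expect_equal(nrow(none$summary), 0L)
  expect_null(none$test)
})

test_that("run_screen chains filter, association and FDR with p-ranked output", {
  sim <- simulate_screen(mk_screen_config(5, n_planted = 10, target_r = 0.6,
                                          n_cells = 100, n_genes = 300))
  expect_true(all(diff(sim$records$p) >= 0))
  expect_equal(sim$records$significant,
               sim$records$p <= sim$critical_p &
                 rep(sim$critical_p > 0, nrow(sim$records)))
  # planted effects at r = 0.6 are nearly all recovered
  expect_gte(sim$sensitivity, 0.8)
})
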