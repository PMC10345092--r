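test_that("Kruskal-Wallis reproduces hand-computed and base-R values", {
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2) # mean ranks 2/5/8, N = 9
  expect_equal(kw$df, 2L)

  # identical groups: no rank separation
  flat <- kruskal_wallis(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  # rank invariance under monotone transforms
  set.seed(1)
  x <- rnorm(30)
  g <- sample(letters[1:3], 30, replace = TRUE)
  expect_equal(kruskal_wallis(exp(x), g)$statistic,
               kruskal_wallis(x, g)$statistic)

  # agreement with stats::kruskal.test on tied data
  for (i in 1:25) {
    set.seed(i)
    x <- sample(1:6, 40, replace = TRUE) # heavy ties
    g <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
    if (length(unique(g)) < 2) next
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Dunn z and Holm adjustment follow their defining rules", {
  # one group shifted far from two identical others: its two pairs get the
  # smallest adjusted p
  set.seed(7)
  x <- c(rnorm(12), rnorm(12), rnorm(12) + 50)
  g <- rep(c("a", "b", "c"), each = 12)
  d <- dunn_holm(x, g)
  with_c <- d$group_a == "c" | d$group_b == "c"
  expect_true(max(d$p_adjusted[with_c]) < min(d$p_adjusted[!with_c]))
  expect_true(all(d$p_adjusted >= d$p_raw - 1e-15))

  # Holm on raw {0.01, 0.02, 0.04} -> {0.03, 0.04, 0.04}
  expect_equal(phenoscreen:::holm_adjust(c(0.01, 0.02, 0.04)),
               c(0.03, 0.04, 0.04))
  # and against both the step-down oracle and p.adjust on random vectors
  for (i in 1:20) {
    set.seed(i)
    p <- runif(sample(2:8, 1))
    expect_equal(phenoscreen:::holm_adjust(p), oracle_holm(p),
                 tolerance = 1e-12)
    expect_equal(phenoscreen:::holm_adjust(p), p.adjust(p, "holm"),
                 tolerance = 1e-12)
  }

  # identical groups: all adjusted p = 1
  flat <- dunn_holm(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_true(all(flat$p_adjusted == 1))

  # restricted family keeps only pairs touching the reference groups
  d_ref <- dunn_holm(x, g, reference = "a")
  expect_true(all(d_ref$group_a == "a" | d_ref$group_b == "a"))
  expect_equal(nrow(d_ref), 2L)
})

test_that("Dunn ranking matches a permutation-test oracle on separation order", {
  # permutation p for the mean-rank difference of each pair must order the
  # pairs the same way as the Dunn z
  set.seed(11)
  x <- c(rnorm(8), rnorm(8) + 0.5, rnorm(8) + 3)
  g <- rep(c("a", "b", "c"), each = 8)
  d <- dunn_holm(x, g)
  perm_p <- vapply(seq_len(nrow(d)), function(i) {
    keep <- g %in% c(d$group_a[i], d$group_b[i])
    xs <- x[keep]; gs <- g[keep]
    obs <- abs(mean(rank(x)[g == d$group_a[i]]) -
               mean(rank(x)[g == d$group_b[i]]))
    hits <- 0
    for (b in 1:2000) {
      gp <- sample(g)
      stat <- abs(mean(rank(x)[gp == d$group_a[i]]) -
                  mean(rank(x)[gp == d$group_b[i]]))
      if (stat >= obs - 1e-12) hits <- hits + 1
    }
    hits / 2000
  }, numeric(1))
  expect_equal(order(perm_p), order(d$p_raw))
})

test_that("donor collapse produces complete median blocks", {
  vals <- c(1, 2, 9, 4, 5, 6, 7, 8)
  donors <- c("d1", "d1", "d1", "d1", "d2", "d2", "d2", "d2")
  conds <- c("A", "A", "A", "B", "A", "A", "B", "B")
  m <- donor_collapse(vals, donors, conds)
  expect_equal(m["d1", "A"], 2) # median of {1,2,9}
  expect_equal(dim(m), c(2L, 2L))

  # donor missing a condition is dropped with a warning
  expect_warning(
    m2 <- donor_collapse(c(vals, 10), c(donors, "d3"), c(conds, "A")),
    "d3"
  )
  expect_equal(rownames(m2), c("d1", "d2"))

  expect_error(
    suppressWarnings(donor_collapse(c(1, 2), c("d1", "d2"), c("A", "B"))),
    "2 complete donors"
  )

  # 3 donors x 6 conditions complete
  full <- expand.grid(d = paste0("d", 1:3), c = LETTERS[1:6])
  m3 <- donor_collapse(seq_len(nrow(full)), full$d, full$c)
  expect_equal(dim(m3), c(3L, 6L))
})

test_that("Friedman statistic matches hand computation, symmetry and base R", {
  # three donors ranking three conditions identically: rank sums 3/6/9
  m <- matrix(rep(c(1, 2, 3), 3), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("d", 1:3), c("A", "B", "C")))
  fr <- friedman(m)
  expect_equal(fr$statistic, 6)
  expect_equal(fr$df, 2L)

  # permuting condition columns leaves the statistic unchanged
  expect_equal(friedman(m[, c(3, 1, 2)])$statistic, fr$statistic)

  # all values equal: statistic 0
  expect_equal(friedman(matrix(5, 3, 3))$statistic, 0)

  # agreement with stats::friedman.test on tie-free matrices
  for (i in 1:25) {
    set.seed(i)
    mm <- matrix(sample(1:1000, 12), 4, 3)
    ref <- stats::friedman.test(mm)
    ours <- friedman(mm)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  expect_error(friedman(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "incomplete")
  expect_error(friedman(matrix(1:4, 2, 2)), "3 conditions")
})

test_that("exact Friedman permutation p identifies 6.0 as the n=3, k=3 maximum", {
  m <- matrix(rep(c(1, 2, 3), 3), nrow = 3, byrow = TRUE)
  fr <- friedman(m, exact = TRUE)
  expect_equal(fr$statistic, 6)
  # only the 6 all-donors-agree orderings of 6^3 reach the maximum
  expect_equal(fr$p_exact, 6 / 216)
  # asymptotic p points the same direction (small)
  expect_lt(fr$p, 0.06)
})

test_that("Kruskal-Wallis p values are calibrated under the null", {
  set.seed(19)
  reject <- logical(1000)
  for (i in seq_len(1000)) {
    x <- rnorm(60)
    g <- rep(c("a", "b", "c"), each = 20)
    reject[i] <- kruskal_wallis(x, g)$p < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})
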