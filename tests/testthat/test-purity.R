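toy_expr <- function(values, genes = sprintf("G%02d", seq_along(values))) {
  matrix(values, ncol = 1, dimnames = list(genes, "S1"))
}

test_that("ssgsea score increases with rank placement of the set", {
  genes <- sprintf("G%02d", 1:10)
  top <- matrix(10:1, ncol = 1, dimnames = list(genes, "S"))
  set_top <- gene_set("s", genes[1:2])     # occupy the top 2 ranks
  set_bot <- gene_set("s", genes[9:10])    # occupy the bottom 2 ranks
  expect_gt(ssgsea_score(top, set_top), ssgsea_score(top, set_bot))
})

test_that("ssgsea matches the hand-enumerated running sum on 6 genes", {
  # 6 genes ranked 6..1; the 2-gene set sits at ranks 6 and 3. Walking the
  # descending rank list, the running sum telescopes to
  # 3 * w6 / (w6 + w3) with w = rank^0.25.
  expr <- toy_expr(c(60, 50, 40, 30, 20, 10))
  set <- gene_set("s", c("G01", "G04"))
  expected <- 3 * 6^0.25 / (6^0.25 + 3^0.25)
  expect_equal(as.numeric(ssgsea_score(expr, set, alpha = 0.25)), expected,
               tolerance = 1e-12)
})

test_that("scores are per-sample: permuting samples permutes scores", {
  set.seed(1)
  expr <- matrix(rnorm(60), 10, 6,
                 dimnames = list(sprintf("G%02d", 1:10),
                                 sprintf("S%d", 1:6)))
  set <- gene_set("s", c("G01", "G05", "G09"))
  sc <- ssgsea_score(expr, set)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(as.numeric(ssgsea_score(expr[, perm], set)),
               as.numeric(sc[perm]))
})

test_that("scores are invariant under strictly monotone transforms", {
  set.seed(2)
  expr <- matrix(rexp(40), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10),
                                 sprintf("S%d", 1:4)))
  set <- gene_set("s", c("G02", "G07"))
  expect_equal(ssgsea_score(expr, set), ssgsea_score(log1p(expr), set))
  expect_equal(ssgsea_score(expr, set), ssgsea_score(expr^3, set))
})

test_that("estimate_scores sums components exactly and errors usefully", {
  set.seed(3)
  expr <- matrix(rnorm(80), 20, 4,
                 dimnames = list(sprintf("G%02d", 1:20),
                                 sprintf("S%d", 1:4)))
  stromal <- gene_set("stromal", c("G01", "G02", "G03"))
  immune <- gene_set("immune", c("G10", "G11"))
  res <- estimate_scores(expr, stromal, immune)
  expect_identical(res$combined_score, res$stromal_score + res$immune_score)
  expect_error(
    estimate_scores(expr, gene_set("missing", "NOT_THERE"), immune),
    "missing")
})

test_that("the cosine purity formula evaluates and inverts correctly", {
  expect_equal(as.numeric(purity_from_score(0)), cos(0.6049872018))
  expect_equal(as.numeric(purity_from_score(0)), 0.8225, tolerance = 1e-4)
  # score at which purity hits 0.60, from inverting the closed form
  s60 <- (acos(0.60) - 0.6049872018) / 0.0001467884
  expect_equal(s60, 2196, tolerance = 1e-3)
  expect_equal(as.numeric(purity_from_score(s60)), 0.60, tolerance = 1e-12)
  # strictly decreasing while the cosine stays non-negative
  scores <- seq(0, 6000, length.out = 50)
  expect_true(all(diff(as.numeric(purity_from_score(scores))) < 0))
  # scores pushing the cosine below zero clamp to 0 with a flag
  p <- purity_from_score(c(0, 8000))
  expect_equal(as.numeric(p[2]), 0)
  expect_true(attr(p, "clamped")[2])
  expect_false(attr(p, "clamped")[1])
})

test_that("purity filter is boundary-inclusive and handles degenerate cuts", {
  res <- data.frame(sample_id = c("a", "b", "c"),
                    purity = c(0.59, 0.60, 0.61))
  expect_equal(filter_by_purity(res, 0.60), c("b", "c"))
  expect_equal(filter_by_purity(res, 0), c("a", "b", "c"))
  expect_warning(keep <- filter_by_purity(res, 1), "no samples")
  expect_length(keep, 0)
})

test_that("estimated purity tracks planted admixture on synthetic cohorts", {
  # noise-free: strictly decreasing purity across the 5 admixture levels
  dir <- withr::local_tempdir()
  cfg <- cohort_config(seed = 21, n_tumors = 5, n_cell_lines = 2,
                       expression_noise_sd = 0)
  sim <- simulate_cohort(cfg, dir)
  expr <- read_expression(sim$paths$expression_tumors)
  stromal <- read_gene_set(sim$paths$stromal_set)
  immune <- read_gene_set(sim$paths$immune_set)
  res <- estimate_purity(expr, stromal, immune)
  truth <- sim$truth[match(res$sample_id, sim$truth$sample_id), ]
  expect_equal(cor(res$purity, truth$purity, method = "spearman"), 1)
  # stromal score rises monotonically with the planted stromal fraction
  expect_equal(cor(res$stromal_score, 1 - truth$purity,
                   method = "spearman"), 1)

  # under the default noise model the ordering survives (rho <= -0.9
  # against planted admixture)
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_cohort(cohort_config(seed = 22, n_tumors = 20,
                                        n_cell_lines = 2), dir2)
  expr2 <- read_expression(sim2$paths$expression_tumors)
  res2 <- estimate_purity(expr2, stromal, immune)
  truth2 <- sim2$truth[match(res2$sample_id, sim2$truth$sample_id), ]
  expect_lte(cor(res2$purity, 1 - truth2$purity, method = "spearman"),
             -0.9)
})
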