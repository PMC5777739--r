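test_that("segment-to-gene projection assigns contained and split genes", {
  model <- make_model(c("GA", "GB", "GX"), c("1", "1", "X"),
                      c(100, 100, 10), c(200, 299, 90))
  segs <- make_seg(rep("S1", 3), c("1", "1", "X"),
                   c(1, 150, 1), c(149, 1000, 1000),
                   c(0.0, 0.4, 2))
  # GA [100,200]: 50 bp in seg1 (mean 0) + 51 bp in seg2 (mean 0.4)
  m <- project_segments_to_genes(segs, model, drop_xy = FALSE)
  expect_equal(m["GA", "S1"], (50 * 0 + 51 * 0.4) / 101)
  # GB [100,299]: 50 bp at 0.0, 150 bp at 0.4 -> 0.3
  expect_equal(m["GB", "S1"], (50 * 0 + 150 * 0.4) / 200)
  expect_equal(m["GX", "S1"], 2)

  # gene fully inside one segment carries exactly that value
  model2 <- make_model("G1", "1", 160, 180)
  m2 <- project_segments_to_genes(segs, model2)
  expect_equal(m2["G1", "S1"], 0.4)

  # X genes dropped by default
  mx <- project_segments_to_genes(segs, model, drop_xy = TRUE)
  expect_false("GX" %in% rownames(mx))
  # gene with no overlapping segment is missing
  model3 <- make_model(c("G1", "GFAR"), c("1", "2"), c(160, 10),
                       c(180, 90))
  m3 <- project_segments_to_genes(segs, model3)
  expect_true(is.na(m3["GFAR", "S1"]))
})

test_that("FGA follows the length-weighted thresholded formula", {
  prof <- make_seg(rep("S", 2), "1", c(1, 3e6 + 1), c(3e6, 4e6),
                   c(0.5, 0.1))
  expect_equal(fga(prof, threshold = 0.2)$fga, 0.75)  # 3 Mb of 4 Mb

  low <- make_seg(rep("S", 2), "1", c(1, 101), c(100, 300), c(0.1, -0.2))
  expect_equal(fga(low, threshold = 0.2)$fga, 0)      # |mean| <= T
  high <- make_seg(rep("S", 2), "1", c(1, 101), c(100, 300), c(0.5, -0.9))
  expect_equal(fga(high, threshold = 0.2)$fga, 1)

  # strict inequality at the threshold: |mean| == T does not count
  at <- make_seg("S", "1", 1, 100, 0.2)
  expect_equal(fga(at, threshold = 0.2)$fga, 0)

  # X/Y segments excluded from numerator and denominator
  sexy <- make_seg(rep("S", 2), c("1", "X"), c(1, 1), c(100, 1e6),
                   c(0.5, 0.5))
  expect_equal(fga(sexy)$total_length, 100)
  expect_equal(fga(sexy)$fga, 1)

  expect_error(fga(make_seg(character(0), character(0), numeric(0),
                            numeric(0), numeric(0))), "empty")
})

test_that("FGA is invariant under segment subdivision", {
  set.seed(7)
  for (i in 1:5) {
    n <- 6
    starts <- cumsum(c(1, sample(1e4:1e5, n - 1)))
    ends <- starts + sample(1e4:1e5, n)
    means <- rnorm(n, 0, 0.4)
    whole <- make_seg(rep("S", n), "1", starts, ends, means)
    # split every segment at its midpoint, same mean
    mid <- floor((starts + ends) / 2)
    split <- make_seg(rep("S", 2 * n), "1",
                      c(starts, mid + 1), c(mid, ends), c(means, means))
    expect_equal(fga(split)$fga, fga(whole)$fga, tolerance = 1e-12)
  }
})

test_that("pairwise gene CN correlation handles exact and degenerate cases", {
  genes <- sprintf("G%d", 1:5)
  a <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(genes, "CL1"))
  b <- cbind(T1 = c(1, 2, 3, 4, 5), T2 = -c(1, 2, 3, 4, 5),
             T3 = c(2, 4, 5, 4, 5))
  rownames(b) <- genes
  cc <- pairwise_gene_cn_correlation(a, b)
  expect_equal(cc$r["CL1", "T1"], 1)
  expect_equal(cc$r["CL1", "T2"], -1)
  # closed form by hand: cov deviations (-2,-1,0,1,2).(−2,0,1,0,1) = 6,
  # sds sqrt(10)*sqrt(6)/4 -> r = 6/sqrt(60)
  expect_equal(cc$r["CL1", "T3"], 6 / sqrt(60))
  expect_equal(cc$r["CL1", "T3"], cor(c(1, 2, 3, 4, 5), c(2, 4, 5, 4, 5)))

  # too few usable genes -> NA with reason
  b_na <- b; b_na[1:3, "T1"] <- NA
  cc2 <- pairwise_gene_cn_correlation(a, b_na)
  expect_true(is.na(cc2$r["CL1", "T1"]))
  expect_equal(cc2$reason["CL1", "T1"], "too_few_genes")
  expect_equal(cc2$n_genes_used["CL1", "T1"], 2L)

  # zero variance -> NA with reason
  b_flat <- b; b_flat[, "T2"] <- 1
  cc3 <- pairwise_gene_cn_correlation(a, b_flat)
  expect_equal(cc3$reason["CL1", "T2"], "zero_variance")

  # gene_subset restricts the universe
  cc4 <- pairwise_gene_cn_correlation(a, b, gene_subset = genes[1:3])
  expect_equal(cc4$n_genes_used["CL1", "T1"], 3L)
})

test_that("mean-profile correlation reduces to pairwise for trivial cohorts", {
  genes <- sprintf("G%d", 1:6)
  set.seed(11)
  a <- matrix(rnorm(12), 6, 2, dimnames = list(genes, c("CL1", "CL2")))
  b1 <- matrix(rnorm(6), 6, 1, dimnames = list(genes, "T1"))
  mp <- correlation_to_mean_profile(a, b1)
  pw <- pairwise_gene_cn_correlation(a, b1)
  expect_equal(mp$r, unname(pw$r[, "T1"]))

  # all b samples identical -> same as pairwise against any one
  b3 <- b1[, c(1, 1, 1)]; colnames(b3) <- c("T1", "T2", "T3")
  mp3 <- correlation_to_mean_profile(a, b3)
  expect_equal(mp3$r, unname(pw$r[, "T1"]))
})

test_that("correlation structure is invariant under sample reordering", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cohort_config(seed = 31, n_tumors = 8,
                                       n_cell_lines = 4,
                                       background_mut_rate = 0,
                                       exclusive_pair = NULL), dir)
  model <- read_gene_model(sim$paths$gene_model)
  st <- read_seg(sim$paths$seg_tumors)
  sc <- read_seg(sim$paths$seg_cell_lines)
  gt <- project_segments_to_genes(st, model)
  gc <- project_segments_to_genes(sc, model)
  r1 <- pairwise_gene_cn_correlation(gc, gt)$r
  perm <- rev(colnames(gt))
  r2 <- pairwise_gene_cn_correlation(gc, gt[, perm])$r
  expect_equal(r2[, colnames(r1)], r1)
})

test_that("shared focal signal raises concordance; mean profile amplifies it", {
  # cohorts share planted focal events; remaining genes are pure noise
  dir <- withr::local_tempdir()
  cfg <- cohort_config(seed = 33, n_tumors = 12, n_cell_lines = 6,
                       focal_events = shared_focal_events(8, 1.0),
                       background_mut_rate = 0, exclusive_pair = NULL)
  sim <- simulate_cohort(cfg, dir)
  model <- read_gene_model(sim$paths$gene_model)
  gt <- project_segments_to_genes(read_seg(sim$paths$seg_tumors), model)
  gcl <- project_segments_to_genes(read_seg(sim$paths$seg_cell_lines),
                                   model)
  pw <- pairwise_gene_cn_correlation(gcl, gt)
  mp <- correlation_to_mean_profile(gcl, gt)
  # correlation to the tumor mean gives larger r than the mean pairwise r
  expect_gt(mean(mp$r), mean(pw$r))

  # restricting to planted focal-event genes raises mean r above all-genes
  peaks <- readLines(sim$paths$focal_peaks)
  pwf <- pairwise_gene_cn_correlation(gcl, gt, gene_subset = peaks)
  expect_gt(mean(pwf$r, na.rm = TRUE), mean(pw$r, na.rm = TRUE))
})

test_that("mean pairwise r grows with the planted shared-event fraction", {
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- vapply(qs, function(q) {
    dir <- withr::local_tempdir()
    cfg <- cohort_config(seed = 35, n_tumors = 10, n_cell_lines = 5,
                         focal_events = shared_focal_events(8, q),
                         background_mut_rate = 0, exclusive_pair = NULL)
    sim <- simulate_cohort(cfg, dir)
    model <- read_gene_model(sim$paths$gene_model)
    gt <- project_segments_to_genes(read_seg(sim$paths$seg_tumors), model)
    gcl <- project_segments_to_genes(read_seg(sim$paths$seg_cell_lines),
                                     model)
    mean(pairwise_gene_cn_correlation(gcl, gt)$r)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
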