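small_cfg <- function(seed, ...) {
  cohort_config(seed = seed, n_tumors = 6, n_cell_lines = 3, ...)
}

test_that("identical seeds give byte-identical cohorts; seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_cohort(small_cfg(101), d1)
  simulate_cohort(small_cfg(101), d2)
  simulate_cohort(small_cfg(102), d3)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_false(identical(readLines(file.path(d1, "tumors.maf")),
                         readLines(file.path(d3, "tumors.maf"))))
})

test_that("emitted files are parseable by the readers without warnings", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_cfg(103), dir)
  expect_no_warning({
    maf_t <- read_maf(sim$paths$maf_tumors)
    maf_c <- read_maf(sim$paths$maf_cell_lines)
    segs <- read_seg(sim$paths$seg_tumors)
    read_seg(sim$paths$seg_cell_lines)
    read_expression(sim$paths$expression_tumors)
    read_expression(sim$paths$expression_cell_lines)
    read_gene_model(sim$paths$gene_model)
    read_gene_set(sim$paths$stromal_set)
    read_gene_set(sim$paths$immune_set)
    for (p in sim$paths$coverage)
      read_coverage(p, if (grepl("wig$", p)) "wig" else "bed")
  })
  expect_gt(nrow(maf_t), 0)
  expect_gt(nrow(maf_c), 0)
  # MAF round-trips the generator's record-level truth: VAF/depth present
  expect_true(all(!is.na(maf_t$vaf)))
  expect_true(all(maf_t$depth >= 1))
})

test_that("uv_weight 1 emits only strand-normalizable dipyrimidine C>T", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_cfg(104, uv_weight = 1,
                                   exclusive_pair = NULL), dir)
  maf <- rbind(read_maf(sim$paths$maf_tumors),
               read_maf(sim$paths$maf_cell_lines))
  uv <- uv_signature(maf)
  expect_true(all(uv$frac_ct_dipyrimidine[uv$n_substitutions > 0] == 1))

  dir0 <- withr::local_tempdir()
  sim0 <- simulate_cohort(small_cfg(105, uv_weight = 0, cctt_rate = 0,
                                    exclusive_pair = NULL), dir0)
  maf0 <- rbind(read_maf(sim0$paths$maf_tumors),
                read_maf(sim0$paths$maf_cell_lines))
  uv0 <- uv_signature(maf0)
  expect_true(all(uv0$frac_ct_dipyrimidine == 0))
  expect_true(all(!uv0$is_uv))
})

test_that("a fully penetrant focal event shows up in projected CN", {
  dir <- withr::local_tempdir()
  ev <- focal_event("1", 2e5 + 1, 6e5, "amp",
                    c(tumor = 1, cell_line = 1), effect = 1)
  sim <- simulate_cohort(small_cfg(106, focal_events = list(ev),
                                   background_cn_sd = 0.05), dir)
  model <- read_gene_model(sim$paths$gene_model)
  segs <- read_seg(sim$paths$seg_tumors)
  m <- project_segments_to_genes(segs, model)
  inreg <- model$gene[model$chrom == "1" & model$start >= 2e5 &
                      model$end <= 6e5]
  expect_true(all(abs(m[inreg, ] - 1) < 0.25))
  outreg <- model$gene[model$chrom == "2"]
  expect_true(all(abs(m[outreg, ]) < 0.25))
})

test_that("truth report matches the emitted files", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(107, background_cn_sd = 0)     # noise-free CN
  sim <- simulate_cohort(cfg, dir)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 9L)
  expect_equal(sum(truth$group == "tumor"), 6L)
  # planted purity column reproduces the configured admixture levels
  expect_equal(truth$purity[truth$group == "tumor"],
               rep_len(cfg$purity_levels, 6))
  # planted FGA equals fga() on the emitted noise-free SEG
  segs <- rbind(read_seg(sim$paths$seg_tumors),
                read_seg(sim$paths$seg_cell_lines))
  f <- fga_all(segs, threshold = 0.2)
  expect_equal(f$fga[match(truth$sample_id, f$sample_id)],
               truth$fga_planted, tolerance = 1e-12)
  # breadth in truth equals breadth computed from the coverage files
  for (sid in truth$sample_id) {
    p <- sim$paths$coverage[[sid]]
    tr <- read_coverage(p, if (grepl("wig$", p)) "wig" else "bed")
    expect_equal(coverage_breadth(tr, 14),
                 truth$breadth_bp[truth$sample_id == sid])
  }
})

test_that("impossible exclusivity configurations are rejected", {
  expect_error(cohort_config(seed = 1,
                             exclusive_pair = list(gene_a = "G0001",
                                                   gene_b = "G0002",
                                                   coverage_prob = 0.8,
                                                   co_occurrence_prob = 0.3)),
               "impossible")
  expect_error(simulate_pair_statuses(10, 0.9, 0.5, 0.2, seed = 1),
               "impossible")
  expect_error(cohort_config(seed = 1, uv_weight = 1.5))
})

test_that("pair-status generator hits its expected margins", {
  sim <- simulate_pair_statuses(4000, coverage_prob = 0.743,
                                balance = 0.64,
                                co_occurrence_prob = 0.019, seed = 8)
  tab <- sim$table
  expect_equal(tab$n, 4000L)
  expect_equal(tab$gene1_only / 4000, 0.743 * 0.64, tolerance = 0.05)
  expect_equal(tab$both / 4000, 0.019, tolerance = 0.3)
})
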