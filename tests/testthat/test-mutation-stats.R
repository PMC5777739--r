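test_that("mutation matrix sets presence bits from non-synonymous records", {
  rec <- rbind(
    make_records(c("S1", "S1"), gene = "BRAF"),           # 2 hits, 1 bit
    make_records("S2", gene = "BRAF", synonymous = TRUE), # silent only
    make_records("S3", gene = "NRAS"))
  m <- build_mutation_matrix(rec)
  expect_true(m["BRAF", "S1"])
  expect_false(m["BRAF", "S2"])
  expect_true(m["NRAS", "S3"])
  expect_false(m["NRAS", "S1"])

  empty <- build_mutation_matrix(make_records(character(0))[0, ],
                                 genes = "BRAF", samples = c("S1", "S2"))
  expect_false(any(empty))

  expect_error(build_mutation_matrix(rec, samples = c("S1", "S1")),
               "duplicate")
})

test_that("differential test skips rare genes and detects no association", {
  # equal proportions 5/50 vs 41/410 -> p = 1
  expect_equal(fisher_exact_2x2(5, 45, 41, 369), 1)

  rec_a <- rbind(make_records(sprintf("A%d", 1:4), gene = "RARE"),
                 make_records(sprintf("A%d", 1:10), gene = "COMMON"))
  rec_b <- make_records(sprintf("B%d", 1:3), gene = "COMMON")
  a <- build_mutation_matrix(rec_a, genes = c("RARE", "COMMON"),
                             samples = sprintf("A%d", 1:20))
  b <- build_mutation_matrix(rec_b, genes = c("RARE", "COMMON"),
                             samples = sprintf("B%d", 1:20))
  res <- differential_mutation_test(a, b, min_mutated = 5)
  expect_false("RARE" %in% res$gene)   # only 4 mutated samples in total
  expect_true("COMMON" %in% res$gene)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * res$multiplier))

  expect_warning(differential_mutation_test(a, b, min_mutated = 0,
                                            multiplier = 1),
                 "smaller than the number of tests")
})

test_that("exclusivity mid-p handles degenerate margins and errors", {
  # empty gene-2 margin forces B = 0: p = 0 + 0.5 * 1
  expect_equal(exclusivity_midp(contingency22(10, 0, 5, 0)), 0.5)
  # co-occurring pairs score near 1
  expect_gt(exclusivity_midp(contingency22(40, 2, 2, 16)), 0.99)
  expect_error(contingency22(-1, 2, 3, 4), "non-negative")
  expect_error(contingency22(0, 0, 0, 0), "at least one")
})

test_that("pair testing enumerates all pairs and is label-symmetric", {
  set.seed(5)
  genes <- sprintf("G%d", 1:8)
  m <- matrix(runif(8 * 50) < 0.3, 8, 50,
              dimnames = list(genes, sprintf("S%02d", 1:50)))
  res <- test_exclusivity_pairs(m, genes)
  expect_equal(nrow(res), 28L)
  expect_equal(unique(res$multiplier), 28L)

  # swapping the two genes leaves the p-value unchanged
  r12 <- test_exclusivity_pairs(m, c("G1", "G2"))
  r21 <- test_exclusivity_pairs(m, c("G2", "G1"))
  expect_equal(r12$p_raw, r21$p_raw)

  expect_error(test_exclusivity_pairs(m, c("G1", "NOPE")), "NOPE")
})

test_that("planted exclusive pairs are detected on synthetic cohorts", {
  # margins ~200 and ~120 of n = 400, both = 8: strong exclusivity
  sim <- simulate_pair_statuses(400, coverage_prob = 0.76, balance = 0.63,
                                co_occurrence_prob = 0.02, seed = 99)
  p <- exclusivity_midp(sim$table)
  expect_lt(bonferroni_adjust(p, 28), 0.05)
})

test_that("coverage breadth and burden follow their formulas", {
  bed <- structure(list(sample_id = "S", mode = "intervals",
                        intervals = data.frame(chrom = "1",
                                               start = c(100, 300),
                                               end = c(200, 350))),
                   class = "coverage_track")
  expect_equal(coverage_breadth(bed), 150)

  empty <- structure(list(sample_id = "S", mode = "intervals",
                          intervals = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric())),
                     class = "coverage_track")
  expect_equal(coverage_breadth(empty), 0)

  rec30 <- make_records(rep("S", 30), pos = 1:30)
  b <- mutation_burden(rec30, 30e6)
  expect_equal(b$per_mb, 1)
  expect_equal(b$log2_per_mb, 0)
  b2 <- mutation_burden(rbind(rec30, make_records(rep("S", 30),
                                                  pos = 31:60)), 30e6)
  expect_equal(b2$log2_per_mb, 1)

  # synonymous records COUNT for burden
  syn <- make_records(rep("S", 10), pos = 1:10, synonymous = TRUE)
  expect_equal(mutation_burden(syn, 1e6)$n_mutations, 10L)

  # sub-threshold VAF records are excluded
  low <- make_records(rep("S", 10), pos = 1:10,
                      vaf = c(rep(0.09, 4), rep(0.5, 6)))
  expect_equal(mutation_burden(low, 1e6)$n_mutations, 6L)

  expect_error(mutation_burden(rec30, 0), "positive")
})

test_that("burden is invariant to proportional scaling of count and breadth", {
  rec <- make_records(rep("S", 12), pos = 1:12)
  b1 <- mutation_burden(rec, 2e6)
  b3 <- mutation_burden(rec[rep(1:12, 3), ], 6e6)
  expect_equal(b3$per_mb, b1$per_mb)
})

test_that("UV classification applies both branches of the rule", {
  # 7 of 10 substitutions are dipyrimidine C>T -> positive at >= 60%
  uvrec <- rbind(
    make_records(rep("S", 7), pos = seq(10, 130, by = 20),
                 ref = "C", alt = "T", flank5 = "T", flank3 = "A"),
    make_records(rep("S", 3), pos = seq(210, 250, by = 20),
                 ref = "T", alt = "G", flank5 = "A", flank3 = "A"))
  res <- uv_signature(uvrec)
  expect_equal(res$n_substitutions, 10L)
  expect_equal(res$frac_ct_dipyrimidine, 0.7)
  expect_true(res$is_uv)

  # CC>TT branch: 100 substitutions, 5 adjacent CC>TT pairs, few C>T
  cctt <- do.call(rbind, lapply(1:5, function(k)
    make_records(rep("S", 2), pos = c(1000 * k, 1000 * k + 1),
                 ref = "C", alt = "T",
                 flank5 = c("A", "C"), flank3 = c("C", "A"))))
  other <- make_records(rep("S", 90), pos = 5000 + seq(10, 900, by = 10),
                        ref = "T", alt = "A", flank5 = "G", flank3 = "G")
  res2 <- uv_signature(rbind(cctt, other))
  expect_equal(res2$n_substitutions, 100L)
  expect_equal(res2$frac_cc_tt, 0.05)
  expect_lt(res2$frac_ct_dipyrimidine, 0.6)
  expect_true(res2$is_uv)

  # no C>T at all -> negative
  ag <- make_records(rep("S", 20), pos = 1:20 * 7, ref = "A", alt = "G")
  res3 <- uv_signature(ag)
  expect_equal(res3$frac_ct_dipyrimidine, 0)
  expect_false(res3$is_uv)
})

test_that("UV classification strand-normalizes and tracks unknown context", {
  # G>A on the opposite strand with complemented flanks is C>T at a
  # dipyrimidine: 5' flank of the pyrimidine strand = complement of the
  # 3' flank here (G -> C)
  ga <- make_records(rep("S", 10), pos = 1:10 * 11, ref = "G", alt = "A",
                     flank5 = "T", flank3 = "G")
  res <- uv_signature(ga)
  expect_equal(res$frac_ct_dipyrimidine, 1)
  expect_true(res$is_uv)

  # undecidable context: C>T with non-pyrimidine 5' flank, unknown 3'
  unk <- rbind(
    make_records(rep("S", 4), pos = 1:4 * 13, ref = "C", alt = "T",
                 flank5 = "A", flank3 = NA_character_),
    make_records(rep("S", 6), pos = 5:10 * 13, ref = "C", alt = "T",
                 flank5 = "T", flank3 = "A"))
  res2 <- uv_signature(unk)
  expect_equal(res2$n_context_unknown, 4L)
  expect_equal(res2$n_substitutions, 6L)   # unknowns out of the denominator
  expect_equal(res2$frac_ct_dipyrimidine, 1)

  # indels never enter the substitution pool; zero substitutions -> not UV
  ind <- make_records(rep("S", 3), pos = 1:3 * 17, ref = "A", alt = "-",
                      class = "DEL")
  res3 <- uv_signature(ind)
  expect_equal(res3$n_substitutions, 0L)
  expect_false(res3$is_uv)
})
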