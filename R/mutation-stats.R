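# Mutation-level comparative statistics: presence matrices, differential
# mutation (Fisher), mutual-exclusivity pair testing, coverage-normalized
# burden, and UV-signature classification.

#' Build a binary gene x sample mutation-presence matrix
#'
#' A presence bit is set when the sample carries at least one qualifying
#' non-synonymous record for the gene. Records should already be filtered by
#' VAF/depth ([filter_mutations()]); synonymous records never set a bit even
#' if present in the input. Genes/samples supplied but absent from the
#' records get all-`FALSE` rows/columns.
#'
#' @param records a `maf_records` data frame.
#' @param genes gene universe (default: genes observed in `records`).
#' @param samples sample universe (default: samples observed). Duplicate ids
#'   are an error.
#' @return logical matrix, genes x samples.
#' @export
build_mutation_matrix <- function(records, genes = NULL, samples = NULL) {
  nonsyn <- records[!records$is_synonymous, , drop = FALSE]
  genes <- genes %||% sort(unique(nonsyn$gene))
  samples <- samples %||% sort(unique(records$sample_id))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in gene universe")
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  hit <- nonsyn$gene %in% genes & nonsyn$sample_id %in% samples
  if (any(hit))
    m[cbind(match(nonsyn$gene[hit], genes),
            match(nonsyn$sample_id[hit], samples))] <- TRUE
  m
}

#' Differentially mutated genes between two cohorts
#'
#' Per shared gene, a two-sided Fisher exact test ([fisher_exact_2x2()]) on
#' mutated/unmutated counts in the two cohorts. Genes with fewer than
#' `min_mutated` mutated samples in total (both cohorts combined) are
#' skipped. Bonferroni adjustment uses `multiplier` (default: size of the
#' shared gene universe, which can exceed the number of genes actually
#' tested).
#'
#' @param a,b logical mutation matrices ([build_mutation_matrix()]) sharing
#'   a gene universe (tests run on the intersection of their gene sets).
#' @param min_mutated minimum total mutated samples for a gene to be tested
#'   (default 5).
#' @param multiplier Bonferroni multiplier; default `NULL` uses the shared
#'   gene-universe size.
#' @return data frame: `gene`, `mutated_a`, `n_a`, `mutated_b`, `n_b`,
#'   `p_raw`, `p_adjusted`, `multiplier`, sorted by `p_raw`.
#' @export
differential_mutation_test <- function(a, b, min_mutated = 5L,
                                       multiplier = NULL) {
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) == 0L) stop("no shared genes between the two matrices")
  multiplier <- multiplier %||% length(genes)
  ma <- rowSums(a[genes, , drop = FALSE])
  mb <- rowSums(b[genes, , drop = FALSE])
  na <- ncol(a); nb <- ncol(b)
  test <- genes[(ma[genes] + mb[genes]) >= min_mutated]
  if (length(test) == 0L)
    return(data.frame(gene = character(), mutated_a = integer(),
                      n_a = integer(), mutated_b = integer(),
                      n_b = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), multiplier = numeric(),
                      stringsAsFactors = FALSE))
  p <- vapply(test, function(g)
    fisher_exact_2x2(ma[[g]], na - ma[[g]], mb[[g]], nb - mb[[g]]),
    numeric(1))
  out <- data.frame(gene = test,
                    mutated_a = as.integer(ma[test]), n_a = na,
                    mutated_b = as.integer(mb[test]), n_b = nb,
                    p_raw = unname(p),
                    p_adjusted = unname(bonferroni_adjust(p, multiplier)),
                    multiplier = multiplier,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact mutual-exclusivity tests for all pairs of a gene list
#'
#' Builds the 2x2 joint-status table for every unordered pair of `genes`
#' from the presence matrix and applies [exclusivity_midp()]. Bonferroni
#' multiplier is the number of pairs, `k*(k-1)/2`.
#'
#' @param m logical mutation matrix.
#' @param genes character vector (>= 2) of genes to pair; all must be rows
#'   of `m`.
#' @return data frame: `gene1`, `gene2`, `neither`, `gene2_only`,
#'   `gene1_only`, `both`, `p_raw`, `p_adjusted`, `multiplier`.
#' @export
test_exclusivity_pairs <- function(m, genes) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) absent from the mutation matrix: ",
         paste(missing, collapse = ", "))
  if (length(genes) < 2L) stop("need at least two genes")
  pairs <- utils::combn(genes, 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x1 <- m[g1, ]; x2 <- m[g2, ]
    tab <- contingency22(neither = sum(!x1 & !x2),
                         gene2_only = sum(!x1 & x2),
                         gene1_only = sum(x1 & !x2),
                         both = sum(x1 & x2))
    data.frame(gene1 = g1, gene2 = g2,
               neither = tab$neither, gene2_only = tab$gene2_only,
               gene1_only = tab$gene1_only, both = tab$both,
               p_raw = exclusivity_midp(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, n_pairs)
  out$multiplier <- n_pairs
  out
}

#' Breadth of sequencing coverage in base pairs
#'
#' Interval tracks (BED, already depth-thresholded by the producer):
#' `sum(end - start)` over the half-open intervals. Per-position tracks
#' (WIG): count of positions with depth at or above `min_depth`.
#'
#' @param track a `coverage_track` ([read_coverage()]).
#' @param min_depth depth threshold for per-position tracks (default 14).
#' @return breadth in base pairs (0 for an empty track).
#' @export
coverage_breadth <- function(track, min_depth = 14L) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$mode == "intervals") {
    sum(track$intervals$end - track$intervals$start)
  } else {
    sum(track$positions$depth >= min_depth)
  }
}

#' Coverage-normalized tumor mutational burden for one sample
#'
#' Counts qualifying records — synonymous variants *included*, unlike the
#' presence matrix — after VAF/depth filtering, and normalizes by coverage
#' breadth: `per_mb = n / (breadth_bp / 1e6)`; `log2_per_mb` is defined only
#' when at least one mutation qualifies.
#'
#' @param records `maf_records` for a single sample.
#' @param breadth_bp coverage breadth in base pairs (> 0).
#' @param min_vaf,min_depth record filters (defaults 0.1 and 14).
#' @return one-row data frame: `sample_id`, `n_mutations`, `breadth_bp`,
#'   `per_mb`, `log2_per_mb`.
#' @export
mutation_burden <- function(records, breadth_bp, min_vaf = 0.1,
                            min_depth = 14L) {
  if (!is.numeric(breadth_bp) || length(breadth_bp) != 1L || breadth_bp <= 0)
    stop("breadth_bp must be a single positive number")
  sid <- unique(records$sample_id)
  if (length(sid) > 1L)
    stop("mutation_burden() expects records of a single sample")
  if (length(sid) == 0L) sid <- NA_character_
  kept <- filter_mutations(records, min_vaf = min_vaf,
                           min_depth = min_depth,
                           include_synonymous = TRUE)
  n <- nrow(kept)
  per_mb <- n / (breadth_bp / 1e6)
  data.frame(sample_id = sid, n_mutations = n, breadth_bp = breadth_bp,
             per_mb = per_mb,
             log2_per_mb = if (n > 0) log2(per_mb) else NA_real_,
             stringsAsFactors = FALSE)
}

# Strand-normalize substitutions to the pyrimidine reference: a G>A call is
# the reverse-strand read of C>T, so ref/alt are complemented and the flanks
# complemented and swapped.
normalize_substitutions <- function(records) {
  snp <- records[records$variant_class == "SNP", , drop = FALSE]
  if (nrow(snp) == 0L) return(snp)
  purine <- snp$ref_allele %in% c("A", "G")
  f5 <- snp$flank5; f3 <- snp$flank3
  snp$flank5[purine] <- complement_base(f3[purine])
  snp$flank3[purine] <- complement_base(f5[purine])
  snp$ref_allele[purine] <- complement_base(snp$ref_allele[purine])
  snp$alt_allele[purine] <- complement_base(snp$alt_allele[purine])
  snp
}

#' UV mutational-signature classification per sample
#'
#' Substitutions (SNP records; indels excluded) are strand-normalized to the
#' pyrimidine reference. A sample is UV-positive when C>T transitions at
#' dipyrimidine sites (a C or T on either flank — configurable to require
#' the 5' flank) make up at least `ct_cutoff` of all substitutions, or
#' CC>TT events (two normalized C>T substitutions at adjacent positions in
#' the same sample, counted once per adjacent pair) make up at least
#' `cctt_cutoff`. C>T records whose dipyrimidine status cannot be decided
#' from the available flanks are excluded from both numerator and
#' denominator and tallied in `n_context_unknown`.
#'
#' @param records a `maf_records` data frame (any number of samples;
#'   filter for VAF/depth first if desired).
#' @param ct_cutoff dipyrimidine C>T fraction for positivity (default 0.60).
#' @param cctt_cutoff CC>TT fraction for positivity (default 0.05).
#' @param flank_rule `"either"` (default) or `"five_prime"`: which flank(s)
#'   may supply the pyrimidine context.
#' @return data frame, one row per sample: `sample_id`, `n_substitutions`,
#'   `frac_ct_dipyrimidine`, `frac_cc_tt`, `is_uv`, `n_context_unknown`.
#' @export
uv_signature <- function(records, ct_cutoff = 0.60, cctt_cutoff = 0.05,
                         flank_rule = c("either", "five_prime")) {
  flank_rule <- match.arg(flank_rule)
  samples <- sort(unique(records$sample_id))
  snp <- normalize_substitutions(records)
  rows <- lapply(samples, function(sid) {
    s <- snp[snp$sample_id == sid, , drop = FALSE]
    is_ct <- s$ref_allele == "C" & s$alt_allele == "T"
    if (flank_rule == "either") {
      dipyr <- (s$flank5 %in% c("C", "T")) | (s$flank3 %in% c("C", "T"))
      # undecidable: no flank says yes and at least one flank unknown
      unknown <- is_ct & !dipyr & (is.na(s$flank5) | is.na(s$flank3))
    } else {
      dipyr <- s$flank5 %in% c("C", "T")
      unknown <- is_ct & is.na(s$flank5)
    }
    usable <- !unknown
    n_sub <- sum(usable)
    n_ct_dipyr <- sum(usable & is_ct & dipyr)
    # CC>TT: adjacent normalized C>T pairs on the same chromosome
    ct <- s[is_ct & usable, , drop = FALSE]
    n_cctt <- 0L
    if (nrow(ct) > 1L) {
      ct <- ct[order(ct$chrom, ct$pos), , drop = FALSE]
      adj <- ct$chrom[-1L] == ct$chrom[-nrow(ct)] &
             diff(ct$pos) == 1
      n_cctt <- sum(adj)
    }
    frac_ct <- if (n_sub > 0) n_ct_dipyr / n_sub else 0
    frac_cctt <- if (n_sub > 0) n_cctt / n_sub else 0
    data.frame(sample_id = sid, n_substitutions = n_sub,
               frac_ct_dipyrimidine = frac_ct, frac_cc_tt = frac_cctt,
               is_uv = n_sub > 0 &&
                 (frac_ct >= ct_cutoff || frac_cctt >= cctt_cutoff),
               n_context_unknown = sum(unknown),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(sample_id = character(), n_substitutions = integer(),
               frac_ct_dipyrimidine = numeric(), frac_cc_tt = numeric(),
               is_uv = logical(), n_context_unknown = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
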