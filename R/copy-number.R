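# Copy-number statistics: fraction genome altered, segment-to-gene
# projection, and cell-line-vs-tumor Pearson concordance.

#' Fraction genome altered (FGA) of one segmented profile
#'
#' `FGA = sum(L_i * [|CN_i| > T]) / sum(L_i)` over the autosomal segments of
#' the profile, where `L_i` is segment length (1-based inclusive,
#' `end - start + 1`) and `CN_i` the segment's normalized log2 copy-number
#' ratio. The inequality at the threshold is strict; X/Y segments are
#' excluded from numerator and denominator. FGA is invariant under
#' subdividing a segment into pieces with the same mean.
#'
#' @param profile a `seg_profiles` data frame holding exactly one sample
#'   (or a subset of rows for one sample).
#' @param threshold positive copy-number threshold `T` on the |log2 ratio|
#'   scale (default 0.2).
#' @return one-row data frame: `sample_id`, `fga`, `threshold`,
#'   `total_length`.
#' @export
fga <- function(profile, threshold = 0.2) {
  stopifnot(threshold > 0)
  if (nrow(profile) == 0L) stop("empty segment profile")
  sid <- unique(profile$sample_id)
  if (length(sid) != 1L)
    stop("fga() expects one sample; got ", length(sid),
         " (use fga_all() for cohorts)")
  auto <- profile[!is_sex_chrom(profile$chrom), , drop = FALSE]
  if (nrow(auto) == 0L) stop("profile has no autosomal segments")
  len <- auto$end - auto$start + 1
  altered <- abs(auto$seg_mean) > threshold
  data.frame(sample_id = sid,
             fga = sum(len[altered]) / sum(len),
             threshold = threshold,
             total_length = sum(len),
             stringsAsFactors = FALSE)
}

#' FGA for every sample in a segment table
#'
#' @param segs a `seg_profiles` data frame (multiple samples).
#' @inheritParams fga
#' @return data frame with one row per sample (columns as in [fga()]).
#' @export
fga_all <- function(segs, threshold = 0.2) {
  if (nrow(segs) == 0L)
    return(data.frame(sample_id = character(), fga = numeric(),
                      threshold = numeric(), total_length = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split_profiles(segs), fga,
                               threshold = threshold))
  rownames(out) <- NULL
  out
}

#' Project segmented copy number onto genes
#'
#' Each gene's value per sample is the overlap-length-weighted mean of the
#' segment means of all segments intersecting the gene's span (a gene fully
#' contained in one segment carries exactly that segment's value). Genes
#' with no overlapping segment are `NA`. Genes on X and Y are removed when
#' `drop_xy` is `TRUE`, so male- and female-derived samples compare on the
#' same gene universe.
#'
#' @param segs a `seg_profiles` data frame.
#' @param model a `gene_model` data frame ([read_gene_model()]).
#' @param drop_xy drop X/Y genes? Default `TRUE`.
#' @return numeric matrix genes x samples (class kept plain), mean log2
#'   ratio per gene per sample, `NA` where no segment overlaps.
#' @export
project_segments_to_genes <- function(segs, model, drop_xy = TRUE) {
  stopifnot(nrow(model) > 0)
  if (drop_xy) model <- model[!is_sex_chrom(model$chrom), , drop = FALSE]
  if (nrow(model) == 0L) stop("gene model empty after X/Y removal")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = model$start, end = model$end))
  samples <- unique(segs$sample_id)
  out <- matrix(NA_real_, nrow = nrow(model), ncol = length(samples),
                dimnames = list(model$gene, samples))
  for (sid in samples) {
    p <- segs[segs$sample_id == sid, , drop = FALSE]
    seg_gr <- GenomicRanges::GRanges(
      seqnames = p$chrom,
      ranges = IRanges::IRanges(start = p$start, end = p$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(IRanges::ranges(gene_gr)[qh],
                              IRanges::ranges(seg_gr)[sh])
    w <- IRanges::width(ov)
    wm <- w * p$seg_mean[sh]
    num <- tapply(wm, qh, sum)
    den <- tapply(w, qh, sum)
    idx <- as.integer(names(num))
    out[idx, sid] <- as.numeric(num / den)
  }
  out
}

#' Pairwise Pearson correlation of gene-level copy number
#'
#' Correlates every sample (column) of `a` against every sample of `b` over
#' the genes present and non-missing in both, optionally restricted to a
#' gene subset (e.g. genes inside significant focal amplification/deletion
#' peaks). Cells with fewer than `min_genes` usable genes, or zero variance
#' in either vector, are reported `NA` with a reason.
#'
#' @param a,b gene x sample matrices from [project_segments_to_genes()].
#' @param gene_subset optional character vector restricting the gene
#'   universe.
#' @param min_genes minimum pairwise-complete genes per cell (default 3).
#' @return list of class `"cn_correlation"`: `r` (samples of `a` x samples
#'   of `b` Pearson matrix), `n_genes_used` (same shape), `reason`
#'   (character matrix, `NA` where `r` is defined).
#' @export
pairwise_gene_cn_correlation <- function(a, b, gene_subset = NULL,
                                         min_genes = 3L) {
  genes <- intersect(rownames(a), rownames(b))
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) < min_genes)
    stop("fewer than ", min_genes, " shared genes after subsetting")
  A <- a[genes, , drop = FALSE]
  B <- b[genes, , drop = FALSE]
  r <- matrix(NA_real_, ncol(A), ncol(B),
              dimnames = list(colnames(A), colnames(B)))
  n_used <- matrix(0L, ncol(A), ncol(B), dimnames = dimnames(r))
  reason <- matrix(NA_character_, ncol(A), ncol(B), dimnames = dimnames(r))
  for (i in seq_len(ncol(A))) {
    x <- A[, i]
    okx <- !is.na(x)
    for (j in seq_len(ncol(B))) {
      y <- B[, j]
      ok <- okx & !is.na(y)
      n <- sum(ok)
      n_used[i, j] <- n
      if (n < min_genes) { reason[i, j] <- "too_few_genes"; next }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        reason[i, j] <- "zero_variance"; next
      }
      r[i, j] <- stats::cor(x[ok], y[ok])
    }
  }
  structure(list(r = r, n_genes_used = n_used, reason = reason,
                 genes = genes),
            class = "cn_correlation")
}

#' Correlation of each sample against a cohort's mean profile
#'
#' Computes the gene-wise mean over the samples of `b` (missing entries
#' ignored), then the Pearson correlation of every sample of `a` against
#' that mean vector. With a single sample in `b` this reduces to the
#' pairwise correlation against that sample.
#'
#' @inheritParams pairwise_gene_cn_correlation
#' @return data frame: `sample_id`, `r`, `n_genes_used`, `reason`.
#' @export
correlation_to_mean_profile <- function(a, b, gene_subset = NULL,
                                        min_genes = 3L) {
  genes <- intersect(rownames(a), rownames(b))
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) < min_genes)
    stop("fewer than ", min_genes, " shared genes after subsetting")
  A <- a[genes, , drop = FALSE]
  m <- rowMeans(b[genes, , drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  out <- data.frame(sample_id = colnames(A), r = NA_real_,
                    n_genes_used = 0L, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(A))) {
    x <- A[, i]
    ok <- !is.na(x) & !is.na(m)
    out$n_genes_used[i] <- sum(ok)
    if (sum(ok) < min_genes) { out$reason[i] <- "too_few_genes"; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(m[ok]) == 0) {
      out$reason[i] <- "zero_variance"; next
    }
    out$r[i] <- stats::cor(x[ok], m[ok])
  }
  out
}
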