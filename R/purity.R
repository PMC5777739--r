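# Stromal/immune enrichment scoring and tumor-cell-fraction estimation.
# The enrichment statistic is the unnormalized single-sample (ssGSEA)
# running sum; the combined stromal+immune score maps to an estimated tumor
# cell fraction through a published cosine calibration.

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (average ranks on ties;
#' highest expression gets the highest rank). Walking the gene list from the
#' highest-ranked gene down, the score is the sum over all positions of the
#' difference between the weighted in-set cumulative distribution (weights
#' `rank^alpha`) and the unweighted out-of-set cumulative distribution —
#' the unnormalized single-sample enrichment statistic. Scores depend on the
#' expression values only through their ranks, so any strictly monotone
#' per-sample transformation leaves them unchanged.
#'
#' @param expr numeric matrix, genes x samples, rownames gene symbols.
#' @param set a [gene_set()].
#' @param alpha rank-weight exponent, > 0 (default 0.25).
#' @return named numeric vector of per-sample scores, with attribute
#'   `n_matched` giving the size of the set/matrix gene intersection.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), alpha > 0)
  inset <- rownames(expr) %in% set$symbols
  n_matched <- sum(inset)
  if (n_matched == 0L)
    stop("gene set '", set$name, "' has no genes in the expression matrix")
  if (all(inset))
    stop("gene set '", set$name, "' covers every gene; no out-of-set genes")
  n <- nrow(expr)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    in_ord <- inset[ord]
    w <- r[ord]^alpha * in_ord
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_ord) / (n - n_matched)
    sum(p_in - p_out)
  }, numeric(1))
  names(scores) <- colnames(expr)
  attr(scores, "n_matched") <- n_matched
  scores
}

#' Stromal, immune, and combined enrichment scores per sample
#'
#' Runs [ssgsea_score()] with `alpha = 0.25` for the stromal and immune
#' signatures and sums them into the combined score. The tumor-cell fraction
#' column is left `NA`; fill it with [estimate_purity()] or
#' [purity_from_score()].
#'
#' @param expr genes x samples expression matrix.
#' @param stromal,immune [gene_set()] objects.
#' @return data frame of class `"purity_results"`: `sample_id`,
#'   `stromal_score`, `immune_score`, `combined_score`, `purity` (`NA`),
#'   `clamped`, `n_stromal_matched`, `n_immune_matched`.
#' @export
estimate_scores <- function(expr, stromal, immune) {
  s <- ssgsea_score(expr, stromal, alpha = 0.25)
  i <- ssgsea_score(expr, immune, alpha = 0.25)
  out <- data.frame(sample_id = colnames(expr),
                    stromal_score = unname(s),
                    immune_score = unname(i),
                    combined_score = unname(s) + unname(i),
                    purity = NA_real_,
                    clamped = FALSE,
                    n_stromal_matched = attr(s, "n_matched"),
                    n_immune_matched = attr(i, "n_matched"),
                    stringsAsFactors = FALSE)
  class(out) <- c("purity_results", "data.frame")
  out
}

# Cosine calibration constants from the published combined-score -> tumor
# cell fraction formula (Yoshihara et al. calibration).
.purity_intercept <- 0.6049872018
.purity_slope <- 0.0001467884

#' Convert a combined enrichment score to an estimated tumor-cell fraction
#'
#' `purity = cos(0.6049872018 + 0.0001467884 * combined_score)`. Values
#' falling outside \[0, 1\] (cosine argument outside \[0, pi/2\]) are clamped
#' to the boundary and flagged. Purity is strictly decreasing in the score
#' while the cosine argument stays within \[0, pi\].
#'
#' @param combined_score numeric vector of combined (stromal + immune)
#'   scores.
#' @return numeric vector of purities in \[0, 1\], with attribute `clamped`
#'   (logical vector marking boundary-clamped entries).
#' @export
purity_from_score <- function(combined_score) {
  raw <- cos(.purity_intercept + .purity_slope * combined_score)
  clamped <- !is.na(raw) & (raw < 0 | raw > 1)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

#' Score a cohort and fill in estimated purity
#'
#' Convenience wrapper: [estimate_scores()] followed by
#' [purity_from_score()] on the combined score.
#'
#' @inheritParams estimate_scores
#' @return a `purity_results` data frame with `purity` and `clamped` filled.
#' @export
estimate_purity <- function(expr, stromal, immune) {
  res <- estimate_scores(expr, stromal, immune)
  p <- purity_from_score(res$combined_score)
  res$purity <- as.numeric(p)
  res$clamped <- attr(p, "clamped")
  res
}

#' Filter samples at a tumor-cell-fraction threshold
#'
#' @param results a `purity_results` data frame with defined purities.
#' @param threshold minimum tumor-cell fraction; boundary inclusive
#'   (default 0.60).
#' @return character vector of sample ids with `purity >= threshold`.
#' @export
filter_by_purity <- function(results, threshold = 0.60) {
  if (anyNA(results$purity))
    stop("purity undefined for ",  sum(is.na(results$purity)),
         " sample(s); run estimate_purity() first")
  keep <- results$sample_id[results$purity >= threshold]
  if (length(keep) == 0L)
    warning("no samples pass the purity threshold ", threshold)
  keep
}
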