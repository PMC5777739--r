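#' Build a 2x2 mutation contingency table for a gene pair
#'
#' Counts samples by joint mutation status of two genes: mutated in neither,
#' in gene 2 only, in gene 1 only, or in both. With margins fixed, the
#' both-mutated count follows a hypergeometric law, which is the basis of the
#' exact mutual-exclusivity test ([exclusivity_midp()]).
#'
#' @param neither,gene2_only,gene1_only,both non-negative integer counts.
#' @return An object of class `"contingency22"`: a list with the four counts,
#'   the total `n`, and the two margins `m1` (gene 1 mutated) and `m2`
#'   (gene 2 mutated).
#' @export
contingency22 <- function(neither, gene2_only, gene1_only, both) {
  counts <- c(neither = neither, gene2_only = gene2_only,
              gene1_only = gene1_only, both = both)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("contingency table must contain at least one sample")
  structure(list(neither = as.integer(neither),
                 gene2_only = as.integer(gene2_only),
                 gene1_only = as.integer(gene1_only),
                 both = as.integer(both),
                 n = as.integer(n),
                 m1 = as.integer(gene1_only + both),
                 m2 = as.integer(gene2_only + both)),
            class = "contingency22")
}

#' @export
print.contingency22 <- function(x, ...) {
  m <- matrix(c(x$neither, x$gene2_only, x$gene1_only, x$both), 2, 2,
              dimnames = list(c("gene1 wt", "gene1 mut"),
                              c("gene2 wt", "gene2 mut")))
  print(m)
  invisible(x)
}

#' Exact mid-p test for mutual exclusivity of a gene pair
#'
#' With both margins of the 2x2 table fixed, the number of samples mutated in
#' both genes, B, is hypergeometric: `B ~ Hyper(N = n, K = m1, draws = m2)`.
#' The test is one-sided toward exclusivity, with the mid-p convention (half
#' weight on the observed count):
#' `p = P(B < b_obs) + 0.5 * P(B = b_obs)`.
#' Pairs co-occurring more than expected give p near 1. Tail sums are
#' accumulated in log space so p-values down to ~1e-50 are representable.
#'
#' @param table a [contingency22()] object (or a list/vector with elements
#'   `neither`, `gene2_only`, `gene1_only`, `both`).
#' @return the raw one-sided mid-p value, in (0, 1].
#' @export
exclusivity_midp <- function(table) {
  tab <- as_contingency22(table)
  N <- tab$n; m1 <- tab$m1; m2 <- tab$m2; b <- tab$both
  lo <- max(0L, m2 - (N - m1))
  hi <- min(m1, m2)
  if (b < lo || b > hi)
    stop("inconsistent contingency table: 'both' outside its support")
  k <- lo:hi
  lp <- stats::dhyper(k, m1, N - m1, m2, log = TRUE)
  terms <- c(lp[k < b], lp[k == b] + log(0.5))
  p <- exp(logsumexp(terms))
  min(max(p, .Machine$double.xmin), 1)
}

as_contingency22 <- function(x) {
  if (inherits(x, "contingency22")) return(x)
  x <- as.list(x)
  need <- c("neither", "gene2_only", "gene1_only", "both")
  if (!all(need %in% names(x)))
    stop("table must provide counts: ", paste(need, collapse = ", "))
  contingency22(x$neither, x$gene2_only, x$gene1_only, x$both)
}

#' Two-sided Fisher exact test for a 2x2 table, in log space
#'
#' The two-sided p-value is the sum, over all tables with the observed
#' margins, of the probabilities of tables no more likely than the observed
#' one. Ties are included up to a relative error of 1e-7, the convention of
#' [stats::fisher.test()]. Probabilities are accumulated in log space so that
#' p-values far below double underflow of individual products remain exact to
#' double precision.
#'
#' @param a,b,c,d counts of the 2x2 table `[a, b; c, d]` (e.g. mutated /
#'   unmutated in cohort 1 on the first row, cohort 2 on the second).
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  N <- sum(counts)
  if (N < 1) stop("empty table")
  m1 <- a + b          # row 1 total
  m2 <- a + c          # column 1 total
  lo <- max(0L, m2 - (N - m1))
  hi <- min(m1, m2)
  k <- lo:hi
  lp <- stats::dhyper(k, m1, N - m1, m2, log = TRUE)
  lobs <- stats::dhyper(a, m1, N - m1, m2, log = TRUE)
  keep <- lp <= lobs + log1p(1e-7)
  p <- exp(logsumexp(lp[keep]))
  min(max(p, .Machine$double.xmin), 1)
}
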