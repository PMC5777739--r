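#' @keywords internal
"_PACKAGE"

# Chromosome label normalization shared by every reader: case-insensitive,
# "chr" prefix stripped, numeric sex-chromosome aliases mapped to X/Y.
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

is_sex_chrom <- function(x) normalize_chrom(x) %in% c("X", "Y")

# log(sum(exp(x))) without underflow; x may contain -Inf.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Bonferroni adjustment with an explicit multiplier
#'
#' Multiplies each raw p-value by `multiplier` and caps at 1. The multiplier
#' is explicit (rather than taken from the number of p-values) because the
#' test family can be larger than the set of tests actually run, e.g. a
#' shared gene universe of which only some genes pass a frequency filter.
#'
#' @param p numeric vector of raw p-values.
#' @param multiplier positive integer, the size of the test family.
#' @return numeric vector, `pmin(1, p * multiplier)`.
#' @export
bonferroni_adjust <- function(p, multiplier) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier < 1)
    stop("'multiplier' must be a single number >= 1")
  if (multiplier < length(p))
    warning("Bonferroni multiplier (", multiplier,
            ") is smaller than the number of tests (", length(p), ")")
  pmin(1, p * multiplier)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

complement_base <- function(b) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(map[toupper(b)])
  out[is.na(b)] <- NA_character_
  out
}
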