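# SEG (segmented copy number) reading/writing. Coordinates are 1-based
# inclusive as distributed by the source projects; segment length is
# end - start + 1.

#' Read a SEG file of segmented copy-number profiles
#'
#' Expects the 5-column SEG dialect (sample, chromosome, start, end, segment
#' mean as a ploidy-corrected log2 ratio), with an optional probe-count
#' column between `end` and the segment mean tolerated. Chromosome labels
#' are normalized ("chr" stripped, 23/24 mapped to X/Y).
#'
#' @param path path to a tab-separated SEG file with a header row.
#' @return A data frame of class `"seg_profiles"` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `seg_mean`, ordered by sample then position.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 5L) stop("SEG format error: expected at least 5 columns")
  # seg mean is the last column; probe-count column (if any) sits before it
  seg_mean <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  if (nrow(df) > 0 && anyNA(seg_mean))
    stop("SEG parse error at line ", which(is.na(seg_mean))[1L] + 1L,
         ": non-numeric segment mean")
  start <- suppressWarnings(as.numeric(df[[3L]]))
  end <- suppressWarnings(as.numeric(df[[4L]]))
  if (nrow(df) > 0 && (anyNA(start) || anyNA(end)))
    stop("SEG parse error at line ",
         which(is.na(start) | is.na(end))[1L] + 1L, ": non-numeric coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("SEG parse error at line ", bad[1L] + 1L,
         ": segment start must be < end")
  out <- data.frame(sample_id = as.character(df[[1L]]),
                    chrom = normalize_chrom(df[[2L]]),
                    start = start, end = end, seg_mean = seg_mean,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seg_profiles", "data.frame")
  out
}

#' Write segment profiles to a SEG file
#'
#' Inverse of [read_seg()]; re-reading the written file reproduces the input
#' structure exactly.
#'
#' @param segs a `seg_profiles` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  out <- data.frame(Sample = segs$sample_id, Chromosome = segs$chrom,
                    Start = format(segs$start, scientific = FALSE, trim = TRUE),
                    End = format(segs$end, scientific = FALSE, trim = TRUE),
                    Segment_Mean = segs$seg_mean)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split a seg_profiles table into a named list of per-sample profiles.
split_profiles <- function(segs) {
  split(segs, segs$sample_id)
}
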