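# Sequencing-coverage tracks. Two dialects: BED3 intervals (0-based,
# half-open; assumed already thresholded at the producer's read depth) and
# WIG per-position depth (fixedStep / variableStep).

#' Read a sequencing-coverage track
#'
#' BED input yields an interval-mode track: intervals are taken as already
#' depth-thresholded by the producer, so breadth is simply the summed
#' interval length. WIG input yields a per-position track (`fixedStep` and
#' `variableStep` declarations supported, with optional `span`), from which
#' breadth is the count of positions at or above a depth threshold.
#'
#' @param path path to a BED3 or WIG file.
#' @param dialect `"bed"` or `"wig"`.
#' @param sample_id sample label to attach; defaults to the file name.
#' @return A list of class `"coverage_track"` with elements `sample_id`,
#'   `mode` (`"intervals"` or `"per_position"`), and either `intervals`
#'   (data frame `chrom`, `start`, `end`; 0-based half-open) or `positions`
#'   (data frame `chrom`, `pos`, `depth`; 1-based).
#' @export
read_coverage <- function(path, dialect = c("bed", "wig"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sample_id <- sample_id %||% sub("\\.(bed|wig)$", "",
                                  basename(path), ignore.case = TRUE)
  if (dialect == "bed") read_coverage_bed(path, sample_id)
  else read_coverage_wig(path, sample_id)
}

read_coverage_bed <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    iv <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      stop("BED parse error at line ", which(lengths(parts) < 3L)[1L],
           ": fewer than 3 fields")
    chrom <- normalize_chrom(vapply(parts, `[[`, "", 1L))
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
    if (length(bad))
      stop("BED parse error at line ", bad[1L],
           ": need 0 <= start < end")
    iv <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, mode = "intervals", intervals = iv),
            class = "coverage_track")
}

read_coverage_wig <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  chrom_v <- character(0); pos_v <- numeric(0); depth_v <- numeric(0)
  mode <- NULL; chrom <- NULL; nextpos <- NA_real_; step <- 1; span <- 1
  parse_kv <- function(line) {
    kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1L]]
    vals <- sub("^[A-Za-z]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    vals
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "fixedStep") || startsWith(line, "variableStep")) {
      kv <- parse_kv(line)
      if (!"chrom" %in% names(kv))
        stop("WIG parse error at line ", i, ": step declaration lacks chrom")
      chrom <- normalize_chrom(kv[["chrom"]])
      span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
      if (is.na(span) || span < 1)
        stop("WIG parse error at line ", i, ": bad span")
      if (startsWith(line, "fixedStep")) {
        mode <- "fixed"
        if (!all(c("start", "step") %in% names(kv)))
          stop("WIG parse error at line ", i,
               ": fixedStep needs start and step")
        nextpos <- as.numeric(kv[["start"]])
        step <- as.numeric(kv[["step"]])
        if (is.na(nextpos) || is.na(step) || nextpos < 1 || step < 1)
          stop("WIG parse error at line ", i, ": bad start/step")
      } else {
        mode <- "variable"
      }
    } else {
      if (is.null(mode))
        stop("WIG parse error at line ", i, ": data before step declaration")
      fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
      if (mode == "fixed") {
        d <- suppressWarnings(as.numeric(fields[[1L]]))
        if (is.na(d)) stop("WIG parse error at line ", i, ": bad depth")
        p0 <- nextpos
        nextpos <- nextpos + step
      } else {
        if (length(fields) < 2L)
          stop("WIG parse error at line ", i,
               ": variableStep needs position and depth")
        p0 <- suppressWarnings(as.numeric(fields[[1L]]))
        d <- suppressWarnings(as.numeric(fields[[2L]]))
        if (is.na(p0) || is.na(d) || p0 < 1)
          stop("WIG parse error at line ", i, ": bad position/depth")
      }
      if (d < 0) stop("WIG parse error at line ", i, ": negative depth")
      pp <- p0 + seq_len(span) - 1
      chrom_v <- c(chrom_v, rep(chrom, span))
      pos_v <- c(pos_v, pp)
      depth_v <- c(depth_v, rep(d, span))
    }
  }
  structure(list(sample_id = sample_id, mode = "per_position",
                 positions = data.frame(chrom = chrom_v, pos = pos_v,
                                        depth = depth_v,
                                        stringsAsFactors = FALSE)),
            class = "coverage_track")
}

#' Write an interval-mode coverage track as BED3
#'
#' @param track an intervals-mode `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"), track$mode == "intervals")
  iv <- track$intervals
  writeLines(sprintf("%s\t%s\t%s", iv$chrom,
                     format(iv$start, scientific = FALSE, trim = TRUE),
                     format(iv$end, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}
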