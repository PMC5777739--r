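# MAF reading. Accepts both TCGA- and CCLE-style column spellings; all
# downstream mutation statistics consume the normalized record table this
# produces.

.maf_aliases <- list(
  sample_id     = c("Tumor_Sample_Barcode", "sample_id", "sample", "Sample"),
  gene          = c("Hugo_Symbol", "gene", "Gene"),
  chrom         = c("Chromosome", "chrom", "chr"),
  pos           = c("Start_position", "Start_Position", "pos", "position"),
  ref_allele    = c("Reference_Allele", "ref_allele", "ref"),
  alt_allele    = c("Tumor_Seq_Allele2", "Tumor_Seq_Allele1", "alt_allele", "alt"),
  variant_class = c("Variant_Classification", "variant_classification"),
  variant_type  = c("Variant_Type", "variant_type"),
  alt_count     = c("t_alt_count", "alt_count", "Tumor_Alt_Count", "i_t_alt_count"),
  ref_count     = c("t_ref_count", "ref_count", "Tumor_Ref_Count", "i_t_ref_count"),
  depth         = c("t_depth", "depth", "total_reads"),
  ref_context   = c("ref_context", "Ref_Context", "context"),
  flank5        = c("flank5", "Flank_5"),
  flank3        = c("flank3", "Flank_3")
)

.find_col <- function(header, key) {
  hit <- .maf_aliases[[key]][.maf_aliases[[key]] %in% header]
  if (length(hit)) hit[[1L]] else NA_character_
}

# Variant classifications counted as synonymous (no protein change).
.synonymous_classes <- c("silent", "synonymous", "synonymous_variant")

#' Read a MAF (Mutation Annotation Format) file
#'
#' Parses a tab-separated somatic variant table into one normalized record
#' per row. Column names follow TCGA conventions, with common CCLE spellings
#' accepted (see Details). VAF is derived as `alt / (alt + ref)` when allele
#' counts are present, or `alt / depth` when a total-depth column exists;
#' records without count columns carry `NA` VAF/depth. Flanking bases come
#' from `flank5`/`flank3` columns or from a `ref_context` string centered on
#' the variant position; absent context is recorded as unknown (`NA`).
#'
#' @details Mandatory columns (any accepted alias): sample, gene, chromosome,
#'   position, reference allele, alternate allele, variant classification.
#'   `Variant_Type` (SNP/INS/DEL) is used when present, otherwise inferred
#'   from the alleles. Chromosome labels are normalized ("chr" stripped,
#'   23/24 to X/Y).
#'
#' @param path path to a tab-separated MAF file with a header row.
#' @return A data frame of class `"maf_records"` with columns `sample_id`,
#'   `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `variant_class`
#'   (`"SNP"`, `"INS"`, `"DEL"`), `is_synonymous`, `vaf`, `depth`, `flank5`,
#'   `flank3`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  header <- names(df)
  mandatory <- c("sample_id", "gene", "chrom", "pos", "ref_allele",
                 "alt_allele", "variant_class")
  cols <- vapply(mandatory, .find_col, character(1), header = header)
  if (anyNA(cols)) {
    missing <- mandatory[is.na(cols)]
    stop("MAF format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_maf_records())

  pos <- suppressWarnings(as.integer(df[[cols["pos"]]]))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad))
    stop("MAF parse error at line ", bad[1L] + 1L,
         ": position must be a positive integer")

  ref <- toupper(as.character(df[[cols["ref_allele"]]]))
  alt <- toupper(as.character(df[[cols["alt_allele"]]]))
  vclass_raw <- as.character(df[[cols["variant_class"]]])
  is_syn <- tolower(vclass_raw) %in% .synonymous_classes

  vt_col <- .find_col(header, "variant_type")
  if (!is.na(vt_col)) {
    vtype <- toupper(as.character(df[[vt_col]]))
    vtype[!vtype %in% c("SNP", "INS", "DEL")] <- NA_character_
  } else {
    vtype <- rep(NA_character_, nrow(df))
  }
  infer <- is.na(vtype)
  vtype[infer & (ref == "-" | nchar(alt) > nchar(ref))] <- "INS"
  vtype[infer & is.na(vtype) & (alt == "-" | nchar(alt) < nchar(ref))] <- "DEL"
  vtype[is.na(vtype)] <- "SNP"

  bad_snp <- which(vtype == "SNP" &
                   (nchar(ref) != 1L | nchar(alt) != 1L | ref == alt))
  if (length(bad_snp))
    stop("MAF parse error at line ", bad_snp[1L] + 1L,
         ": SNP requires single, distinct ref/alt bases")

  # VAF / depth from whichever count columns exist
  ac_col <- .find_col(header, "alt_count")
  rc_col <- .find_col(header, "ref_count")
  dp_col <- .find_col(header, "depth")
  vaf <- rep(NA_real_, nrow(df))
  depth <- rep(NA_integer_, nrow(df))
  if (!is.na(ac_col)) {
    altc <- suppressWarnings(as.numeric(df[[ac_col]]))
    if (!is.na(dp_col)) {
      depth <- suppressWarnings(as.integer(df[[dp_col]]))
      vaf <- ifelse(depth > 0, altc / depth, NA_real_)
    } else if (!is.na(rc_col)) {
      refc <- suppressWarnings(as.numeric(df[[rc_col]]))
      depth <- as.integer(altc + refc)
      vaf <- ifelse(depth > 0, altc / depth, NA_real_)
    }
  }
  if (any(depth < 0, na.rm = TRUE))
    stop("MAF parse error: negative read depth at line ",
         which(depth < 0)[1L] + 1L)
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE))
    stop("MAF parse error: VAF outside [0,1] at line ",
         which(vaf < 0 | vaf > 1)[1L] + 1L)

  # Flanking context: explicit columns beat ref_context extraction
  f5_col <- .find_col(header, "flank5"); f3_col <- .find_col(header, "flank3")
  ctx_col <- .find_col(header, "ref_context")
  flank5 <- rep(NA_character_, nrow(df))
  flank3 <- rep(NA_character_, nrow(df))
  if (!is.na(f5_col) && !is.na(f3_col)) {
    flank5 <- toupper(as.character(df[[f5_col]]))
    flank3 <- toupper(as.character(df[[f3_col]]))
  } else if (!is.na(ctx_col)) {
    ctx <- toupper(as.character(df[[ctx_col]]))
    mid <- (nchar(ctx) + 1L) %/% 2L
    ok <- !is.na(ctx) & nchar(ctx) >= 3L & nchar(ctx) %% 2L == 1L
    flank5[ok] <- substr(ctx[ok], mid[ok] - 1L, mid[ok] - 1L)
    flank3[ok] <- substr(ctx[ok], mid[ok] + 1L, mid[ok] + 1L)
  }
  flank5[!flank5 %in% c("A", "C", "G", "T")] <- NA_character_
  flank3[!flank3 %in% c("A", "C", "G", "T")] <- NA_character_

  out <- data.frame(
    sample_id = as.character(df[[cols["sample_id"]]]),
    gene = as.character(df[[cols["gene"]]]),
    chrom = normalize_chrom(df[[cols["chrom"]]]),
    pos = pos,
    ref_allele = ref,
    alt_allele = alt,
    variant_class = vtype,
    is_synonymous = is_syn,
    vaf = vaf,
    depth = depth,
    flank5 = flank5,
    flank3 = flank3,
    stringsAsFactors = FALSE
  )
  class(out) <- c("maf_records", "data.frame")
  out
}

empty_maf_records <- function() {
  out <- data.frame(sample_id = character(), gene = character(),
                    chrom = character(), pos = integer(),
                    ref_allele = character(), alt_allele = character(),
                    variant_class = character(), is_synonymous = logical(),
                    vaf = numeric(), depth = integer(),
                    flank5 = character(), flank3 = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("maf_records", "data.frame")
  out
}

#' Filter mutation records by VAF, depth, and synonymy
#'
#' Keeps records with `vaf >= min_vaf` and `depth >= min_depth` (both
#' boundaries inclusive). Records with unknown VAF or depth are dropped
#' whenever the corresponding threshold is positive. Synonymous records are
#' dropped unless `include_synonymous` is `TRUE`. Row order is preserved;
#' the operation is idempotent.
#'
#' @param records a `maf_records` data frame from [read_maf()].
#' @param min_vaf minimum variant allele fraction (default 0.1).
#' @param min_depth minimum total read depth (default 8).
#' @param include_synonymous keep synonymous records? Default `FALSE`.
#' @return the filtered `maf_records` data frame.
#' @export
filter_mutations <- function(records, min_vaf = 0.1, min_depth = 8,
                             include_synonymous = FALSE) {
  stopifnot(min_vaf >= 0, min_depth >= 0)
  keep_vaf <- if (min_vaf > 0) !is.na(records$vaf) & records$vaf >= min_vaf
              else is.na(records$vaf) | records$vaf >= min_vaf
  keep_depth <- if (min_depth > 0) !is.na(records$depth) & records$depth >= min_depth
                else is.na(records$depth) | records$depth >= min_depth
  keep <- keep_vaf & keep_depth
  if (!include_synonymous) keep <- keep & !records$is_synonymous
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("maf_records", "data.frame")
  out
}
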