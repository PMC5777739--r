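# Expression matrices, gene models, and gene-set files. Gene symbols are
# HGNC-style strings; matching between matrices and sets is exact on the
# symbol.

#' Read a normalized gene x sample expression matrix
#'
#' Tab-separated, header row of sample ids, first column gene symbols; one
#' additional leading annotation column (e.g. a description field) is
#' tolerated and dropped. Duplicate gene symbols are collapsed to the row
#' with the highest mean expression (a deterministic rule, common for
#' probe-level inputs); a message reports how many rows were collapsed.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix, rownames gene symbols, colnames sample ids.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression format error: no sample columns")
  genes <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  # tolerate one leading non-numeric annotation column
  if (ncol(df) >= 1L) {
    first <- suppressWarnings(as.numeric(df[[1L]]))
    if (nrow(df) > 0 && all(is.na(first)) && !all(is.na(df[[1L]])))
      df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) == 0L) stop("expression format error: zero samples")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    mat2 <- suppressWarnings(apply(df, 2, as.numeric))
    if (anyNA(mat2) && !anyNA(df))
      stop("expression parse error: non-numeric values")
    mat <- matrix(mat2, nrow = nrow(df), dimnames = list(NULL, names(df)))
  }
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(mat, na.rm = TRUE)
    ord <- order(means, decreasing = TRUE)
    keep <- ord[!duplicated(genes[ord])]
    n_dropped <- nrow(mat) - length(keep)
    # restore original gene order among kept rows
    keep <- sort(keep)
    mat <- mat[keep, , drop = FALSE]
    message("read_expression: collapsed ", n_dropped,
            " duplicate gene symbol row(s) by maximum mean expression")
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for matrices without duplicate symbols.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-coordinate model
#'
#' Tab-separated table with columns gene, chromosome, start, end (1-based
#' inclusive, header required). One entry per gene symbol is enforced.
#'
#' @param path path to the TSV file.
#' @return data frame of class `"gene_model"` with columns `gene`, `chrom`,
#'   `start`, `end`.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4L) stop("gene model format error: expected 4 columns")
  out <- data.frame(gene = as.character(df[[1L]]),
                    chrom = normalize_chrom(df[[2L]]),
                    start = as.numeric(df[[3L]]),
                    end = as.numeric(df[[4L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("gene model error: start must be < end (line ",
         which(out$start >= out$end)[1L] + 1L, ")")
  if (anyDuplicated(out$gene))
    stop("gene model error: duplicate gene symbol '",
         out$gene[duplicated(out$gene)][1L], "'")
  class(out) <- c("gene_model", "data.frame")
  out
}

#' Read a gene-set file
#'
#' Plain-text format: first line is the set name, each following line one
#' gene symbol.
#'
#' @param path path to the gene-set file.
#' @return list of class `"gene_set"` with elements `name` and `symbols`
#'   (unique, in file order).
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("gene set file must have a name header and at least one symbol")
  gene_set(lines[[1L]], lines[-1L])
}

#' Construct a gene set
#'
#' @param name set name.
#' @param symbols character vector of gene symbols; duplicates are removed.
#' @return list of class `"gene_set"`.
#' @export
gene_set <- function(name, symbols) {
  symbols <- unique(as.character(symbols))
  if (length(symbols) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' Write a gene set in the name-header format read by [read_gene_set()]
#'
#' @param set a `gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(set, path) {
  writeLines(c(set$name, set$symbols), path)
  invisible(path)
}
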