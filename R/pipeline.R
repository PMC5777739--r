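# End-to-end orchestration: purity filter -> FGA -> copy-number
# concordance -> mutation statistics -> burden -> UV signature, with
# per-stage TSV outputs and a JSON summary of sample accounting. All
# stages are deterministic; reruns with the same config produce
# byte-identical outputs.

#' Build a pipeline run configuration
#'
#' Paths may be `NULL`; stages lacking their inputs are skipped with an
#' explicit entry in the run summary. Thresholds default to the standard
#' analysis cutoffs: purity 0.60, FGA threshold 0.2, VAF 0.1, presence
#' depth 8, burden depth 14, minimum 5 mutated samples for the
#' differential test, UV cutoffs 0.60 / 0.05.
#'
#' @param out_dir output directory for stage TSVs, `summary.json`, and
#'   `run.log`.
#' @param maf_tumors,maf_cell_lines MAF paths.
#' @param seg_tumors,seg_cell_lines SEG paths.
#' @param expression_tumors,expression_cell_lines expression TSV paths.
#' @param gene_model gene-coordinate TSV path.
#' @param stromal_set,immune_set gene-set file paths.
#' @param coverage named character vector of per-sample coverage paths
#'   (`.bed` or `.wig`; names are sample ids).
#' @param focal_peaks optional focal-peak gene-list path (one symbol per
#'   line).
#' @param exclusivity_genes optional character vector of genes to pair in
#'   the exclusivity test; default picks the most frequently mutated
#'   shared genes (up to 8).
#' @param purity_threshold,fga_threshold,min_vaf,depth_presence,depth_burden,min_mutated,uv_ct_cutoff,uv_cctt_cutoff
#'   analysis thresholds.
#' @param diff_multiplier Bonferroni multiplier for the differential test;
#'   `NULL` uses the shared-gene-universe size.
#' @param seed recorded in the log (the pipeline itself draws no random
#'   numbers).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       maf_tumors = NULL, maf_cell_lines = NULL,
                       seg_tumors = NULL, seg_cell_lines = NULL,
                       expression_tumors = NULL,
                       expression_cell_lines = NULL,
                       gene_model = NULL,
                       stromal_set = NULL, immune_set = NULL,
                       coverage = NULL, focal_peaks = NULL,
                       exclusivity_genes = NULL,
                       purity_threshold = 0.60, fga_threshold = 0.2,
                       min_vaf = 0.1, depth_presence = 8L,
                       depth_burden = 14L, min_mutated = 5L,
                       uv_ct_cutoff = 0.60, uv_cctt_cutoff = 0.05,
                       diff_multiplier = NULL, seed = NULL) {
  stopifnot(purity_threshold >= 0, fga_threshold > 0,
            min_vaf >= 0, min_vaf <= 1, depth_presence >= 0,
            depth_burden >= 0, min_mutated >= 0,
            uv_ct_cutoff >= 0, uv_ct_cutoff <= 1,
            uv_cctt_cutoff >= 0, uv_cctt_cutoff <= 1)
  cfg <- list(out_dir = out_dir, maf_tumors = maf_tumors,
              maf_cell_lines = maf_cell_lines, seg_tumors = seg_tumors,
              seg_cell_lines = seg_cell_lines,
              expression_tumors = expression_tumors,
              expression_cell_lines = expression_cell_lines,
              gene_model = gene_model, stromal_set = stromal_set,
              immune_set = immune_set, coverage = coverage,
              focal_peaks = focal_peaks,
              exclusivity_genes = exclusivity_genes,
              purity_threshold = purity_threshold,
              fga_threshold = fga_threshold, min_vaf = min_vaf,
              depth_presence = as.integer(depth_presence),
              depth_burden = as.integer(depth_burden),
              min_mutated = as.integer(min_mutated),
              uv_ct_cutoff = uv_ct_cutoff,
              uv_cctt_cutoff = uv_cctt_cutoff,
              diff_multiplier = diff_multiplier, seed = seed)
  for (p in c("maf_tumors", "maf_cell_lines", "seg_tumors",
              "seg_cell_lines", "expression_tumors",
              "expression_cell_lines", "gene_model", "stromal_set",
              "immune_set", "focal_peaks")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file for '", p, "' does not exist: ", cfg[[p]])
  }
  if (!is.null(coverage) && any(!file.exists(coverage)))
    stop("missing coverage file(s): ",
         paste(coverage[!file.exists(coverage)], collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run configuration for a simulated cohort directory
#'
#' Points a [run_config()] at the files [simulate_cohort()] writes.
#'
#' @param cohort_dir directory given to [simulate_cohort()].
#' @param out_dir pipeline output directory (default
#'   `file.path(cohort_dir, "results")`).
#' @param ... further arguments passed to [run_config()].
#' @return a `run_config`.
#' @export
cohort_run_config <- function(cohort_dir,
                              out_dir = file.path(cohort_dir, "results"),
                              ...) {
  cov_files <- list.files(file.path(cohort_dir, "coverage"),
                          full.names = TRUE)
  names(cov_files) <- sub("\\.(bed|wig)$", "", basename(cov_files))
  run_config(out_dir = out_dir,
             maf_tumors = file.path(cohort_dir, "tumors.maf"),
             maf_cell_lines = file.path(cohort_dir, "cell_lines.maf"),
             seg_tumors = file.path(cohort_dir, "tumors.seg"),
             seg_cell_lines = file.path(cohort_dir, "cell_lines.seg"),
             expression_tumors = file.path(cohort_dir,
                                           "expression_tumors.tsv"),
             expression_cell_lines = file.path(cohort_dir,
                                               "expression_cell_lines.tsv"),
             gene_model = file.path(cohort_dir, "gene_model.tsv"),
             stromal_set = file.path(cohort_dir, "geneset_stromal.txt"),
             immune_set = file.path(cohort_dir, "geneset_immune.txt"),
             coverage = cov_files,
             focal_peaks = file.path(cohort_dir, "focal_peak_genes.txt"),
             ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

group_comparison_tsv <- function(gc, value_name, path) {
  df <- gc$pairwise
  df$anova_p <- gc$anova_p
  df$value <- value_name
  write_tsv(df, path)
}

#' Run the full cell-line-vs-tumor comparison pipeline
#'
#' Stages, in order: (1) purity scoring and tumor filtering; (2) FGA per
#' sample with a cell-line/tumor group comparison; (3) gene-level
#' copy-number projection with pairwise and mean-profile correlations,
#' over all genes and over the focal-peak subset; (4) mutation presence
#' matrix on the shared gene universe, differential-mutation test, and
#' mutual-exclusivity pair tests in each cohort; (5) coverage-normalized
#' mutational burden with a group comparison; (6) UV-signature
#' classification. Each stage writes a TSV under `config$out_dir`;
#' `summary.json` records sample counts at every filter step, and
#' `run.log` records every threshold actually used. Stages without
#' eligible inputs are skipped with an explicit summary entry; downstream
#' stages still run where possible.
#'
#' @param config a [run_config()], or the path to a YAML file whose keys
#'   are `run_config()` arguments.
#' @return invisible list of class `"lineconcord_run"`: `summary` (the
#'   summary-JSON structure), `outputs` (named file paths), `results`
#'   (in-memory stage results).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    if (!is.null(args$coverage)) args$coverage <- unlist(args$coverage)
    config <- do.call(run_config, args)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, paste0(...))
  for (th in c("purity_threshold", "fga_threshold", "min_vaf",
               "depth_presence", "depth_burden", "min_mutated",
               "uv_ct_cutoff", "uv_cctt_cutoff"))
    logit("threshold ", th, " = ", config[[th]])
  if (!is.null(config$seed)) logit("seed = ", config$seed)

  summary <- list(thresholds = config[c("purity_threshold",
                                        "fga_threshold", "min_vaf",
                                        "depth_presence", "depth_burden",
                                        "min_mutated", "uv_ct_cutoff",
                                        "uv_cctt_cutoff")],
                  stages = list())
  outputs <- list(); results <- list()
  tumor_keep <- NULL   # NULL = no purity information, keep all

  ## stage 1: purity ------------------------------------------------------
  if (!is.null(config$expression_tumors) &&
      !is.null(config$expression_cell_lines) &&
      !is.null(config$stromal_set) && !is.null(config$immune_set)) {
    stromal <- read_gene_set(config$stromal_set)
    immune <- read_gene_set(config$immune_set)
    et <- read_expression(config$expression_tumors)
    ec <- read_expression(config$expression_cell_lines)
    pt <- estimate_purity(et, stromal, immune); pt$group <- "tumor"
    pc <- estimate_purity(ec, stromal, immune); pc$group <- "cell_line"
    purity <- rbind(pt, pc)
    outputs$purity <- write_tsv(purity,
                                file.path(config$out_dir, "purity.tsv"))
    tumor_keep <- suppressWarnings(
      filter_by_purity(pt, config$purity_threshold))
    results$purity <- purity
    summary$stages$purity <- list(
      status = if (length(tumor_keep)) "ok" else "no_tumors_pass",
      n_tumors_scored = nrow(pt), n_cell_lines_scored = nrow(pc),
      n_tumors_pass = length(tumor_keep))
    logit("purity: ", length(tumor_keep), "/", nrow(pt),
          " tumors at fraction >= ", config$purity_threshold)
  } else {
    summary$stages$purity <- list(status = "skipped_missing_input")
  }

  keep_tumors <- function(ids) {
    if (is.null(tumor_keep)) ids else intersect(ids, tumor_keep)
  }

  ## stage 2: FGA ---------------------------------------------------------
  segs_t <- if (!is.null(config$seg_tumors)) read_seg(config$seg_tumors)
  segs_c <- if (!is.null(config$seg_cell_lines))
    read_seg(config$seg_cell_lines)
  if (!is.null(segs_t) && !is.null(segs_c)) {
    t_ids <- keep_tumors(unique(segs_t$sample_id))
    ft <- fga_all(segs_t[segs_t$sample_id %in% t_ids, ],
                  config$fga_threshold)
    ft$group <- rep("tumor", nrow(ft))
    fc <- fga_all(segs_c, config$fga_threshold)
    fc$group <- rep("cell_line", nrow(fc))
    fga_tab <- rbind(fc, ft)
    outputs$fga <- write_tsv(fga_tab,
                             file.path(config$out_dir, "fga.tsv"))
    results$fga <- fga_tab
    st <- list(status = "ok", n_tumors = nrow(ft),
               n_cell_lines = nrow(fc))
    if (min(table(fga_tab$group)) >= 2 &&
        length(unique(fga_tab$group)) >= 2) {
      gc <- group_compare(fga_tab$fga, fga_tab$group)
      outputs$fga_groups <- group_comparison_tsv(
        gc, "fga", file.path(config$out_dir, "fga_group_comparison.tsv"))
      results$fga_groups <- gc
      st$anova_p <- gc$anova_p
    }
    summary$stages$fga <- st
    logit("fga: T = ", config$fga_threshold, ", ", nrow(fga_tab),
          " samples")
  } else {
    summary$stages$fga <- list(status = "skipped_missing_input")
  }

  ## stage 3: copy-number concordance --------------------------------------
  if (!is.null(segs_t) && !is.null(segs_c) &&
      !is.null(config$gene_model)) {
    model <- read_gene_model(config$gene_model)
    t_ids <- keep_tumors(unique(segs_t$sample_id))
    gm_t <- project_segments_to_genes(
      segs_t[segs_t$sample_id %in% t_ids, ], model)
    gm_c <- project_segments_to_genes(segs_c, model)
    pw <- pairwise_gene_cn_correlation(gm_c, gm_t)
    mp <- correlation_to_mean_profile(gm_c, gm_t)
    outputs$cn_pairwise <- write_matrix_tsv(
      pw$r, file.path(config$out_dir, "cn_correlation_pairwise.tsv"))
    outputs$cn_mean <- write_tsv(
      mp, file.path(config$out_dir, "cn_correlation_mean.tsv"))
    results$cn_pairwise <- pw; results$cn_mean <- mp
    st <- list(status = "ok", n_genes = length(pw$genes),
               n_cell_lines = nrow(pw$r), n_tumors = ncol(pw$r))
    if (!is.null(config$focal_peaks)) {
      peaks <- trimws(readLines(config$focal_peaks))
      peaks <- peaks[nzchar(peaks)]
      pwf <- pairwise_gene_cn_correlation(gm_c, gm_t, gene_subset = peaks)
      mpf <- correlation_to_mean_profile(gm_c, gm_t, gene_subset = peaks)
      outputs$cn_pairwise_focal <- write_matrix_tsv(
        pwf$r,
        file.path(config$out_dir, "cn_correlation_pairwise_focal.tsv"))
      outputs$cn_mean_focal <- write_tsv(
        mpf, file.path(config$out_dir, "cn_correlation_mean_focal.tsv"))
      results$cn_pairwise_focal <- pwf; results$cn_mean_focal <- mpf
      st$n_focal_genes <- length(pwf$genes)
    }
    summary$stages$cn_correlation <- st
    logit("cn correlation: ", length(pw$genes), " genes")
  } else {
    summary$stages$cn_correlation <- list(status = "skipped_missing_input")
  }

  ## stage 4: mutation comparison -----------------------------------------
  maf_t <- if (!is.null(config$maf_tumors)) read_maf(config$maf_tumors)
  maf_c <- if (!is.null(config$maf_cell_lines))
    read_maf(config$maf_cell_lines)
  if (!is.null(maf_t) && !is.null(maf_c)) {
    ft <- filter_mutations(maf_t, config$min_vaf, config$depth_presence,
                           include_synonymous = FALSE)
    fc <- filter_mutations(maf_c, config$min_vaf, config$depth_presence,
                           include_synonymous = FALSE)
    t_ids <- keep_tumors(unique(maf_t$sample_id))
    ft <- ft[ft$sample_id %in% t_ids, , drop = FALSE]
    universe <- intersect(unique(ft$gene), unique(fc$gene))
    st <- list(status = "ok", n_tumors = length(t_ids),
               n_cell_lines = length(unique(maf_c$sample_id)),
               n_shared_genes = length(universe))
    if (length(universe) >= 1) {
      mt <- build_mutation_matrix(ft, genes = universe, samples = t_ids)
      mc <- build_mutation_matrix(fc, genes = universe,
                                  samples = sort(unique(maf_c$sample_id)))
      diff <- differential_mutation_test(
        mc, mt, min_mutated = config$min_mutated,
        multiplier = config$diff_multiplier %||% length(universe))
      outputs$mut_differential <- write_tsv(
        diff, file.path(config$out_dir, "mut_differential.tsv"))
      results$mut_differential <- diff
      st$n_genes_tested <- nrow(diff)
      st$n_significant <- sum(diff$p_adjusted <= 0.05)
      excl_genes <- config$exclusivity_genes %||% {
        freq <- rowSums(mt) + rowSums(mc)
        names(sort(freq, decreasing = TRUE))[
          seq_len(min(8L, length(freq)))]
      }
      excl_genes <- intersect(excl_genes, universe)
      if (length(excl_genes) >= 2) {
        ex_t <- test_exclusivity_pairs(mt, excl_genes)
        ex_c <- test_exclusivity_pairs(mc, excl_genes)
        outputs$exclusivity_tumors <- write_tsv(
          ex_t, file.path(config$out_dir, "exclusivity_tumors.tsv"))
        outputs$exclusivity_cell_lines <- write_tsv(
          ex_c, file.path(config$out_dir, "exclusivity_cell_lines.tsv"))
        results$exclusivity_tumors <- ex_t
        results$exclusivity_cell_lines <- ex_c
        st$n_pairs <- nrow(ex_t)
      }
    } else st$status <- "no_shared_genes"
    summary$stages$mutations <- st
    logit("mutations: ", length(universe), " shared genes")
  } else {
    summary$stages$mutations <- list(status = "skipped_missing_input")
  }

  ## stage 5: burden --------------------------------------------------------
  if (!is.null(maf_t) && !is.null(maf_c) && !is.null(config$coverage)) {
    all_maf <- rbind(maf_t, maf_c)
    groups <- c(stats::setNames(rep("tumor",
                                    length(unique(maf_t$sample_id))),
                                unique(maf_t$sample_id)),
                stats::setNames(rep("cell_line",
                                    length(unique(maf_c$sample_id))),
                                unique(maf_c$sample_id)))
    ids <- intersect(names(config$coverage), names(groups))
    ids <- c(keep_tumors(ids[groups[ids] == "tumor"]),
             ids[groups[ids] == "cell_line"])
    rows <- list()
    for (sid in ids) {
      path <- config$coverage[[sid]]
      dialect <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
                 else "bed"
      track <- read_coverage(path, dialect, sample_id = sid)
      breadth <- coverage_breadth(track, min_depth = config$depth_burden)
      if (breadth == 0) {
        warning("sample ", sid, ": empty coverage track, burden undefined")
        next
      }
      rec <- all_maf[all_maf$sample_id == sid, , drop = FALSE]
      b <- mutation_burden(rec, breadth, min_vaf = config$min_vaf,
                           min_depth = config$depth_burden)
      b$sample_id <- sid
      b$group <- groups[[sid]]
      rows[[sid]] <- b
    }
    if (length(rows)) {
      burden <- do.call(rbind, rows); rownames(burden) <- NULL
      outputs$burden <- write_tsv(
        burden, file.path(config$out_dir, "burden.tsv"))
      results$burden <- burden
      st <- list(status = "ok", n_samples = nrow(burden))
      ok <- !is.na(burden$log2_per_mb)
      if (length(unique(burden$group[ok])) >= 2 &&
          min(table(burden$group[ok])) >= 2) {
        gc <- group_compare(burden$log2_per_mb[ok], burden$group[ok])
        outputs$burden_groups <- group_comparison_tsv(
          gc, "log2_per_mb",
          file.path(config$out_dir, "burden_group_comparison.tsv"))
        results$burden_groups <- gc
        st$anova_p <- gc$anova_p
      }
      summary$stages$burden <- st
      logit("burden: ", nrow(burden), " samples at depth >= ",
            config$depth_burden)
    } else {
      summary$stages$burden <- list(status = "no_eligible_samples")
    }
  } else {
    summary$stages$burden <- list(status = "skipped_missing_input")
  }

  ## stage 6: UV signature --------------------------------------------------
  if (!is.null(maf_t) && !is.null(maf_c)) {
    uv_rows <- list()
    for (grp in c("tumor", "cell_line")) {
      maf <- if (grp == "tumor") maf_t else maf_c
      recs <- filter_mutations(maf, config$min_vaf,
                               config$depth_presence,
                               include_synonymous = TRUE)
      if (grp == "tumor")
        recs <- recs[recs$sample_id %in%
                       keep_tumors(unique(maf$sample_id)), , drop = FALSE]
      uv <- uv_signature(recs, ct_cutoff = config$uv_ct_cutoff,
                         cctt_cutoff = config$uv_cctt_cutoff)
      if (nrow(uv)) uv$group <- grp
      uv_rows[[grp]] <- uv
    }
    uv <- do.call(rbind, uv_rows[vapply(uv_rows, nrow, 1L) > 0])
    if (!is.null(uv) && nrow(uv)) {
      rownames(uv) <- NULL
      outputs$uv <- write_tsv(uv, file.path(config$out_dir, "uv.tsv"))
      results$uv <- uv
      rate <- function(g) if (any(uv$group == g))
        mean(uv$is_uv[uv$group == g]) else NA_real_
      summary$stages$uv <- list(status = "ok", n_samples = nrow(uv),
                                uv_rate_tumor = rate("tumor"),
                                uv_rate_cell_line = rate("cell_line"))
      logit("uv: cutoffs ", config$uv_ct_cutoff, " / ",
            config$uv_cctt_cutoff)
    } else {
      summary$stages$uv <- list(status = "no_eligible_samples")
    }
  } else {
    summary$stages$uv <- list(status = "skipped_missing_input")
  }

  outputs$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, outputs$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs$log <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, outputs$log)

  res <- structure(list(summary = summary, outputs = outputs,
                        results = results, config = config),
                   class = "lineconcord_run")
  invisible(res)
}

#' @export
print.lineconcord_run <- function(x, ...) {
  cat("lineconcord pipeline run\n")
  cat("  output dir:", x$config$out_dir, "\n")
  for (nm in names(x$summary$stages)) {
    st <- x$summary$stages[[nm]]
    cat(sprintf("  %-16s %s\n", nm, st$status))
  }
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classic (equal-variance) one-way ANOVA across groups, followed by
#' all-pairs comparison with Tukey's honestly-significant-difference
#' procedure (studentized-range adjustment; unbalanced groups allowed).
#'
#' @param values numeric vector.
#' @param labels group label per value (>= 2 groups, >= 2 values each).
#' @return list of class `"group_comparison"`: `anova_p`, `pairwise` (data
#'   frame `group_i`, `group_j`, `mean_difference`, `adjusted_p`),
#'   `n_per_group`.
#' @export
group_compare <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  g <- factor(labels)
  counts <- table(g)
  if (length(counts) < 2L) stop("need at least 2 groups")
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("group(s) with fewer than 2 values: ",
         paste(small, collapse = ", "))
  fit <- stats::aov(values ~ g)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$g
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- data.frame(
    group_i = vapply(pair_names, `[[`, "", 1L),
    group_j = vapply(pair_names, `[[`, "", 2L),
    mean_difference = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE)
  structure(list(anova_p = anova_p, pairwise = pairwise,
                 n_per_group = as.list(counts)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("one-way ANOVA p =", format(x$anova_p, digits = 4), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Row and column orderings by Ward hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances with Ward linkage
#' (`ward.D2`); missing values are imputed to the column mean (with a
#' note). A degenerate all-equal matrix returns the input order with a
#' warning. The ordering is deterministic for a given input.
#'
#' @param m numeric matrix, at least 2x2.
#' @return list with `rows` and `cols`, integer orderings.
#' @export
cluster_heatmap_order <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  if (anyNA(m)) {
    message("cluster_heatmap_order: imputing missing values to column means")
    for (j in seq_len(ncol(m))) {
      mu <- mean(m[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      m[is.na(m[, j]), j] <- mu
    }
  }
  if (max(m) == min(m)) {
    warning("degenerate matrix (all values equal); returning input order")
    return(list(rows = seq_len(nrow(m)), cols = seq_len(ncol(m))))
  }
  list(rows = stats::hclust(stats::dist(m), method = "ward.D2")$order,
       cols = stats::hclust(stats::dist(t(m)), method = "ward.D2")$order)
}
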