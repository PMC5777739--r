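# Seeded generator of paired tumor / cell-line cohorts with known ground
# truth for every statistic the pipeline computes: segmented copy number
# with planted focal events, mutation cohorts with a planted mutually
# exclusive driver pair and a controlled UV-context fraction, coverage
# tracks of configurable breadth, and expression matrices that are convex
# mixtures of tumor/stromal/immune archetypes at known purity.

#' Build a focal copy-number event description
#'
#' @param chrom chromosome label.
#' @param start,end event span, 1-based inclusive.
#' @param direction `"amp"` or `"del"`.
#' @param carrier_prob named vector `c(tumor=, cell_line=)` of carrier
#'   probabilities per group.
#' @param effect absolute mean log2 effect in carriers (default 1.0).
#' @return list describing the event.
#' @export
focal_event <- function(chrom, start, end, direction = c("amp", "del"),
                        carrier_prob = c(tumor = 0.7, cell_line = 0.7),
                        effect = 1.0) {
  direction <- match.arg(direction)
  stopifnot(start >= 1, start < end, effect > 0,
            all(carrier_prob >= 0 & carrier_prob <= 1))
  list(chrom = as.character(chrom), start = start, end = end,
       direction = direction,
       carrier_prob = carrier_prob, effect = effect)
}

#' Focal-event sets with a controlled shared fraction
#'
#' Tiles the genome with `n_events` equally sized focal events of which a
#' fraction `shared_fraction` is carried by both tumors and cell lines; the
#' remainder alternate between tumor-only and cell-line-only. Used to study
#' how copy-number concordance grows with the fraction of shared events.
#'
#' @param n_events number of events.
#' @param shared_fraction fraction of events carried by both groups.
#' @param n_chromosomes,chrom_length genome geometry (match the cohort
#'   config).
#' @param carrier_prob carrier probability for the carrying group(s).
#' @param effect absolute mean log2 effect.
#' @return list of [focal_event()] descriptions.
#' @export
shared_focal_events <- function(n_events, shared_fraction,
                                n_chromosomes = 2L, chrom_length = 1e6,
                                carrier_prob = 0.9, effect = 1.0) {
  stopifnot(n_events >= 1, shared_fraction >= 0, shared_fraction <= 1)
  n_shared <- round(shared_fraction * n_events)
  total <- n_chromosomes * chrom_length
  slot <- floor(total / n_events)
  lapply(seq_len(n_events), function(k) {
    g0 <- (k - 1) * slot          # global 0-based slot start
    start <- g0 + floor(slot / 4) + 1
    end <- g0 + floor(3 * slot / 4)
    chrom <- as.character((start - 1) %/% chrom_length + 1)
    start_c <- ((start - 1) %% chrom_length) + 1
    end_c <- ((end - 1) %% chrom_length) + 1
    if (end_c < start_c) end_c <- chrom_length  # clip slot at chromosome end
    cp <- if (k <= n_shared) c(tumor = carrier_prob, cell_line = carrier_prob)
          else if ((k - n_shared) %% 2L == 1L) c(tumor = carrier_prob, cell_line = 0)
          else c(tumor = 0, cell_line = carrier_prob)
    focal_event(chrom, start_c, end_c,
                direction = if (k %% 2L) "amp" else "del",
                carrier_prob = cp, effect = effect)
  })
}

#' Configuration of a synthetic paired cohort
#'
#' Defaults describe a desk-scale genome (2 chromosomes of 1 Mb, 200 genes
#' of 400 bp) so the full pipeline runs in seconds; every rate and
#' distribution is a knob. The background mutation rate is per megabase of
#' *covered gene space*, and its default is chosen so a desk-scale sample
#' carries a few dozen variants — the same order of variants per sample a
#' whole-exome cohort shows at typical melanoma rates.
#'
#' @param seed integer seed (mandatory); all emitted files are byte-stable
#'   given the seed.
#' @param n_tumors,n_cell_lines cohort sizes.
#' @param n_chromosomes,chrom_length,n_genes,gene_length genome geometry.
#' @param focal_events list of [focal_event()]s (default: one shared
#'   amplification and one shared deletion).
#' @param background_cn_sd Gaussian noise SD on segment means (log2 units).
#' @param exclusive_pair list: `gene_a`, `gene_b`, `coverage_prob`
#'   (probability a sample carries exactly one of the two), `balance`
#'   (probability the carried one is `gene_a`), `co_occurrence_prob`
#'   (probability of carrying both). `NULL` plants no pair.
#' @param background_mut_rate mutations per covered megabase.
#' @param uv_weight fraction of background substitutions drawn as C>T at a
#'   dipyrimidine site.
#' @param cctt_rate fraction of UV events emitted as adjacent CC>TT pairs.
#' @param indel_fraction,synonymous_fraction composition of background
#'   mutations.
#' @param vaf_shape Beta(a, b) parameters of the VAF law.
#' @param depth_mu,depth_size negative-binomial read-depth parameters.
#' @param coverage_breadth_fraction probability a gene is covered in a
#'   sample's track.
#' @param purity_levels planted tumor-cell fractions, recycled across
#'   tumors; cell lines are pure.
#' @param expression_noise_sd Gaussian noise SD on expression values.
#' @param stromal_set_size,immune_set_size sizes of the emitted signature
#'   gene sets.
#' @return validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed,
                          n_tumors = 40L, n_cell_lines = 12L,
                          n_chromosomes = 2L, chrom_length = 1e6,
                          n_genes = 200L, gene_length = 400L,
                          focal_events = NULL,
                          background_cn_sd = 0.1,
                          exclusive_pair = list(gene_a = "G0010",
                                                gene_b = "G0020",
                                                coverage_prob = 0.6,
                                                balance = 0.5,
                                                co_occurrence_prob = 0.02),
                          background_mut_rate = 500,
                          uv_weight = 0.75, cctt_rate = 0.05,
                          indel_fraction = 0.05,
                          synonymous_fraction = 0.25,
                          vaf_shape = c(2, 4),
                          depth_mu = 60, depth_size = 2,
                          coverage_breadth_fraction = 0.8,
                          purity_levels = c(1, 0.9, 0.75, 0.6, 0.4),
                          expression_noise_sd = 0.25,
                          stromal_set_size = 30L, immune_set_size = 30L) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory and must be a single integer")
  stopifnot(n_tumors >= 1, n_cell_lines >= 1, n_chromosomes >= 1,
            n_genes >= 2, gene_length >= 10,
            n_genes * gene_length <= n_chromosomes * chrom_length,
            background_cn_sd >= 0, background_mut_rate >= 0,
            uv_weight >= 0, uv_weight <= 1, cctt_rate >= 0, cctt_rate <= 1,
            indel_fraction >= 0, indel_fraction < 1,
            synonymous_fraction >= 0, synonymous_fraction < 1,
            length(vaf_shape) == 2L, all(vaf_shape > 0),
            depth_mu > 0, depth_size > 0,
            coverage_breadth_fraction > 0, coverage_breadth_fraction <= 1,
            all(purity_levels >= 0 & purity_levels <= 1),
            expression_noise_sd >= 0,
            stromal_set_size >= 1, immune_set_size >= 1,
            stromal_set_size + immune_set_size <= n_genes)
  if (is.null(focal_events)) {
    focal_events <- list(
      focal_event("1", chrom_length * 0.5 + 1, chrom_length * 0.8, "amp",
                  c(tumor = 0.7, cell_line = 0.7)),
      focal_event(as.character(min(2L, n_chromosomes)),
                  chrom_length * 0.2 + 1, chrom_length * 0.5, "del",
                  c(tumor = 0.5, cell_line = 0.5)))
  }
  for (ev in focal_events) {
    if (!ev$chrom %in% as.character(seq_len(n_chromosomes)))
      stop("focal event on unknown chromosome ", ev$chrom)
    if (ev$end > chrom_length) stop("focal event beyond chromosome end")
  }
  if (!is.null(exclusive_pair)) {
    ep <- exclusive_pair
    stopifnot(!is.null(ep$gene_a), !is.null(ep$gene_b),
              ep$coverage_prob >= 0, ep$coverage_prob <= 1,
              ep$co_occurrence_prob >= 0, ep$co_occurrence_prob <= 1)
    ep$balance <- ep$balance %||% 0.5
    stopifnot(ep$balance >= 0, ep$balance <= 1)
    if (ep$coverage_prob + ep$co_occurrence_prob > 1)
      stop("impossible config: coverage_prob + co_occurrence_prob > 1")
    exclusive_pair <- ep
  }
  structure(list(seed = as.integer(seed), n_tumors = as.integer(n_tumors),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length, n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 focal_events = focal_events,
                 background_cn_sd = background_cn_sd,
                 exclusive_pair = exclusive_pair,
                 background_mut_rate = background_mut_rate,
                 uv_weight = uv_weight, cctt_rate = cctt_rate,
                 indel_fraction = indel_fraction,
                 synonymous_fraction = synonymous_fraction,
                 vaf_shape = vaf_shape, depth_mu = depth_mu,
                 depth_size = depth_size,
                 coverage_breadth_fraction = coverage_breadth_fraction,
                 purity_levels = purity_levels,
                 expression_noise_sd = expression_noise_sd,
                 stromal_set_size = as.integer(stromal_set_size),
                 immune_set_size = as.integer(immune_set_size)),
            class = "cohort_config")
}

# Deterministic gene model implied by the config (no RNG involved).
synthetic_gene_model <- function(config) {
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  spacing <- floor(config$chrom_length / per_chrom)
  stopifnot(spacing >= config$gene_length)
  idx <- seq_len(config$n_genes)
  chrom_i <- (idx - 1L) %/% per_chrom + 1L
  within <- (idx - 1L) %% per_chrom
  start <- within * spacing + 1
  out <- data.frame(gene = sprintf("G%04d", idx),
                    chrom = as.character(chrom_i),
                    start = start, end = start + config$gene_length - 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_model", "data.frame")
  out
}

# Substream seeding: one fixed offset per generated data type so adding a
# generator never perturbs the draws of the others.
.stream_offsets <- c(cn = 11L, mutations = 12L, drivers = 13L,
                     read_counts = 14L, coverage = 15L, expression = 16L)

with_stream <- function(seed, stream, expr) {
  set.seed(seed + .stream_offsets[[stream]])
  expr
}

#' Simulate a complete paired tumor / cell-line cohort
#'
#' Emits, under `dir`, every file type the pipeline consumes — gene model,
#' SEG (tumors and cell lines), MAF x2, per-sample coverage (BED for
#' tumors, WIG for cell lines), expression TSV x2, stromal/immune gene-set
#' files, a focal-peak gene list — plus a machine-readable ground-truth
#' table. Output is deterministic given `config$seed` (byte-identical
#' across reruns).
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @return invisible list: `paths` (named file paths), `truth` (data
#'   frame), `config`, `gene_model`.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  model <- synthetic_gene_model(config)
  tumors <- sprintf("TUMOR_%03d", seq_len(config$n_tumors))
  lines <- sprintf("CL_%03d", seq_len(config$n_cell_lines))
  samples <- c(tumors, lines)
  group <- c(rep("tumor", config$n_tumors),
             rep("cell_line", config$n_cell_lines))

  ## --- copy number -------------------------------------------------------
  cn <- with_stream(config$seed, "cn",
                    simulate_cn(config, samples, group))
  ## --- coverage ----------------------------------------------------------
  cov <- with_stream(config$seed, "coverage",
                     simulate_coverage(config, model, samples))
  ## --- background mutations ---------------------------------------------
  muts <- with_stream(config$seed, "mutations",
                      simulate_mutations(config, model, samples, cov))
  ## --- exclusive driver pair --------------------------------------------
  drv <- with_stream(config$seed, "drivers",
                     simulate_drivers(config, model, samples))
  ## --- read counts (VAF / depth) ----------------------------------------
  muts <- with_stream(config$seed, "read_counts",
                      assign_read_counts(config, muts))
  all_muts <- rbind(muts, drv$records)
  all_muts <- all_muts[order(all_muts$sample_id, all_muts$chrom,
                             all_muts$pos), , drop = FALSE]
  ## --- expression --------------------------------------------------------
  sets <- signature_sets(config, model)
  expr <- with_stream(config$seed, "expression",
                      simulate_expression(config, model, samples, group,
                                          sets))

  ## --- write files --------------------------------------------------------
  paths <- list()
  paths$gene_model <- file.path(dir, "gene_model.tsv")
  utils::write.table(as.data.frame(model), paths$gene_model, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$seg_tumors <- file.path(dir, "tumors.seg")
  paths$seg_cell_lines <- file.path(dir, "cell_lines.seg")
  write_seg(cn$segs[cn$segs$sample_id %in% tumors, ], paths$seg_tumors)
  write_seg(cn$segs[cn$segs$sample_id %in% lines, ], paths$seg_cell_lines)
  paths$maf_tumors <- file.path(dir, "tumors.maf")
  paths$maf_cell_lines <- file.path(dir, "cell_lines.maf")
  write_synthetic_maf(all_muts[all_muts$sample_id %in% tumors, ],
                      paths$maf_tumors)
  write_synthetic_maf(all_muts[all_muts$sample_id %in% lines, ],
                      paths$maf_cell_lines)
  paths$coverage <- vapply(samples, function(sid) {
    if (group[match(sid, samples)] == "tumor") {
      f <- file.path(dir, "coverage", paste0(sid, ".bed"))
      write_coverage_bed_file(cov[[sid]], model, config, f)
    } else {
      f <- file.path(dir, "coverage", paste0(sid, ".wig"))
      write_coverage_wig_file(cov[[sid]], model, config, f)
    }
    f
  }, character(1))
  paths$expression_tumors <- file.path(dir, "expression_tumors.tsv")
  paths$expression_cell_lines <- file.path(dir, "expression_cell_lines.tsv")
  write_expression(expr[, tumors, drop = FALSE], paths$expression_tumors)
  write_expression(expr[, lines, drop = FALSE],
                   paths$expression_cell_lines)
  paths$stromal_set <- file.path(dir, "geneset_stromal.txt")
  paths$immune_set <- file.path(dir, "geneset_immune.txt")
  write_gene_set(sets$stromal, paths$stromal_set)
  write_gene_set(sets$immune, paths$immune_set)
  paths$focal_peaks <- file.path(dir, "focal_peak_genes.txt")
  writeLines(focal_peak_genes(config, model), paths$focal_peaks)

  ## --- ground truth -------------------------------------------------------
  truth <- build_truth(config, samples, group, cn, cov, all_muts, expr)
  paths$truth <- file.path(dir, "truth.tsv")
  truth_report(truth, paths$truth)

  invisible(list(paths = paths, truth = truth, config = config,
                 gene_model = model))
}

# Per-sample segment table with planted focal events. Chromosomes are
# partitioned at event boundaries; carriers get the event effect added to
# the background mean of the event segments.
simulate_cn <- function(config, samples, group) {
  events <- config$focal_events
  # chromosome partitions
  parts <- lapply(seq_len(config$n_chromosomes), function(ci) {
    cl <- config$chrom_length
    cuts <- c(1, cl + 1)
    for (ev in events) if (ev$chrom == as.character(ci))
      cuts <- c(cuts, ev$start, ev$end + 1)
    cuts <- sort(unique(cuts))
    data.frame(chrom = as.character(ci), start = cuts[-length(cuts)],
               end = cuts[-1L] - 1, stringsAsFactors = FALSE)
  })
  skel <- do.call(rbind, parts)
  # which events cover which skeleton segments
  ev_cover <- lapply(events, function(ev)
    skel$chrom == ev$chrom & skel$start >= ev$start & skel$end <= ev$end)
  carriers <- matrix(FALSE, length(samples), length(events),
                     dimnames = list(samples, NULL))
  seg_list <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    mean_s <- stats::rnorm(nrow(skel), 0, config$background_cn_sd)
    for (e in seq_along(events)) {
      ev <- events[[e]]
      carry <- stats::runif(1) < ev$carrier_prob[[group[s]]]
      carriers[s, e] <- carry
      if (carry) {
        eff <- if (ev$direction == "amp") ev$effect else -ev$effect
        mean_s[ev_cover[[e]]] <- mean_s[ev_cover[[e]]] + eff
      }
    }
    seg_list[[s]] <- data.frame(sample_id = samples[s], chrom = skel$chrom,
                                start = skel$start, end = skel$end,
                                seg_mean = mean_s, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, seg_list)
  class(segs) <- c("seg_profiles", "data.frame")
  # planted FGA: carried event length over total genome length
  ev_len <- vapply(events, function(ev) ev$end - ev$start + 1, numeric(1))
  total <- config$n_chromosomes * config$chrom_length
  fga_planted <- as.numeric(carriers %*% ev_len) / total
  list(segs = segs, carriers = carriers, fga_planted = fga_planted)
}

# Covered-gene indicator per sample (the breadth knob).
simulate_coverage <- function(config, model, samples) {
  out <- lapply(samples, function(sid)
    which(stats::runif(config$n_genes) < config$coverage_breadth_fraction))
  names(out) <- samples
  out
}

write_coverage_bed_file <- function(covered_idx, model, config, path) {
  g <- model[covered_idx, , drop = FALSE]
  track <- structure(list(sample_id = basename(path), mode = "intervals",
                          intervals = data.frame(chrom = g$chrom,
                                                 start = g$start - 1,
                                                 end = g$end,
                                                 stringsAsFactors = FALSE)),
                     class = "coverage_track")
  write_bed(track, path)
}

write_coverage_wig_file <- function(covered_idx, model, config, path) {
  g <- model[covered_idx, , drop = FALSE]
  L <- config$gene_length
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines,
               sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       g$chrom[i], as.integer(g$start[i]), L, L),
               "20")
  }
  writeLines(lines, path)
  invisible(path)
}

# Background mutations: placed uniformly over each sample's covered gene
# space; substitution contexts drawn so a fraction uv_weight are C>T at a
# dipyrimidine (CC>TT pairs at rate cctt_rate within those); half of all
# SNP records are emitted on the opposite strand to exercise
# strand-normalization downstream.
simulate_mutations <- function(config, model, samples, cov) {
  rows <- list()
  bases <- c("A", "C", "G", "T")
  nonuv <- list(c("C", "A"), c("C", "G"), c("T", "A"), c("T", "C"),
                c("T", "G"))
  for (sid in samples) {
    covered <- cov[[sid]]
    if (length(covered) == 0L) next
    mb <- length(covered) * config$gene_length / 1e6
    n <- stats::rpois(1, config$background_mut_rate * mb)
    if (n == 0L) next
    gi <- covered[sample.int(length(covered), n, replace = TRUE)]
    offs <- sample.int(config$gene_length - 2L, n, replace = TRUE)
    pos <- model$start[gi] + offs
    is_indel <- stats::runif(n) < config$indel_fraction
    is_uv <- !is_indel & stats::runif(n) < config$uv_weight
    is_cctt <- is_uv & stats::runif(n) < config$cctt_rate
    is_syn <- !is_indel & stats::runif(n) < config$synonymous_fraction
    flip <- stats::runif(n) < 0.5
    for (k in seq_len(n)) {
      if (is_indel[k]) {
        del <- stats::runif(1) < 0.5
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene = model$gene[gi[k]],
          chrom = model$chrom[gi[k]], pos = pos[k],
          ref_allele = if (del) "A" else "-",
          alt_allele = if (del) "-" else "A",
          variant_class = if (del) "DEL" else "INS",
          classification = if (del) "Frame_Shift_Del" else "Frame_Shift_Ins",
          flank5 = NA_character_, flank3 = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      cls <- if (is_syn[k]) "Silent" else "Missense_Mutation"
      if (is_cctt[k]) {
        # adjacent CC>TT pair; each member is a dipyrimidine C>T
        f5 <- sample(bases, 1)
        f3 <- sample(bases, 1)
        part <- data.frame(
          sample_id = sid, gene = model$gene[gi[k]],
          chrom = model$chrom[gi[k]], pos = c(pos[k], pos[k] + 1),
          ref_allele = "C", alt_allele = "T", variant_class = "SNP",
          classification = cls,
          flank5 = c(f5, "C"), flank3 = c("C", f3),
          stringsAsFactors = FALSE)
        if (flip[k]) part <- flip_strand(part)
        rows[[length(rows) + 1L]] <- part
        next
      }
      if (is_uv[k]) {
        ra <- c("C", "T")
        f5 <- sample(c("C", "T"), 1)        # guarantees dipyrimidine
        f3 <- sample(bases, 1)
      } else {
        ra <- nonuv[[sample.int(length(nonuv), 1)]]
        f5 <- sample(bases, 1)
        f3 <- sample(bases, 1)
      }
      part <- data.frame(
        sample_id = sid, gene = model$gene[gi[k]],
        chrom = model$chrom[gi[k]], pos = pos[k],
        ref_allele = ra[1], alt_allele = ra[2], variant_class = "SNP",
        classification = cls, flank5 = f5, flank3 = f3,
        stringsAsFactors = FALSE)
      if (flip[k]) part <- flip_strand(part)
      rows[[length(rows) + 1L]] <- part
    }
  }
  if (length(rows) == 0L) return(empty_sim_records())
  do.call(rbind, rows)
}

flip_strand <- function(df) {
  f5 <- df$flank5; f3 <- df$flank3
  df$ref_allele <- complement_base(df$ref_allele)
  df$alt_allele <- complement_base(df$alt_allele)
  df$flank5 <- complement_base(f3)
  df$flank3 <- complement_base(f5)
  df
}

empty_sim_records <- function() {
  data.frame(sample_id = character(), gene = character(),
             chrom = character(), pos = numeric(),
             ref_allele = character(), alt_allele = character(),
             variant_class = character(), classification = character(),
             flank5 = character(), flank3 = character(),
             vaf = numeric(), depth = integer(), alt_count = integer(),
             exclusive_status = character(),
             stringsAsFactors = FALSE)
}

# Exclusive-pair driver assignment: A xor B with probability coverage_prob
# (split by `balance`), both with co_occurrence_prob. Driver records always
# pass the VAF/depth filters so planted margins are recovered exactly.
simulate_drivers <- function(config, model, samples) {
  ep <- config$exclusive_pair
  status <- stats::setNames(rep("neither", length(samples)), samples)
  if (is.null(ep)) return(list(records = empty_sim_records()[0, ],
                               status = status))
  for (g in c(ep$gene_a, ep$gene_b))
    if (!g %in% model$gene) stop("exclusive-pair gene not in model: ", g)
  rows <- list()
  for (sid in samples) {
    u <- stats::runif(1)
    st <- if (u < ep$coverage_prob * ep$balance) "A"
          else if (u < ep$coverage_prob) "B"
          else if (u < ep$coverage_prob + ep$co_occurrence_prob) "both"
          else "neither"
    status[[sid]] <- st
    carry <- switch(st, A = ep$gene_a, B = ep$gene_b,
                    both = c(ep$gene_a, ep$gene_b), neither = character(0))
    for (g in carry) {
      gi <- match(g, model$gene)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene = g, chrom = model$chrom[gi],
        pos = model$start[gi] + 10, ref_allele = "T", alt_allele = "C",
        variant_class = "SNP", classification = "Missense_Mutation",
        flank5 = "A", flank3 = "G",
        vaf = 0.5, depth = 100L, alt_count = 50L,
        exclusive_status = st, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    empty_sim_records()[0, ]
  list(records = records, status = status)
}

assign_read_counts <- function(config, muts) {
  n <- nrow(muts)
  if (n == 0L) {
    muts$vaf <- numeric(0); muts$depth <- integer(0)
    muts$alt_count <- integer(0)
    muts$exclusive_status <- character(0)
    return(muts)
  }
  depth <- pmax(1L, stats::rnbinom(n, mu = config$depth_mu,
                                   size = config$depth_size))
  vaf_raw <- stats::rbeta(n, config$vaf_shape[1], config$vaf_shape[2])
  alt <- pmin(depth, pmax(0L, as.integer(round(vaf_raw * depth))))
  muts$vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  muts$depth <- depth
  muts$alt_count <- alt
  muts$exclusive_status <- NA_character_
  muts
}

signature_sets <- function(config, model) {
  n <- config$n_genes
  s_idx <- (n - config$stromal_set_size - config$immune_set_size + 1L):
           (n - config$immune_set_size)
  i_idx <- (n - config$immune_set_size + 1L):n
  list(stromal = gene_set("STROMAL_SYNTHETIC", model$gene[s_idx]),
       immune = gene_set("IMMUNE_SYNTHETIC", model$gene[i_idx]),
       stromal_idx = s_idx, immune_idx = i_idx)
}

# Expression = purity * tumor archetype + (1 - purity)/2 * (stromal +
# immune archetypes) + Gaussian noise. Cell lines are pure tumor.
simulate_expression <- function(config, model, samples, group, sets) {
  n <- config$n_genes
  tumor_arch <- stats::rnorm(n, 5, 2)
  stromal_arch <- stats::rnorm(n, 2, 1)
  stromal_arch[sets$stromal_idx] <- stromal_arch[sets$stromal_idx] + 6
  immune_arch <- stats::rnorm(n, 2, 1)
  immune_arch[sets$immune_idx] <- immune_arch[sets$immune_idx] + 6
  purity <- planted_purity(config, samples, group)
  expr <- vapply(seq_along(samples), function(s) {
    f <- purity[[s]]
    f * tumor_arch + (1 - f) * 0.5 * (stromal_arch + immune_arch) +
      stats::rnorm(n, 0, config$expression_noise_sd)
  }, numeric(n))
  dimnames(expr) <- list(model$gene, samples)
  expr
}

planted_purity <- function(config, samples, group) {
  purity <- numeric(length(samples))
  ti <- which(group == "tumor")
  purity[ti] <- rep_len(config$purity_levels, length(ti))
  purity[group == "cell_line"] <- 1
  stats::setNames(purity, samples)
}

focal_peak_genes <- function(config, model) {
  hit <- rep(FALSE, nrow(model))
  for (ev in config$focal_events)
    hit <- hit | (model$chrom == ev$chrom & model$start <= ev$end &
                  model$end >= ev$start)
  model$gene[hit]
}

write_synthetic_maf <- function(muts, path) {
  ctx <- ifelse(muts$variant_class == "SNP" & !is.na(muts$flank5) &
                !is.na(muts$flank3),
                paste0(muts$flank5, muts$ref_allele, muts$flank3), "")
  vt <- muts$variant_class
  out <- data.frame(
    Hugo_Symbol = muts$gene,
    Chromosome = muts$chrom,
    Start_position = format(muts$pos, scientific = FALSE, trim = TRUE),
    Reference_Allele = muts$ref_allele,
    Tumor_Seq_Allele2 = muts$alt_allele,
    Variant_Classification = muts$classification,
    Variant_Type = vt,
    Tumor_Sample_Barcode = muts$sample_id,
    t_ref_count = muts$depth - muts$alt_count,
    t_alt_count = muts$alt_count,
    ref_context = ctx,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

build_truth <- function(config, samples, group, cn, cov, all_muts, expr) {
  purity <- planted_purity(config, samples, group)
  # driver status back from records
  status <- stats::setNames(rep("neither", length(samples)), samples)
  drv <- all_muts[!is.na(all_muts$exclusive_status), , drop = FALSE]
  for (sid in unique(drv$sample_id))
    status[[sid]] <- drv$exclusive_status[drv$sample_id == sid][1L]
  n_mut <- vapply(samples, function(sid)
    sum(all_muts$sample_id == sid), integer(1))
  pass <- all_muts$vaf >= 0.1 & all_muts$depth >= 14
  n_pass <- vapply(samples, function(sid)
    sum(pass & all_muts$sample_id == sid), integer(1))
  breadth <- vapply(samples, function(sid)
    length(cov[[sid]]) * config$gene_length, numeric(1))
  truth <- data.frame(sample_id = samples, group = group,
                      purity = unname(purity[samples]),
                      fga_planted = cn$fga_planted,
                      uv_weight = config$uv_weight,
                      uv_label = config$uv_weight >= 0.6,
                      exclusive_status = unname(status[samples]),
                      n_mutations = unname(n_mut),
                      n_pass_vaf10_depth14 = unname(n_pass),
                      breadth_bp = unname(breadth),
                      stringsAsFactors = FALSE)
  for (e in seq_len(ncol(cn$carriers)))
    truth[[sprintf("focal_%d_carrier", e)]] <- unname(cn$carriers[, e])
  truth
}

#' Simulate joint mutation statuses for a two-gene pair
#'
#' Draws, per sample, whether it carries gene A only, gene B only, both, or
#' neither: exactly one of the two with probability `coverage_prob` (gene A
#' with conditional probability `balance`), both with
#' `co_occurrence_prob`. Setting `co_occurrence_prob` to the product of the
#' two marginal frequencies yields an independently mutated pair with the
#' same margins — the null counterpart for power studies.
#'
#' @param n number of samples.
#' @param coverage_prob probability of carrying exactly one of the pair.
#' @param balance conditional probability the carried gene is A
#'   (default 0.5).
#' @param co_occurrence_prob probability of carrying both.
#' @param seed integer seed.
#' @return list: `status` (character vector in `{"A","B","both","neither"}`)
#'   and `table` (the [contingency22()] of the draw).
#' @export
simulate_pair_statuses <- function(n, coverage_prob, balance = 0.5,
                                   co_occurrence_prob, seed) {
  stopifnot(n >= 1, coverage_prob >= 0, coverage_prob <= 1,
            co_occurrence_prob >= 0, balance >= 0, balance <= 1)
  if (coverage_prob + co_occurrence_prob > 1)
    stop("impossible config: coverage_prob + co_occurrence_prob > 1")
  set.seed(seed)
  u <- stats::runif(n)
  status <- ifelse(u < coverage_prob * balance, "A",
            ifelse(u < coverage_prob, "B",
            ifelse(u < coverage_prob + co_occurrence_prob, "both",
                   "neither")))
  list(status = status,
       table = contingency22(neither = sum(status == "neither"),
                             gene2_only = sum(status == "B"),
                             gene1_only = sum(status == "A"),
                             both = sum(status == "both")))
}

#' Write the ground-truth table of a simulated cohort
#'
#' Column names are stable: `sample_id`, `group`, `purity`, `fga_planted`,
#' `uv_weight`, `uv_label`, `exclusive_status`, `n_mutations`,
#' `n_pass_vaf10_depth14`, `breadth_bp`, then one `focal_<k>_carrier`
#' column per focal event.
#'
#' @param truth the truth data frame from [simulate_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
truth_report <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
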