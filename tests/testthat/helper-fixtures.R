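# Fixture builders shared across the suite. Everything is generated in
# code at test time; no data files ship with the tests.

# Construct a maf_records data frame directly (bypassing file parsing) for
# unit tests of the statistics.
make_records <- function(sample_id, gene = "GENE1", chrom = "1",
                         pos = seq_along(sample_id) * 100,
                         ref = "C", alt = "T", class = "SNP",
                         synonymous = FALSE, vaf = 0.5, depth = 50L,
                         flank5 = "T", flank3 = "A") {
  n <- length(sample_id)
  out <- data.frame(sample_id = sample_id,
                    gene = rep_len(gene, n), chrom = rep_len(chrom, n),
                    pos = rep_len(pos, n),
                    ref_allele = rep_len(ref, n),
                    alt_allele = rep_len(alt, n),
                    variant_class = rep_len(class, n),
                    is_synonymous = rep_len(synonymous, n),
                    vaf = rep_len(vaf, n),
                    depth = as.integer(rep_len(depth, n)),
                    flank5 = rep_len(flank5, n),
                    flank3 = rep_len(flank3, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("maf_records", "data.frame")
  out
}

write_toy_maf <- function(path, rows) {
  header <- paste(c("Hugo_Symbol", "Chromosome", "Start_position",
                    "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Variant_Type",
                    "Tumor_Sample_Barcode", "t_ref_count", "t_alt_count",
                    "ref_context"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

write_toy_seg <- function(path, rows,
                          header = "Sample\tChromosome\tStart\tEnd\tSegment_Mean") {
  writeLines(c(header, rows), path)
  path
}

make_seg <- function(sample_id, chrom, start, end, seg_mean) {
  out <- data.frame(sample_id = sample_id, chrom = as.character(chrom),
                    start = start, end = end, seg_mean = seg_mean,
                    stringsAsFactors = FALSE)
  class(out) <- c("seg_profiles", "data.frame")
  out
}

make_model <- function(gene, chrom, start, end) {
  out <- data.frame(gene = gene, chrom = as.character(chrom),
                    start = start, end = end, stringsAsFactors = FALSE)
  class(out) <- c("gene_model", "data.frame")
  out
}
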