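# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately re-derive results by a different route than
# the package code.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(L) paste(sample(AA20, L, replace = TRUE),
                                  collapse = "")

# Window oracle: the unique min(2f+1, L)-length interval containing p that is
# as centered as possible (clamped to the protein), derived in closed form
# rather than by the two-step extend rule.
oracle_window <- function(protein, p, f) {
  L <- nchar(protein)
  w <- min(2L * f + 1L, L)
  start <- min(max(1L, p - f), L - w + 1L)
  list(start = start, end = start + w - 1L,
       wt = substr(protein, start, start + w - 1L), offset = p - start + 1L)
}

# Sliding-window k-mer oracle via an explicit loop.
oracle_kmers <- function(window, k) {
  out <- character(0)
  i <- 1L
  while (i + k - 1L <= nchar(window)) {
    out <- c(out, substr(window, i, i + k - 1L))
    i <- i + 1L
  }
  out
}

# Best-candidate oracle: explicit row-by-row comparison with the documented
# tie-break (lower MT IC50, then smaller k, then allele string order, then
# smaller start offset).
oracle_best <- function(rows) {
  best <- 1L
  for (j in seq_len(nrow(rows))[-1]) {
    a <- rows[j, ]; b <- rows[best, ]
    better <- if (a$mt_ic50_nm != b$mt_ic50_nm) a$mt_ic50_nm < b$mt_ic50_nm
      else if (a$k != b$k) a$k < b$k
      else if (a$hla_allele != b$hla_allele) a$hla_allele < b$hla_allele
      else a$start_offset < b$start_offset
    if (better) best <- j
  }
  rows[best, ]
}

# A three-variant annotated table, including BRAF V600E on a 766-residue
# protein carrying V at position 600.
tiny_variants <- function() {
  braf <- rand_protein(766)
  substr(braf, 600, 600) <- "V"
  p2 <- rand_protein(100); substr(p2, 12, 12) <- "G"
  p3 <- rand_protein(40); substr(p3, 3, 3) <- "L"
  data.frame(
    variant_id = c("v1", "v2", "v3"),
    chrom = c("chr7", "chr12", "chr1"),
    pos = c(140453136L, 25398284L, 1000L),
    ref = c("A", "C", "G"), alt = c("T", "T", "A"),
    gene = c("BRAF", "KRAS", "G3"),
    transcript_id = c("T1", "T2", "T3"),
    protein_change = c("p.V600E", "G12D", "p.L3P"),
    wt_protein_seq = c(braf, p2, p3),
    stringsAsFactors = FALSE)
}

write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Site metrics that pass every rule of all three rule sets.
passing_metrics <- function() {
  data.frame(distance_to_nearest_indel_bp = 100, nearest_indel_quality = 10,
             max_mapping_quality = 60, snv_calls_in_10bp_window = 0,
             site_depth = 50, consensus_quality = 40, snp_quality = 40,
             var_strand_fraction_fwd = 0.5, var_strand_fraction_rev = 0.5,
             tumor_vaf = 0.40, var_read_count = 20,
             avg_rel_read_position = 0.5, mismatch_qualsum_diff = 0,
             mapping_quality_diff = 0, avg_supporting_read_length_diff = 0,
             avg_rel_distance_to_3prime = 0.5,
             homopolymer_adjacent_length = 0,
             varscan_p_value = 0.01, normal_vaf = 0.0)
}

# For each rule of each rule set: a metric assignment just inside the pass
# boundary and one just outside (violating exactly that rule).
boundary_cases <- function() {
  list(
    snp = list(
      a = list(ok = list(distance_to_nearest_indel_bp = 11,
                         nearest_indel_quality = 60),
               bad = list(distance_to_nearest_indel_bp = 10,
                          nearest_indel_quality = 50)),
      b = list(ok = list(max_mapping_quality = 40),
               bad = list(max_mapping_quality = 39.9)),
      c = list(ok = list(snv_calls_in_10bp_window = 2),
               bad = list(snv_calls_in_10bp_window = 3)),
      d = list(ok = list(site_depth = 3), bad = list(site_depth = 2)),
      e = list(ok = list(consensus_quality = 20, snp_quality = 20),
               bad = list(consensus_quality = 19.9, snp_quality = 20))),
    false_positive = list(
      a = list(ok = list(var_strand_fraction_fwd = 0.01),
               bad = list(var_strand_fraction_fwd = 0.009)),
      b = list(ok = list(tumor_vaf = 0.05), bad = list(tumor_vaf = 0.049)),
      c = list(ok = list(var_read_count = 5), bad = list(var_read_count = 4)),
      d = list(ok = list(avg_rel_read_position = 0.101),
               bad = list(avg_rel_read_position = 0.1)),
      e = list(ok = list(mismatch_qualsum_diff = 49.9),
               bad = list(mismatch_qualsum_diff = 50)),
      f = list(ok = list(mapping_quality_diff = 29.9),
               bad = list(mapping_quality_diff = 30)),
      g = list(ok = list(avg_supporting_read_length_diff = 24.9),
               bad = list(avg_supporting_read_length_diff = 25)),
      h = list(ok = list(avg_rel_distance_to_3prime = 0.2),
               bad = list(avg_rel_distance_to_3prime = 0.199)),
      i = list(ok = list(homopolymer_adjacent_length = 4),
               bad = list(homopolymer_adjacent_length = 5))),
    varscan = list(
      a = list(ok = list(varscan_p_value = 0.07),
               bad = list(varscan_p_value = 0.071)),
      b = list(ok = list(normal_vaf = 0.05), bad = list(normal_vaf = 0.051)),
      c = list(ok = list(tumor_vaf = 0.10), bad = list(tumor_vaf = 0.099)),
      d = list(ok = list(var_read_count = 2), bad = list(var_read_count = 1))))
}

filter_fn <- function(ruleset) switch(ruleset,
  snp = snp_filter_v1, false_positive = false_positive_filter_v1,
  varscan = varscan_high_confidence_v1)

# A minimal annotated-candidate row for the coverage/expression filters.
candidate_row <- function(variant_id = "v1", normal_depth = 30,
                          normal_vaf = 0, tumor_depth = 30, tumor_vaf = 0.5,
                          rna_depth = 30, rna_vaf = 0.5, fpkm = 5) {
  data.frame(variant_id = variant_id, normal_dna_depth = normal_depth,
             normal_dna_vaf = normal_vaf, tumor_dna_depth = tumor_depth,
             tumor_dna_vaf = tumor_vaf, tumor_rna_depth = rna_depth,
             tumor_rna_vaf = rna_vaf, gene_fpkm = fpkm,
             stringsAsFactors = FALSE)
}
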