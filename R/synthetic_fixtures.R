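# Synthetic fixture generators: every pipeline input, with controlled
# statistical structure and planted filter failures, so each stage and the
# end-to-end run are testable with no sequencing data. All generators are
# deterministic given the config seed, which is split per component.

#' Configuration for the synthetic fixture generators
#'
#' The defaults describe a small exome-like cohort: 50 proteins of 30--800
#' residues, 200 missense variants of which 20% sit within the flank length
#' of a protein terminus (exercising the window edge rule), ~30x normal and
#' ~60x tumor depth, founder-clone somatic VAF around 0.5, 10% planted
#' germline-contaminated sites, log-normal FPKM with 30% of genes unexpressed.
#'
#' @param seed Global integer seed; split per component via a keyed hash.
#' @param n_proteins Number of synthetic proteins (one gene/transcript each).
#' @param protein_length_range Min/max protein length (residues).
#' @param n_variants Number of missense variants to plant.
#' @param fraction_near_terminus Fraction of variants placed within `flank`
#'   residues of a protein end.
#' @param flank Flank length the terminus fraction refers to.
#' @param normal_depth_mean,tumor_depth_mean Mean read depths (negative
#'   binomial, size 8).
#' @param true_somatic_vaf_mean Mean tumor VAF of true somatic sites (beta
#'   with concentration 25).
#' @param germline_contam_fraction Fraction of sites planted as germline
#'   (normal VAF near 0.5) — these must fail the normal-VAF filter.
#' @param fpkm_lognormal_params `c(meanlog, sdlog)` of expressed-gene FPKM.
#' @param fraction_unexpressed Fraction of genes planted at FPKM 0 (their
#'   RNA depth is also 0).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, n_proteins = 50,
                           protein_length_range = c(30, 800),
                           n_variants = 200, fraction_near_terminus = 0.2,
                           flank = 10,
                           normal_depth_mean = 30, tumor_depth_mean = 60,
                           true_somatic_vaf_mean = 0.5,
                           germline_contam_fraction = 0.1,
                           fpkm_lognormal_params = c(meanlog = 1, sdlog = 1),
                           fraction_unexpressed = 0.3) {
  stopifnot(n_proteins >= 1, n_variants >= 1,
            protein_length_range[1] >= 1,
            protein_length_range[2] >= protein_length_range[1],
            fraction_near_terminus >= 0, fraction_near_terminus <= 1,
            germline_contam_fraction >= 0, germline_contam_fraction <= 1,
            fraction_unexpressed >= 0, fraction_unexpressed <= 1,
            normal_depth_mean > 0, tumor_depth_mean > 0,
            true_somatic_vaf_mean > 0, true_somatic_vaf_mean < 1)
  structure(list(seed = seed, n_proteins = n_proteins,
                 protein_length_range = protein_length_range,
                 n_variants = n_variants,
                 fraction_near_terminus = fraction_near_terminus,
                 flank = flank,
                 normal_depth_mean = normal_depth_mean,
                 tumor_depth_mean = tumor_depth_mean,
                 true_somatic_vaf_mean = true_somatic_vaf_mean,
                 germline_contam_fraction = germline_contam_fraction,
                 fpkm_lognormal_params = fpkm_lognormal_params,
                 fraction_unexpressed = fraction_unexpressed),
            class = "fixture_config")
}

#' Generate a synthetic proteome
#'
#' Proteins are uniform random strings over the 20 standard amino acids with
#' lengths uniform in the configured range; names are `TX0001`... with gene
#' names `GENE0001`... attached as metadata.
#'
#' @param config A [fixture_config()].
#' @return An `AAStringSet` named by transcript ID, with a `gene_map`
#'   attribute (data.frame `transcript_id`, `gene`).
#' @export
generate_proteome <- function(config) {
  withr::with_seed(derive_seed(config$seed, "proteome"), {
    lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE), collapse = ""),
      character(1))
  })
  tx <- sprintf("TX%04d", seq_len(config$n_proteins))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- tx
  attr(aa, "gene_map") <- data.frame(
    transcript_id = tx, gene = sprintf("GENE%04d", seq_len(config$n_proteins)),
    stringsAsFactors = FALSE)
  aa
}

#' Generate annotated missense variants over a synthetic proteome
#'
#' Each variant samples a protein, a position (interior, or within `flank` of
#' a terminus for the configured fraction, so the window edge rule is
#' exercised), reads the wild-type residue off the protein (so strict
#' validation always passes by construction) and draws a different mutant
#' residue. Genomic coordinates are synthetic and unique per variant.
#'
#' @param proteome `AAStringSet` from [generate_proteome()].
#' @param config A [fixture_config()].
#' @return A variant data.frame in the same shape as
#'   [read_annotated_variants()] output, with a logical `near_terminus`
#'   attribute column used by tests.
#' @export
generate_variants <- function(proteome, config) {
  gene_map <- attr(proteome, "gene_map")
  seqs <- as.character(proteome)
  n <- config$n_variants
  f <- config$flank
  withr::with_seed(derive_seed(config$seed, "variants"), {
    prot_idx <- sample(length(seqs), n, replace = TRUE)
    near <- stats::runif(n) < config$fraction_near_terminus
    pos <- integer(n)
    for (i in seq_len(n)) {
      L <- nchar(seqs[prot_idx[i]])
      edge <- min(f, L)
      if (near[i] || L <= 2L * f + 1L) {
        # within `flank` of either terminus (short proteins are always edges)
        pos[i] <- if (stats::runif(1) < 0.5) sample.int(edge, 1L) else
          L - sample.int(edge, 1L) + 1L
        near[i] <- TRUE
      } else {
        pos[i] <- sample((f + 1L):(L - f), 1L)
      }
    }
    wt <- substring(seqs[prot_idx], pos, pos)
    mt <- vapply(wt, function(w) sample(setdiff(AA_STANDARD, w), 1L),
                 character(1), USE.NAMES = FALSE)
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    gpos <- sample.int(1e8L, n, replace = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
  })
  out <- data.frame(
    variant_id = sprintf("VAR%04d", seq_len(n)),
    chrom = chrom, pos = gpos, ref = ref, alt = alt,
    gene = gene_map$gene[prot_idx],
    transcript_id = gene_map$transcript_id[prot_idx],
    protein_change = paste0("p.", wt, pos, mt),
    wt_protein_seq = unname(seqs[prot_idx]),
    wt_residue = wt, protein_pos = pos, mt_residue = mt,
    variant_type = "missense", stringsAsFactors = FALSE)
  out$near_terminus <- near
  out
}

#' Generate coverage and expression tables for a variant set
#'
#' Depths are overdispersed (negative binomial, size 8) around the configured
#' means. True somatic sites draw their tumor VAF from a beta distribution
#' around the configured mean and have (error-level) normal support; a
#' planted `germline_contam_fraction` of sites instead have normal and tumor
#' VAF near 0.5, which the normal-VAF depth filter must remove. Per gene,
#' FPKM is log-normal with a planted unexpressed fraction at exactly 0; the
#' tumor RNA track has depth 0 for unexpressed genes.
#'
#' @param variants Variant table from [generate_variants()].
#' @param config A [fixture_config()].
#' @return A list with `coverage` and `expression` data.frames (the dialects
#'   read by [read_coverage()] / [read_expression()]) and `truth`, a per-
#'   variant data.frame of planted labels (`is_germline`, `is_expressed`,
#'   `true_vaf`) for oracle tests.
#' @export
generate_coverage_and_expression <- function(variants, config) {
  n <- nrow(variants)
  genes <- unique(variants[, c("gene", "transcript_id")])
  withr::with_seed(derive_seed(config$seed, "coverage"), {
    is_germline <- stats::runif(n) < config$germline_contam_fraction
    kappa <- 25
    vaf <- ifelse(is_germline,
                  stats::rbeta(n, 0.5 * kappa, 0.5 * kappa),
                  stats::rbeta(n, config$true_somatic_vaf_mean * kappa,
                               (1 - config$true_somatic_vaf_mean) * kappa))
    normal_depth <- stats::rnbinom(n, size = 8, mu = config$normal_depth_mean)
    tumor_depth <- stats::rnbinom(n, size = 8, mu = config$tumor_depth_mean)
    rna_depth <- stats::rnbinom(n, size = 8, mu = config$tumor_depth_mean)
    normal_var <- ifelse(is_germline,
                         stats::rbinom(n, normal_depth, vaf),
                         stats::rbinom(n, normal_depth, 0.001))
    tumor_var <- stats::rbinom(n, tumor_depth, vaf)

    unexpressed <- stats::runif(nrow(genes)) < config$fraction_unexpressed
    fpkm <- ifelse(unexpressed, 0,
                   stats::rlnorm(nrow(genes),
                                 config$fpkm_lognormal_params[1],
                                 config$fpkm_lognormal_params[2]))
    gene_expressed <- stats::setNames(!unexpressed, genes$gene)
    rna_depth[!gene_expressed[variants$gene]] <- 0L
    rna_var <- stats::rbinom(n, rna_depth, vaf)
  })
  track_df <- function(track, depth, var) {
    data.frame(chrom = variants$chrom, pos = variants$pos, track = track,
               ref_count = depth - var, var_count = var, total_depth = depth,
               stringsAsFactors = FALSE)
  }
  coverage <- rbind(track_df("normal_dna", normal_depth, normal_var),
                    track_df("tumor_dna", tumor_depth, tumor_var),
                    track_df("tumor_rna", rna_depth, rna_var))
  expression <- data.frame(gene = genes$gene,
                           transcript_id = genes$transcript_id,
                           fpkm = fpkm, stringsAsFactors = FALSE)
  truth <- data.frame(variant_id = variants$variant_id,
                      is_germline = is_germline,
                      is_expressed = unname(gene_expressed[variants$gene]),
                      true_vaf = vaf, stringsAsFactors = FALSE)
  list(coverage = coverage, expression = expression, truth = truth)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates proteome, variants, coverage and expression with one call and
#' writes them in exactly the dialects the pipeline consumes.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return A named list of file paths (`variants`, `coverage`, `expression`,
#'   `proteome`) plus the in-memory `truth` table.
#' @export
generate_fixture_set <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(config)
  variants <- generate_variants(proteome, config)
  covexp <- generate_coverage_and_expression(variants, config)
  paths <- list(variants = file.path(dir, "variants.tsv"),
                coverage = file.path(dir, "coverage.tsv"),
                expression = file.path(dir, "expression.tsv"),
                proteome = file.path(dir, "proteome.fasta"))
  write_annotated_variants(variants, paths$variants)
  utils::write.table(covexp$coverage, paths$coverage, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(covexp$expression, paths$expression, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(proteome, paths$proteome, width = 60L)
  c(paths, list(truth = covexp$truth))
}
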