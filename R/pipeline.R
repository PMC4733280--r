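# End-to-end orchestration: configuration, staged execution, run report and
# stable outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: epitope lengths
#' 8--11 (the lengths class I molecules present), flank 10 (21-mer windows),
#' strict 500 nM mutant binding threshold, normal depth/VAF disqualifiers at
#' 5x / 2%, tumor depth/VAF requirements at 10x / 40% (founder clone), FPKM
#' threshold 1. Thresholds are deliberately user-adjustable; the defaults are
#' a starting point, not a claim of universality.
#'
#' @param alleles Patient HLA class I alleles (any accepted spelling; see
#'   [normalize_hla_allele()]).
#' @param lengths Epitope lengths (subset of 8--11 unless
#'   `allow_nonstandard_lengths`).
#' @param flank Window flank (default 10).
#' @param binding_threshold_nm Strict MT IC50 cutoff in nM (default 500).
#' @param normal_cov_min,normal_vaf_max,tumor_cov_min,tumor_vaf_min,fpkm_min
#'   Filter thresholds; VAFs as fractions in `[0, 1]`.
#' @param predictor `"mock"` (built-in deterministic predictor) or
#'   `"parse-file"` (read an external prediction file).
#' @param seed Integer seed for the mock predictor.
#' @param allowlist HLA allele allow-list (`NULL` disables validation).
#' @param allow_nonstandard_lengths Permit lengths outside 8--11.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alleles, lengths = 8:11, flank = 10,
                            binding_threshold_nm = 500,
                            normal_cov_min = 5, normal_vaf_max = 0.02,
                            tumor_cov_min = 10, tumor_vaf_min = 0.40,
                            fpkm_min = 1.0,
                            predictor = c("mock", "parse-file"), seed = 0,
                            allowlist = DEFAULT_HLA_ALLOWLIST,
                            allow_nonstandard_lengths = FALSE) {
  predictor <- match.arg(predictor)
  alleles <- .validate_alleles(alleles, allowlist)
  lengths <- sort(unique(as.integer(lengths)))
  if (!allow_nonstandard_lengths && !all(lengths %in% 8:11)) {
    stop("epitope lengths outside 8..11 require allow_nonstandard_lengths",
         call. = FALSE)
  }
  stopifnot(flank >= 1, binding_threshold_nm > 0, normal_cov_min >= 0,
            normal_vaf_max >= 0, tumor_cov_min >= 0, tumor_vaf_min >= 0,
            fpkm_min >= 0)
  structure(list(alleles = alleles, lengths = lengths, flank = flank,
                 binding_threshold_nm = binding_threshold_nm,
                 normal_cov_min = normal_cov_min,
                 normal_vaf_max = normal_vaf_max,
                 tumor_cov_min = tumor_cov_min,
                 tumor_vaf_min = tumor_vaf_min, fpkm_min = fpkm_min,
                 predictor = predictor, seed = seed),
            class = "pipeline_config")
}

CANDIDATE_TSV_COLUMNS <- c(
  "variant_id", "gene", "transcript_id", "chrom", "pos", "hla_allele", "k",
  "start_offset", "mt_peptide", "wt_peptide", "mt_ic50_nm", "wt_ic50_nm",
  "fold_change", "log2_fold_change", "normal_dna_depth", "normal_dna_vaf",
  "tumor_dna_depth", "tumor_dna_vaf", "tumor_rna_depth", "tumor_rna_vaf",
  "gene_fpkm")

#' Run the full neoantigen prioritization pipeline
#'
#' Executes all stages in order: read and validate variants, build WT/MT
#' peptide windows, predict (or parse) binding affinities, pair WT with MT,
#' apply the binding filter, join coverage/VAF/FPKM, apply depth and
#' expression filters, and select the best candidate per mutation. Returns
#' both the full filtered candidate table and the one-per-mutation best
#' table, a per-stage count report, and the combined drop log. The run is
#' deterministic for a fixed config and inputs.
#'
#' When RNA coverage rows are present in the coverage table, the tumor RNA
#' track is required by the depth filters in addition to tumor DNA.
#'
#' @param config A [pipeline_config()].
#' @param variants_path Annotated variant TSV.
#' @param coverage_path Coverage TSV (see [read_coverage()]).
#' @param expression_path Expression TSV (see [read_expression()]).
#' @param predictions_path Prediction TSV, required when
#'   `config$predictor == "parse-file"`.
#' @param out_dir If non-NULL, writes `all_candidates.tsv`,
#'   `best_candidates.tsv`, `fasta.fa`, `key.tsv`, `report.tsv` and
#'   `dropped.tsv` there.
#' @return A list with `candidates` (all filtered candidates), `best` (one
#'   per mutation), `report` (named integer vector of per-stage counts) and
#'   `dropped` (all drop logs with a `stage` column).
#' @export
run_pipeline <- function(config, variants_path, coverage_path,
                         expression_path, predictions_path = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  drops <- list()
  note_drops <- function(x, stage) {
    d <- dropped_records(x)
    if (nrow(d) > 0L) {
      d$stage <- stage
      drops[[length(drops) + 1L]] <<- d
    }
    x
  }

  variants <- note_drops(read_annotated_variants(variants_path, strict = FALSE),
                         "variant_io")
  n_input <- nrow(variants) + nrow(dropped_records(variants))

  pairs <- note_drops(build_peptide_pairs(variants, config$flank), "fasta_gen")

  fasta_path <- if (is.null(out_dir)) tempfile(fileext = ".fa") else
    file.path(out_dir, "fasta.fa")
  key_path <- if (is.null(out_dir)) tempfile(fileext = ".tsv") else
    file.path(out_dir, "key.tsv")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  n_fasta <- write_fasta_and_key(pairs, fasta_path, key_path)

  preds <- if (config$predictor == "mock") {
    run_predictions(pairs, config$alleles, config$lengths,
                    mock_predictor(config$seed), allowlist = NULL)
  } else {
    if (is.null(predictions_path)) {
      stop("predictor 'parse-file' requires predictions_path", call. = FALSE)
    }
    parse_prediction_output(predictions_path, key_path)
  }

  paired <- pair_wt_mt(preds, pairs)
  bf <- note_drops(apply_binding_filter(paired, config$binding_threshold_nm),
                   "binding_filter")

  coverage <- read_coverage(coverage_path)
  expression <- read_expression(expression_path)
  annotated <- join_coverage_and_expression(bf, coverage, expression, variants)

  tracks <- "tumor_dna"
  if (any(coverage$track == "tumor_rna")) tracks <- c(tracks, "tumor_rna")
  df <- note_drops(apply_depth_filters(
    annotated, config$normal_cov_min, config$normal_vaf_max,
    config$tumor_cov_min, config$tumor_vaf_min, tracks), "depth_filter")
  ef <- note_drops(apply_expression_filter(df, config$fpkm_min),
                   "expression_filter")

  candidates <- ef[order(ef$variant_id, ef$hla_allele, ef$k, ef$start_offset),
                   , drop = FALSE]
  rownames(candidates) <- NULL
  best <- select_best_candidates(candidates)

  report <- c(input_variants = n_input,
              accepted_missense = nrow(variants),
              peptide_pairs = nrow(pairs),
              fasta_records = n_fasta,
              raw_predictions = nrow(preds),
              paired_rows = nrow(paired),
              binding_filtered = nrow(bf),
              depth_filtered = nrow(df),
              expression_filtered = nrow(ef),
              candidate_variants = nrow(best))

  dropped <- if (length(drops) > 0L) do.call(rbind, drops) else
    data.frame(variant_id = character(0), reason = character(0),
               stage = character(0), stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    fmt <- function(x) x[, intersect(CANDIDATE_TSV_COLUMNS, names(x)),
                         drop = FALSE]
    utils::write.table(fmt(candidates), file.path(out_dir, "all_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fmt(best), file.path(out_dir, "best_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(stage = names(report), count = unname(report)),
                       file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dropped, file.path(out_dir, "dropped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  list(candidates = candidates, best = best, report = report,
       dropped = dropped)
}
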