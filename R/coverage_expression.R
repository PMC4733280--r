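# Join per-site read counts (normal DNA, tumor DNA, tumor RNA) and FPKM
# expression onto candidates; compute VAFs; apply depth- and expression-based
# filters.

COVERAGE_TRACKS <- c("normal_dna", "tumor_dna", "tumor_rna")
COVERAGE_TSV_COLUMNS <- c("chrom", "pos", "track", "ref_count", "var_count",
                          "total_depth")
EXPRESSION_TSV_COLUMNS <- c("gene", "transcript_id", "fpkm")

#' Variant allele fraction
#'
#' VAF is the fraction of reads at a site supporting the variant allele.
#' A site with zero depth has no defined VAF and yields `NA` — missingness
#' is data here, not an error.
#'
#' @param var_count Variant-supporting read count(s).
#' @param total_depth Total read depth(s); must be at least `var_count`.
#' @return Numeric vector in `[0, 1]`, `NA` where depth is zero.
#' @examples
#' compute_vaf(20, 50)  # 0.40
#' @export
compute_vaf <- function(var_count, total_depth) {
  if (any(var_count < 0 | total_depth < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(var_count > total_depth, na.rm = TRUE)) {
    stop("var_count exceeds total_depth", call. = FALSE)
  }
  ifelse(total_depth > 0, var_count / total_depth, NA_real_)
}

#' Read a per-site coverage table
#'
#' Reads the reduced read-count dialect with one row per (site, sample track):
#' columns `chrom`, `pos`, `track` (one of `normal_dna`, `tumor_dna`,
#' `tumor_rna`), `ref_count`, `var_count`, `total_depth`.
#'
#' @param path Coverage TSV path.
#' @return A validated data.frame.
#' @export
read_coverage <- function(path) {
  cov <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert_columns(cov, COVERAGE_TSV_COLUMNS, "coverage table")
  cov$pos <- as.integer(cov$pos)
  bad <- setdiff(unique(cov$track), COVERAGE_TRACKS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown coverage track(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(cov$total_depth < cov$ref_count + cov$var_count)) {
    stop("total_depth below ref_count + var_count", call. = FALSE)
  }
  cov
}

#' Read a gene/transcript expression table
#'
#' @param path Expression TSV with columns `gene`, `transcript_id` (may be
#'   empty for gene-level rows) and `fpkm`.
#' @return A validated data.frame.
#' @export
read_expression <- function(path) {
  expr <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(transcript_id = "character"))
  .assert_columns(expr, EXPRESSION_TSV_COLUMNS, "expression table")
  expr$fpkm <- as.numeric(expr$fpkm)
  if (any(!is.finite(expr$fpkm)) || any(expr$fpkm < 0)) {
    stop("fpkm must be finite and non-negative", call. = FALSE)
  }
  expr
}

#' Annotate candidates with coverage, VAF and expression
#'
#' Joins per-track depth and VAF (normal DNA, tumor DNA, tumor RNA) onto each
#' candidate by genomic site, and FPKM by transcript (preferred) or gene.
#' Absent keys yield missing values, never silent zeros; candidates are not
#' removed here — filtering is a separate, explicit step.
#'
#' @param candidates Candidate table carrying `variant_id` (from
#'   [apply_binding_filter()] or [pair_wt_mt()]).
#' @param coverage Coverage data.frame from [read_coverage()].
#' @param expression Expression data.frame from [read_expression()].
#' @param variants Variant table (maps `variant_id` to `chrom`, `pos`,
#'   `gene`, `transcript_id`).
#' @return `candidates` with columns `chrom`, `pos`, `transcript_id`,
#'   `<track>_depth` and `<track>_vaf` for each of the three tracks, and
#'   `gene_fpkm` appended.
#' @export
join_coverage_and_expression <- function(candidates, coverage, expression,
                                         variants) {
  vi <- match(candidates$variant_id, variants$variant_id)
  if (anyNA(vi)) {
    stop("candidate variant_id(s) absent from the variant table", call. = FALSE)
  }
  out <- candidates
  out$chrom <- variants$chrom[vi]
  out$pos <- variants$pos[vi]
  out$transcript_id <- variants$transcript_id[vi]
  if (!"gene" %in% names(out)) out$gene <- variants$gene[vi]

  site <- paste(out$chrom, out$pos)
  for (track in COVERAGE_TRACKS) {
    sub <- coverage[coverage$track == track, , drop = FALSE]
    ci <- match(site, paste(sub$chrom, sub$pos))
    out[[paste0(track, "_depth")]] <- sub$total_depth[ci]
    out[[paste0(track, "_vaf")]] <- ifelse(
      is.na(ci), NA_real_,
      compute_vaf(sub$var_count[ci], sub$total_depth[ci]))
  }

  # transcript-level FPKM preferred when the transcript matches; else gene
  tx_rows <- expression[nzchar(expression$transcript_id) &
                          !is.na(expression$transcript_id), , drop = FALSE]
  ti <- match(out$transcript_id, tx_rows$transcript_id)
  gi <- match(out$gene, expression$gene)
  out$gene_fpkm <- ifelse(!is.na(ti), tx_rows$fpkm[ti],
                          ifelse(!is.na(gi), expression$fpkm[gi], NA_real_))
  out
}

#' Depth- and VAF-based candidate filters
#'
#' Applies the sequencing-evidence filters. Two independent normal-sample
#' disqualifiers remove a candidate: low normal coverage (depth at or below
#' `normal_cov_min`, which cannot establish absence from the germline) or
#' elevated normal VAF (at or above `normal_vaf_max`, suggesting a germline
#' variant or tumor contamination of the normal). For every required tumor
#' track the candidate must reach `tumor_cov_min` depth and `tumor_vaf_min`
#' VAF — the default 40% targets mutations in the founder clone, and can be
#' lowered to capture subclonal variants. Missing values on the normal track
#' or a required tumor track remove the candidate with reason
#' `insufficient_data`. Each removed candidate carries exactly one
#' (first-failing) reason code in the drop log.
#'
#' @param candidates Annotated table from [join_coverage_and_expression()].
#' @param normal_cov_min Normal depth at or below this removes (default 5).
#' @param normal_vaf_max Normal VAF at or above this removes (default 0.02).
#' @param tumor_cov_min Minimum tumor depth, inclusive (default 10).
#' @param tumor_vaf_min Minimum tumor VAF, inclusive (default 0.40).
#' @param tracks_required Tumor tracks that must pass; defaults to
#'   `"tumor_dna"`, with `"tumor_rna"` added by the pipeline when RNA
#'   coverage is provided.
#' @return The retained subset, with a drop log (see [dropped_records()]).
#' @export
apply_depth_filters <- function(candidates, normal_cov_min = 5,
                                normal_vaf_max = 0.02, tumor_cov_min = 10,
                                tumor_vaf_min = 0.40,
                                tracks_required = "tumor_dna") {
  stopifnot(normal_cov_min >= 0, normal_vaf_max >= 0, tumor_cov_min >= 0,
            tumor_vaf_min >= 0)
  bad_tracks <- setdiff(tracks_required, c("tumor_dna", "tumor_rna"))
  if (length(bad_tracks) > 0L) {
    stop(sprintf("unknown required track(s): %s",
                 paste(bad_tracks, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  fail <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(is.na(reason) & cond, code, reason)
  }
  nd <- candidates$normal_dna_depth
  nv <- candidates$normal_dna_vaf
  fail(is.na(nd), "insufficient_data")
  fail(nd <= normal_cov_min, "normal_coverage_low")
  fail(is.na(nv), "insufficient_data")
  fail(nv >= normal_vaf_max, "normal_vaf_high")
  for (track in tracks_required) {
    d <- candidates[[paste0(track, "_depth")]]
    v <- candidates[[paste0(track, "_vaf")]]
    fail(is.na(d) | is.na(v), "insufficient_data")
    fail(d < tumor_cov_min, paste0(track, "_coverage_low"))
    fail(v < tumor_vaf_min, paste0(track, "_vaf_low"))
  }
  keep <- is.na(reason)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_dropped(out, data.frame(variant_id = candidates$variant_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Expression-based candidate filter
#'
#' Retains candidates whose gene (or matched transcript) FPKM is strictly
#' greater than `fpkm_min`. Genes with any expression (FPKM > 0) are
#' nominally expressed; the default threshold of 1 trims low-level noise.
#' Missing FPKM removes the candidate with reason `no_expression_data`.
#'
#' @param candidates Annotated table from [join_coverage_and_expression()].
#' @param fpkm_min Strict lower bound on FPKM (default 1.0).
#' @return The retained subset, with a drop log (see [dropped_records()]).
#' @export
apply_expression_filter <- function(candidates, fpkm_min = 1.0) {
  if (fpkm_min < 0) stop("fpkm_min must be >= 0", call. = FALSE)
  fpkm <- candidates$gene_fpkm
  keep <- !is.na(fpkm) & fpkm > fpkm_min
  reason <- ifelse(is.na(fpkm), "no_expression_data", "fpkm_below_threshold")
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_dropped(out, data.frame(variant_id = candidates$variant_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}
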