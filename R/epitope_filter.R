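# Pair WT with MT predictions, keep localized mutant binders under the
# binding threshold, compute fold change, and pick the best candidate per
# mutation across lengths and alleles.

#' Does a k-mer contain the mutated residue?
#'
#' A peptide is "localized" when the mutated position of its source window
#' falls inside the k-mer. Only localized peptides are candidate neoepitopes;
#' non-localized k-mers of the mutant window are identical to wild-type
#' sequence and carry no tumor specificity.
#'
#' @param start_offset 1-based start of the k-mer within the window.
#' @param k Peptide length.
#' @param mutant_offset 1-based position of the mutation within the window.
#' @return Logical, vectorized over the arguments.
#' @export
is_localized <- function(start_offset, k, mutant_offset) {
  start_offset <= mutant_offset & mutant_offset <= start_offset + k - 1
}

#' Pair wild-type and mutant predictions at identical coordinates
#'
#' Joins WT and MT predictions on `(variant_id, hla_allele, k, start_offset)`
#' so each row carries both affinities, and annotates each row with the
#' mutant offset of its window, localization, and the WT/MT fold change
#' (wild-type IC50 over mutant IC50; values above 1 mean the mutant binds
#' more strongly). An MT row with no WT partner at the same coordinates is
#' kept with a missing WT score and logged — this occurs when the WT window
#' was excluded (e.g. nonstandard residue). WT-only rows pair with nothing:
#' there is no mutant peptide to consider.
#'
#' @param predictions Epitope predictions from [run_predictions()] or
#'   [parse_prediction_output()].
#' @param pairs Peptide-pair table from [build_peptide_pairs()] (supplies
#'   `mutant_offset` and `gene`).
#' @return A data.frame with one row per MT prediction: `variant_id`, `gene`,
#'   `hla_allele`, `k`, `start_offset`, `mt_peptide`, `wt_peptide`,
#'   `mt_ic50_nm`, `wt_ic50_nm`, `mutant_offset`, `localized`, `fold_change`,
#'   `log2_fold_change`.
#' @export
pair_wt_mt <- function(predictions, pairs) {
  coord_cls <- paste(predictions$variant_id, predictions$hla_allele,
                     predictions$k, predictions$start_offset,
                     predictions$allele_class)
  if (anyDuplicated(coord_cls)) {
    stop("duplicate prediction rows at identical coordinates", call. = FALSE)
  }
  mt <- predictions[predictions$allele_class == "MT", , drop = FALSE]
  wt <- predictions[predictions$allele_class == "WT", , drop = FALSE]
  coord <- function(df) paste(df$variant_id, df$hla_allele, df$k,
                              df$start_offset, sep = "\r")
  m <- match(coord(mt), coord(wt))
  out <- data.frame(variant_id = mt$variant_id,
                    gene = pairs$gene[match(mt$variant_id, pairs$variant_id)],
                    hla_allele = mt$hla_allele, k = mt$k,
                    start_offset = mt$start_offset,
                    mt_peptide = mt$peptide,
                    wt_peptide = wt$peptide[m],
                    mt_ic50_nm = mt$ic50_nm,
                    wt_ic50_nm = wt$ic50_nm[m],
                    stringsAsFactors = FALSE)
  out$mutant_offset <- pairs$mutant_offset[match(mt$variant_id, pairs$variant_id)]
  out$localized <- is_localized(out$start_offset, out$k, out$mutant_offset)
  out$fold_change <- out$wt_ic50_nm / out$mt_ic50_nm
  out$log2_fold_change <- log2(out$fold_change)
  n_unpaired <- sum(is.na(m))
  if (n_unpaired > 0L) {
    message(sprintf("pair_wt_mt: %d MT row(s) lack a WT partner", n_unpaired))
  }
  rownames(out) <- NULL
  out
}

#' Binding filter: localized mutant peptides under the IC50 threshold
#'
#' Retains rows whose mutant IC50 is strictly below the threshold (default
#' 500 nM, the conventional strong-to-intermediate binder cutoff) and whose
#' peptide contains the mutated residue. The wild-type score is reported for
#' comparison but never affects retention.
#'
#' @param paired Paired table from [pair_wt_mt()].
#' @param threshold_nm Strict upper bound on mutant IC50 in nM (default 500).
#' @return The retained subset, with a drop log (see [dropped_records()]).
#' @export
apply_binding_filter <- function(paired, threshold_nm = 500) {
  if (threshold_nm <= 0) stop("threshold_nm must be positive", call. = FALSE)
  keep <- !is.na(paired$mt_ic50_nm) & paired$mt_ic50_nm < threshold_nm &
    paired$localized
  reason <- ifelse(!paired$localized, "not localized",
                   ifelse(is.na(paired$mt_ic50_nm), "missing MT score",
                          "MT IC50 above threshold"))
  out <- paired[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_dropped(out, data.frame(variant_id = paired$variant_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Select the best candidate neoepitope per mutation
#'
#' Among all binding-filtered rows of each variant, picks the single row with
#' the lowest mutant IC50 across every tested length and HLA allele. Exact
#' ties are broken deterministically: shorter peptide first, then
#' lexicographically smaller allele, then smaller start offset.
#'
#' @param filtered Table from [apply_binding_filter()] (possibly after
#'   coverage/expression annotation and filtering).
#' @return One row per `variant_id`, sorted by `variant_id`.
#' @export
select_best_candidates <- function(filtered) {
  if (nrow(filtered) == 0L) return(filtered)
  ord <- order(filtered$mt_ic50_nm, filtered$k, filtered$hla_allele,
               filtered$start_offset)
  sorted <- filtered[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$variant_id), , drop = FALSE]
  out <- out[order(out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
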