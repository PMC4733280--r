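# Paired wild-type/mutant peptide windows and the FASTA + key file pair that
# feeds epitope prediction.

#' Build the paired WT/MT peptide window for one mutation
#'
#' Extracts the peptide window of `flank` residues on each side of the mutated
#' position (21-mer for the default flank of 10). When the mutation lies near
#' either end of the protein, the deficient side is compensated by extending
#' the other side, so the window keeps its full length whenever the protein is
#' long enough: with `L = nchar(protein)`, `p = protein_pos`, `f = flank`,
#'
#' \preformatted{
#'   start <- max(1, p - f); end <- min(L, p + f)
#'   if (end - start + 1 < 2*f + 1) {
#'     start <- max(1, end - 2*f); end <- min(L, start + 2*f)
#'   }
#' }
#'
#' A protein shorter than `2*flank + 1` yields the whole protein.
#'
#' @param protein Full wild-type protein sequence (single string).
#' @param protein_pos 1-based position of the mutated residue.
#' @param mt_residue Mutant residue (single letter).
#' @param flank Number of flanking residues on each side (default 10).
#' @return A list with `wt_window`, `mt_window`, `mutant_offset` (1-based
#'   position of the mutation within the window), `window_start` (1-based
#'   protein coordinate of the window's first residue) and `flank`.
#' @examples
#' build_peptide_window(strrep("A", 100), 50, "E", flank = 10)
#' @export
build_peptide_window <- function(protein, protein_pos, mt_residue, flank = 10) {
  L <- nchar(protein)
  p <- as.integer(protein_pos)
  f <- as.integer(flank)
  if (f < 1L) stop("flank must be >= 1", call. = FALSE)
  if (is.na(p) || p < 1L || p > L) {
    stop(sprintf("protein position %s out of range 1..%d", protein_pos, L),
         call. = FALSE)
  }
  start <- max(1L, p - f)
  end <- min(L, p + f)
  if (end - start + 1L < 2L * f + 1L) {
    start <- max(1L, end - 2L * f)
    end <- min(L, start + 2L * f)
  }
  wt <- substr(protein, start, end)
  offset <- p - start + 1L
  mt <- paste0(substr(wt, 1L, offset - 1L), mt_residue,
               substr(wt, offset + 1L, nchar(wt)))
  list(wt_window = wt, mt_window = mt, mutant_offset = offset,
       window_start = start, flank = f)
}

#' Build peptide pairs for a table of variants
#'
#' Applies [build_peptide_window()] to every accepted variant. Windows that
#' overlap a nonstandard residue (`X` unknown, `U` selenocysteine) are
#' excluded with a logged reason rather than scored, since binding predictors
#' do not handle them reliably; see [dropped_records()].
#'
#' @param variants Variant table from [read_annotated_variants()].
#' @param flank Flanking residues on each side of the mutation (default 10).
#' @return A data.frame with one row per retained variant: `variant_id`,
#'   `gene`, `transcript_id`, `wt_window`, `mt_window`, `mutant_offset`,
#'   `window_start`, `flank`.
#' @export
build_peptide_pairs <- function(variants, flank = 10) {
  n <- nrow(variants)
  rows <- vector("list", n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    w <- build_peptide_window(variants$wt_protein_seq[i],
                              variants$protein_pos[i],
                              variants$mt_residue[i], flank)
    if (grepl("[XU]", w$wt_window)) {
      reasons[i] <- "nonstandard residue (X/U) in peptide window"
      next
    }
    rows[[i]] <- data.frame(variant_id = variants$variant_id[i],
                            gene = variants$gene[i],
                            transcript_id = variants$transcript_id[i],
                            wt_window = w$wt_window, mt_window = w$mt_window,
                            mutant_offset = w$mutant_offset,
                            window_start = w$window_start, flank = w$flank,
                            stringsAsFactors = FALSE)
  }
  kept <- !vapply(rows, is.null, logical(1))
  out <- if (any(kept)) do.call(rbind, rows[kept]) else
    .empty_df(c("variant_id", "gene", "transcript_id", "wt_window",
                "mt_window", "mutant_offset", "window_start", "flank"))
  rownames(out) <- NULL
  dropped <- data.frame(variant_id = variants$variant_id[!kept],
                        reason = reasons[!kept], stringsAsFactors = FALSE)
  if (nrow(dropped) > 0L) {
    message(sprintf("build_peptide_pairs: excluded %d window(s)", nrow(dropped)))
  }
  .set_dropped(out, dropped)
}

#' Write the two-records-per-variant FASTA and its key file
#'
#' Emits two FASTA records per variant — wild-type first, then mutant, headers
#' `>{variant_id}.WT` and `>{variant_id}.MT`, wrapped at 60 columns — and a
#' companion key file mapping each record's 0-based index back to its variant
#' and class. Epitope prediction tools strip FASTA headers from their output,
#' so the key file is what re-associates predictions with variants.
#'
#' @param pairs Peptide-pair table from [build_peptide_pairs()].
#' @param fasta_path,key_path Output paths for the FASTA and the key TSV
#'   (columns `record_index`, `header`, `variant_id`, `class`).
#' @return Number of FASTA records written (`2 * nrow(pairs)`), invisibly.
#' @export
write_fasta_and_key <- function(pairs, fasta_path, key_path) {
  if (nrow(pairs) == 0L) stop("no peptide pairs to write", call. = FALSE)
  dup <- unique(pairs$variant_id[duplicated(pairs$variant_id)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate variant_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(pairs)
  seqs <- character(2L * n)
  headers <- character(2L * n)
  seqs[seq(1L, 2L * n, by = 2L)] <- pairs$wt_window
  seqs[seq(2L, 2L * n, by = 2L)] <- pairs$mt_window
  headers[seq(1L, 2L * n, by = 2L)] <- paste0(pairs$variant_id, ".WT")
  headers[seq(2L, 2L * n, by = 2L)] <- paste0(pairs$variant_id, ".MT")
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, fasta_path, width = 60L)
  key <- data.frame(record_index = seq_len(2L * n) - 1L, header = headers,
                    variant_id = rep(pairs$variant_id, each = 2L),
                    class = rep(c("WT", "MT"), n), stringsAsFactors = FALSE)
  utils::write.table(key, key_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(2L * n)
}

#' Read a FASTA/key pair back into peptide pairs
#'
#' Inverse of [write_fasta_and_key()] up to the fields recoverable from the
#' files: the WT/MT windows, their labels, and the mutant offset (recomputed
#' as the single position at which the two windows differ).
#'
#' @param fasta_path,key_path Paths written by [write_fasta_and_key()].
#' @return A data.frame with `variant_id`, `wt_window`, `mt_window`,
#'   `mutant_offset`.
#' @export
read_fasta_and_key <- function(fasta_path, key_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  key <- utils::read.delim(key_path, colClasses = "character",
                           stringsAsFactors = FALSE)
  .assert_columns(key, c("record_index", "header", "variant_id", "class"),
                  "key file")
  key$record_index <- as.integer(key$record_index)
  key <- key[order(key$record_index), , drop = FALSE]
  if (!identical(names(aa), key$header)) {
    stop("key file does not match FASTA record order", call. = FALSE)
  }
  seqs <- as.character(aa)
  wt_idx <- which(key$class == "WT")
  out <- data.frame(variant_id = key$variant_id[wt_idx],
                    wt_window = unname(seqs[wt_idx]),
                    mt_window = unname(seqs[wt_idx + 1L]),
                    stringsAsFactors = FALSE)
  out$mutant_offset <- mapply(function(w, m) {
    d <- which(strsplit(w, "")[[1]] != strsplit(m, "")[[1]])
    if (length(d) != 1L) stop("WT/MT windows do not differ at exactly one position")
    d
  }, out$wt_window, out$mt_window, USE.NAMES = FALSE)
  out
}
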