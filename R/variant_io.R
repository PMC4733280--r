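# Reading, validating and normalizing the annotated missense-variant table
# that seeds the pipeline.

VARIANT_TSV_COLUMNS <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                         "transcript_id", "protein_change", "wt_protein_seq")

#' Parse a protein-change string
#'
#' Normalizes annotator output such as `"p.V600E"` or `"V600E"` into its three
#' components: wild-type residue, 1-based protein position, mutant residue.
#' Only missense changes are supported, so a synonymous string (wild-type
#' equal to mutant, e.g. `"p.A1A"`) is rejected.
#'
#' @param change A single protein-change string matching
#'   `^(p\.)?[A-Z][0-9]+[A-Z]$`.
#' @return A list with elements `wt_residue`, `protein_pos` (integer) and
#'   `mt_residue`.
#' @examples
#' parse_protein_change("p.V600E")
#' parse_protein_change("G12D")
#' @export
parse_protein_change <- function(change) {
  if (length(change) != 1L || !is.character(change) || is.na(change)) {
    stop("protein change must be a single character string", call. = FALSE)
  }
  m <- regmatches(change, regexec("^(p\\.)?([A-Z])([0-9]+)([A-Z])$", change))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed protein change: '%s'", change), call. = FALSE)
  }
  wt <- m[3]
  pos <- suppressWarnings(as.integer(m[4]))
  mt <- m[5]
  if (is.na(pos) || pos < 1L) {
    stop(sprintf("malformed protein change: '%s' (bad position)", change),
         call. = FALSE)
  }
  if (!wt %in% AA_EXTENDED) {
    stop(sprintf("unknown wild-type residue '%s' in '%s'", wt, change),
         call. = FALSE)
  }
  if (!mt %in% AA_STANDARD) {
    stop(sprintf("unknown mutant residue '%s' in '%s'", mt, change),
         call. = FALSE)
  }
  if (wt == mt) {
    stop(sprintf("synonymous change '%s' is not missense", change),
         call. = FALSE)
  }
  list(wt_residue = wt, protein_pos = pos, mt_residue = mt)
}

# Validate one parsed variant row; returns NULL if valid, else a reason string.
.variant_row_problem <- function(row) {
  seq <- row$wt_protein_seq
  if (is.na(seq) || !nzchar(seq)) return("empty protein sequence")
  letters <- strsplit(seq, "")[[1]]
  if (!all(letters %in% AA_EXTENDED)) {
    bad <- unique(setdiff(letters, AA_EXTENDED))
    return(sprintf("non-amino-acid letter(s) in protein sequence: %s",
                   paste(bad, collapse = ",")))
  }
  if (row$protein_pos > nchar(seq)) {
    return(sprintf("protein position %d exceeds protein length %d",
                   row$protein_pos, nchar(seq)))
  }
  observed <- substr(seq, row$protein_pos, row$protein_pos)
  if (observed != row$wt_residue) {
    return(sprintf(
      "residue mismatch: expected '%s' at protein position %d but found '%s'",
      row$wt_residue, row$protein_pos, observed))
  }
  NULL
}

#' Read an annotated missense-variant table
#'
#' Reads the tab-separated variant table that seeds the pipeline. Each row
#' carries genomic coordinates, gene and transcript identifiers, the protein
#' change (e.g. `p.V600E`) and the full wild-type transcript protein sequence
#' — the two components every downstream step depends on. Positions are
#' 1-based, both genomic and protein. Lines starting with `#` are ignored.
#'
#' Every accepted row is checked against the invariants of the variant model:
#' the protein change parses as missense, the stated position lies inside the
#' protein, and the protein carries the stated wild-type residue at that
#' position. In strict mode any invalid row aborts the read; in lenient mode
#' invalid rows are dropped with a per-row reason (see [dropped_records()]).
#' Duplicate `variant_id`s are an error in both modes.
#'
#' @param path Path to a TSV file with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `transcript_id`, `protein_change`,
#'   `wt_protein_seq`.
#' @param strict If `TRUE` (default) any invalid row is an error; if `FALSE`
#'   invalid rows are dropped and logged.
#' @return A data.frame with one row per accepted variant and parsed columns
#'   `wt_residue`, `protein_pos`, `mt_residue` and `variant_type` added.
#' @seealso [write_annotated_variants()] for the inverse operation.
#' @export
read_annotated_variants <- function(path, strict = TRUE) {
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE)
  .assert_columns(raw, VARIANT_TSV_COLUMNS, "annotated variant table")
  raw <- raw[, VARIANT_TSV_COLUMNS, drop = FALSE]
  dup <- unique(raw$variant_id[duplicated(raw$variant_id)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate variant_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  raw$pos <- suppressWarnings(as.integer(raw$pos))

  keep <- logical(nrow(raw))
  reasons <- character(nrow(raw))
  parsed <- data.frame(wt_residue = character(nrow(raw)),
                       protein_pos = integer(nrow(raw)),
                       mt_residue = character(nrow(raw)),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(raw))) {
    pc <- tryCatch(parse_protein_change(raw$protein_change[i]),
                   error = function(e) conditionMessage(e))
    if (is.character(pc)) {
      reasons[i] <- pc
      next
    }
    parsed$wt_residue[i] <- pc$wt_residue
    parsed$protein_pos[i] <- pc$protein_pos
    parsed$mt_residue[i] <- pc$mt_residue
    row <- c(raw[i, , drop = FALSE], pc)
    problem <- .variant_row_problem(row)
    if (!is.null(problem)) {
      reasons[i] <- problem
      next
    }
    keep[i] <- TRUE
  }

  if (strict && any(!keep)) {
    bad <- which(!keep)[1]
    stop(sprintf("invalid variant '%s': %s", raw$variant_id[bad], reasons[bad]),
         call. = FALSE)
  }

  out <- cbind(raw[keep, , drop = FALSE], parsed[keep, , drop = FALSE])
  out$variant_type <- rep("missense", nrow(out))
  rownames(out) <- NULL
  dropped <- data.frame(variant_id = raw$variant_id[!keep],
                        reason = reasons[!keep], stringsAsFactors = FALSE)
  if (nrow(dropped) > 0L) {
    message(sprintf("read_annotated_variants: dropped %d invalid row(s)",
                    nrow(dropped)))
  }
  .set_dropped(out, dropped)
}

#' Write an annotated variant table back to TSV
#'
#' Writes the nine interface columns in their documented order, so that
#' writing and re-reading a variant table is a lossless round trip.
#'
#' @param variants A variant data.frame as returned by
#'   [read_annotated_variants()] (or built by [generate_variants()]).
#' @param path Output file path.
#' @return The number of rows written, invisibly.
#' @export
write_annotated_variants <- function(variants, path) {
  .assert_columns(variants, VARIANT_TSV_COLUMNS, "variant table")
  utils::write.table(variants[, VARIANT_TSV_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(variants))
}
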