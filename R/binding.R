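# Candidate k-mer enumeration and IC50 binding affinities per HLA allele,
# via a pluggable predictor: the deterministic built-in mock predictor or a
# parser for external prediction output files.

# Allele-specific class I predictors score only a finite allele panel; this
# default allow-list covers the common A/B/C alleles used throughout the
# package's examples and tests. Users can pass their own, or NULL to skip
# validation.
DEFAULT_HLA_ALLOWLIST <- c(
  "HLA-A01:01", "HLA-A02:01", "HLA-A02:06", "HLA-A03:01", "HLA-A11:01",
  "HLA-A23:01", "HLA-A24:02", "HLA-A26:01", "HLA-A29:02", "HLA-A31:01",
  "HLA-A32:01", "HLA-A33:01", "HLA-A68:01", "HLA-A68:02",
  "HLA-B07:02", "HLA-B08:01", "HLA-B14:02", "HLA-B15:01", "HLA-B18:01",
  "HLA-B27:05", "HLA-B35:01", "HLA-B38:01", "HLA-B40:01", "HLA-B44:02",
  "HLA-B44:03", "HLA-B51:01", "HLA-B53:01", "HLA-B57:01", "HLA-B58:01",
  "HLA-C03:04", "HLA-C04:01", "HLA-C05:01", "HLA-C06:02", "HLA-C07:01",
  "HLA-C07:02", "HLA-C08:02")

#' Normalize an HLA class I allele name
#'
#' Accepts the common spellings `"HLA-A02:01"`, `"HLA-A*02:01"` and `"A0201"`
#' and canonicalizes them to the `"HLA-A02:01"` form.
#'
#' @param allele Character vector of allele names.
#' @return Canonical allele names.
#' @examples
#' normalize_hla_allele(c("HLA-A*02:01", "A0201", "HLA-B07:02"))
#' @export
normalize_hla_allele <- function(allele) {
  vapply(allele, function(a) {
    m <- regmatches(a, regexec(
      "^(HLA-)?([A-C])\\*?([0-9]{2,3}):?([0-9]{2,3})$", a))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("unrecognized HLA allele name: '%s'", a), call. = FALSE)
    }
    sprintf("HLA-%s%s:%s", m[3], m[4], m[5])
  }, character(1), USE.NAMES = FALSE)
}

.validate_alleles <- function(alleles, allowlist = DEFAULT_HLA_ALLOWLIST) {
  if (length(alleles) == 0L) stop("at least one HLA allele is required",
                                  call. = FALSE)
  alleles <- normalize_hla_allele(alleles)
  if (!is.null(allowlist)) {
    bad <- setdiff(alleles, allowlist)
    if (length(bad) > 0L) {
      stop(sprintf("unsupported HLA allele(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  alleles
}

#' Enumerate all k-mers of a peptide window
#'
#' @param window Amino-acid string.
#' @param k Peptide length (class I epitopes are typically 8--11).
#' @return A data.frame with `start_offset` (1-based within the window) and
#'   `peptide`, in ascending start order; zero rows when the window is shorter
#'   than `k`.
#' @examples
#' nrow(enumerate_kmers(strrep("A", 21), 9))  # 13
#' @export
enumerate_kmers <- function(window, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nchar(window) - k + 1L
  if (n < 1L) {
    return(data.frame(start_offset = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(n)
  data.frame(start_offset = starts,
             peptide = substring(window, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Deterministic mock IC50 prediction
#'
#' A stand-in for an external MHC class I binding predictor, used to make the
#' whole pipeline testable without a licensed tool. The IC50 is a keyed hash
#' of `(peptide, allele, seed)` mapped onto a log-uniform range of 1--50000 nM:
#' identical inputs always give the identical affinity, different alleles
#' generally give different affinities, and over random peptides the fraction
#' below any threshold t equals `log(t)/log(50000)` (about 0.574 for the
#' conventional 500 nM binder threshold). It encodes no binding biology.
#'
#' @param peptide Character vector of peptides (standard residues only).
#' @param allele HLA allele name(s), recycled against `peptide`.
#' @param seed Integer key mixed into the hash (default 0).
#' @return Numeric vector of IC50 values in nM, in `[1, 50000]`.
#' @seealso [mock_predictor()] for the closure form used by
#'   [run_predictions()].
#' @export
mock_predict <- function(peptide, allele, seed = 0) {
  if (length(peptide) == 0L) return(numeric(0))
  if (any(!nzchar(peptide))) stop("empty peptide", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), peptide)
  if (any(bad)) {
    stop(sprintf("nonstandard residue in peptide(s): %s",
                 paste(unique(peptide[bad]), collapse = ", ")), call. = FALSE)
  }
  allele <- normalize_hla_allele(allele)
  u <- .hash_unit(paste(peptide, allele, seed, sep = "|"))
  50000 ^ u
}

#' Mock predictor as a plug-in
#'
#' Wraps [mock_predict()] with a fixed seed into the predictor interface
#' consumed by [run_predictions()]: a function of `(peptide, allele)`
#' returning IC50 nM.
#'
#' @param seed Integer hash key.
#' @return A `function(peptide, allele)`.
#' @export
mock_predictor <- function(seed = 0) {
  force(seed)
  function(peptide, allele) mock_predict(peptide, allele, seed = seed)
}

#' Run binding predictions over all windows, alleles and lengths
#'
#' For every peptide pair, class (WT/MT), HLA allele and epitope length,
#' enumerates all k-mers of the corresponding window and scores them with the
#' supplied predictor. The output has exactly one row per
#' `(variant, class, allele, length, k-mer)` combination, i.e.
#' `sum over pairs, lengths of 2 * n_alleles * max(0, window_len - k + 1)`
#' rows. A predictor failure flags the affected rows (`ic50_nm = NA`) and
#' logs them rather than dropping them silently.
#'
#' @param pairs Peptide-pair table from [build_peptide_pairs()].
#' @param alleles Character vector of HLA class I alleles (non-empty).
#' @param lengths Integer vector of epitope lengths; the default 8--11 covers
#'   the lengths class I molecules typically present.
#' @param predictor A `function(peptide, allele) -> IC50 nM`, e.g.
#'   [mock_predictor()].
#' @param allowlist Allele allow-list for validation (`NULL` to skip).
#' @return A data.frame of epitope predictions: `variant_id`, `allele_class`,
#'   `hla_allele`, `k`, `start_offset`, `peptide`, `ic50_nm`.
#' @export
run_predictions <- function(pairs, alleles, lengths = 8:11,
                            predictor = mock_predictor(),
                            allowlist = DEFAULT_HLA_ALLOWLIST) {
  alleles <- .validate_alleles(alleles, allowlist)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L)) stop("epitope lengths must be positive", call. = FALSE)
  blocks <- vector("list", 2L * nrow(pairs) * length(lengths))
  bi <- 0L
  for (i in seq_len(nrow(pairs))) {
    for (cls in c("WT", "MT")) {
      window <- if (cls == "WT") pairs$wt_window[i] else pairs$mt_window[i]
      for (k in lengths) {
        km <- enumerate_kmers(window, k)
        if (nrow(km) == 0L) next
        bi <- bi + 1L
        blocks[[bi]] <- data.frame(
          variant_id = pairs$variant_id[i], allele_class = cls,
          k = k, start_offset = km$start_offset, peptide = km$peptide,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (bi == 0L) {
    return(data.frame(variant_id = character(0), allele_class = character(0),
                      hla_allele = character(0), k = integer(0),
                      start_offset = integer(0), peptide = character(0),
                      ic50_nm = numeric(0), stringsAsFactors = FALSE))
  }
  base <- do.call(rbind, blocks[seq_len(bi)])
  out <- do.call(rbind, lapply(alleles, function(a) {
    df <- base
    df$hla_allele <- a
    df
  }))
  out$ic50_nm <- tryCatch(
    predictor(out$peptide, out$hla_allele),
    error = function(e) {
      # retry element-wise so one bad peptide flags only its own rows
      vapply(seq_len(nrow(out)), function(j) {
        tryCatch(predictor(out$peptide[j], out$hla_allele[j]),
                 error = function(e2) NA_real_)
      }, numeric(1))
    })
  n_failed <- sum(is.na(out$ic50_nm))
  if (n_failed > 0L) {
    message(sprintf("run_predictions: predictor failed on %d row(s); flagged NA",
                    n_failed))
  }
  out <- out[, c("variant_id", "allele_class", "hla_allele", "k",
                 "start_offset", "peptide", "ic50_nm")]
  rownames(out) <- NULL
  out
}

PREDICTION_TSV_COLUMNS <- c("record_index", "start_offset", "peptide",
                            "allele", "ic50_nm")

#' Write predictions in the prediction-file dialect
#'
#' Serializes an epitope-prediction table to the tab-separated dialect used
#' for external predictor output (`record_index`, `start_offset`, `peptide`,
#' `allele`, `ic50_nm`), with record indices taken from a FASTA key file so
#' that [parse_prediction_output()] can re-associate each row.
#'
#' @param predictions Table from [run_predictions()].
#' @param key Key data.frame (or path to a key TSV) from
#'   [write_fasta_and_key()].
#' @param path Output TSV path.
#' @return Number of rows written, invisibly.
#' @export
write_predictions <- function(predictions, key, path) {
  if (is.character(key)) {
    key <- utils::read.delim(key, stringsAsFactors = FALSE)
  }
  .assert_columns(key, c("record_index", "variant_id", "class"), "key file")
  idx <- match(paste(predictions$variant_id, predictions$allele_class),
               paste(key$variant_id, key$class))
  if (anyNA(idx)) {
    stop("prediction rows reference records absent from the key file",
         call. = FALSE)
  }
  out <- data.frame(record_index = key$record_index[idx],
                    start_offset = predictions$start_offset,
                    peptide = predictions$peptide,
                    allele = predictions$hla_allele,
                    ic50_nm = predictions$ic50_nm, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(out))
}

#' Parse a prediction output file against its key file
#'
#' Reads an external prediction file in the documented tab-separated dialect
#' and re-associates every row with its variant and WT/MT class through the
#' key file written alongside the FASTA (prediction tools strip FASTA
#' headers, so the record order is the only link back to the variants).
#'
#' @param pred_path Prediction TSV with columns `record_index`,
#'   `start_offset`, `peptide`, `allele`, `ic50_nm`.
#' @param key_path Key TSV from [write_fasta_and_key()].
#' @return An epitope-prediction data.frame in the same shape as
#'   [run_predictions()] output.
#' @export
parse_prediction_output <- function(pred_path, key_path) {
  pred <- utils::read.delim(pred_path, stringsAsFactors = FALSE)
  .assert_columns(pred, PREDICTION_TSV_COLUMNS, "prediction file")
  key <- utils::read.delim(key_path, stringsAsFactors = FALSE)
  .assert_columns(key, c("record_index", "variant_id", "class"), "key file")
  if (nrow(pred) == 0L) {
    return(data.frame(variant_id = character(0), allele_class = character(0),
                      hla_allele = character(0), k = integer(0),
                      start_offset = integer(0), peptide = character(0),
                      ic50_nm = numeric(0), stringsAsFactors = FALSE))
  }
  pred$record_index <- as.integer(pred$record_index)
  pred$start_offset <- as.integer(pred$start_offset)
  pred$ic50_nm <- as.numeric(pred$ic50_nm)
  if (anyNA(pred$record_index) || anyNA(pred$start_offset)) {
    bad <- which(is.na(pred$record_index) | is.na(pred$start_offset))[1]
    stop(sprintf("malformed prediction row at line %d", bad + 1L),
         call. = FALSE)
  }
  idx <- match(pred$record_index, key$record_index)
  if (anyNA(idx)) {
    missing <- unique(pred$record_index[is.na(idx)])
    stop(sprintf("record index(es) not present in key file: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(variant_id = key$variant_id[idx],
                    allele_class = key$class[idx],
                    hla_allele = normalize_hla_allele(pred$allele),
                    k = nchar(pred$peptide),
                    start_offset = pred$start_offset,
                    peptide = pred$peptide,
                    ic50_nm = pred$ic50_nm, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
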