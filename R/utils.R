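# Internal helpers shared across modules.

# The 20 standard amino acids; 'X' (unknown) and 'U' (selenocysteine) are
# tolerated in full protein sequences but never inside peptide windows.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTENDED <- c(AA_STANDARD, "X", "U")

# Polynomial string hash mod 2^31-1 with a final Lehmer mixing step.
# All arithmetic stays below 2^53 so the result is exact in doubles.
.hash_string <- function(x) {
  mod <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% mod
    h <- (h * 48271 + 1) %% mod
    (h * 48271) %% mod
  }, numeric(1), USE.NAMES = FALSE)
}

# Map a string key to (0, 1); used by the mock predictor.
.hash_unit <- function(x) .hash_string(x) / 2147483647

# Derive a stream-specific 32-bit seed from a global seed and a label so the
# fixture generators are independently reproducible.
derive_seed <- function(seed, label) {
  as.integer(.hash_string(paste0(label, ":", seed)) %% 2147483562)
}

.assert_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Attach (or extend) a data.frame of dropped records with reasons, so every
# filtering step leaves an auditable trail.
.set_dropped <- function(df, dropped) {
  if (is.null(dropped)) {
    dropped <- data.frame(variant_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  attr(df, "dropped") <- dropped
  df
}

#' Retrieve the drop log attached to a filtered table
#'
#' Filtering and loading functions in this package never discard records
#' silently: each removed record is recorded once with a machine-readable
#' reason code in a `dropped` attribute on the returned table.
#'
#' @param x A table returned by one of the reading or filtering functions.
#' @return A data.frame with columns `variant_id` and `reason` (zero rows if
#'   nothing was dropped).
#' @export
dropped_records <- function(x) {
  d <- attr(x, "dropped")
  if (is.null(d)) {
    d <- data.frame(variant_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  }
  d
}

.empty_df <- function(cols) {
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}
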