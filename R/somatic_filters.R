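# Rule-based somatic variant filters: three auditable rule sets evaluated
# over per-site read metrics, independent of any aligner or caller binary.
# Boundary semantics follow each printed inequality exactly.

SITE_METRICS_FIELDS <- list(
  snp = c("distance_to_nearest_indel_bp", "nearest_indel_quality",
          "max_mapping_quality", "snv_calls_in_10bp_window", "site_depth",
          "consensus_quality", "snp_quality"),
  false_positive = c("var_strand_fraction_fwd", "var_strand_fraction_rev",
                     "tumor_vaf", "var_read_count", "avg_rel_read_position",
                     "mismatch_qualsum_diff", "mapping_quality_diff",
                     "avg_supporting_read_length_diff",
                     "avg_rel_distance_to_3prime",
                     "homopolymer_adjacent_length"),
  varscan = c("varscan_p_value", "normal_vaf", "tumor_vaf", "var_read_count"))

.metrics_df <- function(m) {
  if (is.data.frame(m)) return(m)
  as.data.frame(m, stringsAsFactors = FALSE)
}

.check_fields <- function(m, fields, ruleset) {
  for (f in fields) {
    if (is.null(m[[f]]) || anyNA(m[[f]])) {
      stop(sprintf("missing metric '%s' required by the %s filter", f, ruleset),
           call. = FALSE)
    }
  }
}

# Each .rules_* returns a logical matrix (rows = sites, cols = rule codes),
# TRUE where the rule is VIOLATED.
.rules_snp <- function(m) {
  cbind(
    # (a) within 10 bp of a predicted indel of quality >= 50
    a = m$distance_to_nearest_indel_bp <= 10 & m$nearest_indel_quality >= 50,
    # (b) maximum mapping quality at the site below 40
    b = m$max_mapping_quality < 40,
    # (c) three or more SNV calls in a 10 bp window around the site
    c = m$snv_calls_in_10bp_window >= 3,
    # (d) fewer than three reads, or an absurdly high 1e9+ reads
    d = m$site_depth < 3 | m$site_depth >= 1e9,
    # (e) consensus or SNP quality below 20
    e = m$consensus_quality < 20 | m$snp_quality < 20)
}

.rules_false_positive <- function(m) {
  cbind(
    # (a) each strand must contribute >= 1% of variant-supporting reads
    a = m$var_strand_fraction_fwd < 0.01 | m$var_strand_fraction_rev < 0.01,
    # (b) VAF must be >= 5%
    b = m$tumor_vaf < 0.05,
    # (c) more than four reads must support the variant
    c = m$var_read_count <= 4,
    # (d) average relative read position must exceed 0.1
    d = m$avg_rel_read_position <= 0.1,
    # (e) variant-vs-reference mismatch quality sum difference must be < 50
    e = m$mismatch_qualsum_diff >= 50,
    # (f) variant-vs-reference mapping quality difference must be < 30
    f = m$mapping_quality_diff >= 30,
    # (g) variant-vs-reference supporting read length difference must be < 25
    g = m$avg_supporting_read_length_diff >= 25,
    # (h) average relative distance to the effective 3' end must be >= 0.2
    h = m$avg_rel_distance_to_3prime < 0.2,
    # (i) not adjacent to a homopolymer run of five or more bases
    i = m$homopolymer_adjacent_length >= 5)
}

# These four are REMOVAL conditions (the rule set lists what to filter out);
# a site passes only when none of them fires.
.rules_varscan <- function(m) {
  cbind(
    a = m$varscan_p_value > 0.07,   # caller p value too weak
    b = m$normal_vaf > 0.05,        # variant present in the normal
    c = m$tumor_vaf < 0.10,         # tumor support too low
    d = m$var_read_count < 2)       # fewer than two supporting reads
}

.verdict <- function(viol) {
  list(pass = !any(viol), violated = colnames(viol)[viol[1, ]])
}

#' SNP filter (five read-pileup rules)
#'
#' A site passes when all five rules hold: (a) more than 10 bp from any
#' predicted indel of quality 50 or greater; (b) maximum mapping quality at
#' the site at least 40; (c) fewer than three SNV calls in a 10 bp window
#' around the site; (d) covered by at least three and fewer than 1e9 reads;
#' (e) consensus and SNP quality both at least 20.
#'
#' @param m A named list or one-row data.frame of site metrics (see the
#'   package's metrics TSV columns).
#' @return A list with `pass` (logical) and `violated` (character vector of
#'   rule codes `a`--`e` that failed).
#' @seealso [somatic_filter_verdicts()] for the vectorized table form.
#' @export
snp_filter_v1 <- function(m) {
  m <- .metrics_df(m)
  .check_fields(m, SITE_METRICS_FIELDS$snp, "snp")
  .verdict(.rules_snp(m[1, , drop = FALSE]))
}

#' False-positive filter (nine read-evidence rules)
#'
#' A variant passes when all nine rules hold: (a) at least 1% of variant
#' support on each strand; (b) VAF at least 5%; (c) more than four supporting
#' reads; (d) average relative position within reads greater than 0.1;
#' (e) mismatch quality sum difference below 50; (f) mapping quality
#' difference below 30; (g) supporting read length difference below 25;
#' (h) average relative distance to the effective 3' end at least 0.2;
#' (i) not adjacent to a homopolymer of five or more identical bases.
#'
#' @inheritParams snp_filter_v1
#' @return A list with `pass` and `violated` (codes `a`--`i`).
#' @export
false_positive_filter_v1 <- function(m) {
  m <- .metrics_df(m)
  .check_fields(m, SITE_METRICS_FIELDS$false_positive, "false_positive")
  .verdict(.rules_false_positive(m[1, , drop = FALSE]))
}

#' High-confidence filter for caller output (four removal rules)
#'
#' Unlike the other two rule sets, these four conditions describe what is
#' removed: (a) caller p value greater than 0.07; (b) normal VAF greater than
#' 5%; (c) tumor VAF less than 10%; (d) fewer than two supporting reads. A
#' variant passes only when none fires, and `violated` lists the removal
#' conditions that did.
#'
#' @inheritParams snp_filter_v1
#' @return A list with `pass` and `violated` (codes `a`--`d`).
#' @export
varscan_high_confidence_v1 <- function(m) {
  m <- .metrics_df(m)
  .check_fields(m, SITE_METRICS_FIELDS$varscan, "varscan")
  .verdict(.rules_varscan(m[1, , drop = FALSE]))
}

#' Evaluate a somatic filter over a metrics table
#'
#' Vectorized form of the three rule-set filters: appends a `pass` flag and a
#' semicolon-joined `violated` column to a per-variant metrics table.
#'
#' @param metrics Data.frame with one row per variant and the metric columns
#'   the chosen rule set requires.
#' @param ruleset One of `"snp"`, `"false_positive"`, `"varscan"`.
#' @return `metrics` with `pass` and `violated` columns appended.
#' @export
somatic_filter_verdicts <- function(metrics,
                                    ruleset = c("snp", "false_positive",
                                                "varscan")) {
  ruleset <- match.arg(ruleset)
  .check_fields(metrics, SITE_METRICS_FIELDS[[ruleset]], ruleset)
  viol <- switch(ruleset,
                 snp = .rules_snp(metrics),
                 false_positive = .rules_false_positive(metrics),
                 varscan = .rules_varscan(metrics))
  metrics$pass <- !apply(viol, 1L, any)
  metrics$violated <- apply(viol, 1L, function(v)
    paste(colnames(viol)[v], collapse = ";"))
  metrics
}
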