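# Small fully-enumerated prediction fixtures for the pairing/filtering stage.
make_paired_fixture <- function(alleles = "HLA-A02:01", lengths = 9,
                                seed = 1) {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  pairs <- build_peptide_pairs(v)
  preds <- run_predictions(pairs, alleles, lengths, mock_predictor(seed))
  list(pairs = pairs, preds = preds,
       paired = pair_wt_mt(preds, pairs))
}

test_that("localization is an inclusive interval test", {
  expect_true(is_localized(3, 9, 11))    # 3..11 contains 11
  expect_false(is_localized(2, 9, 11))   # 2..10 stops short
  expect_true(is_localized(11, 9, 11))   # mutation at the first position
  expect_false(is_localized(12, 9, 11))
})

test_that("WT and MT predictions pair one-to-one at identical coordinates", {
  fx <- make_paired_fixture()
  # v1 and v2 have 21-mer windows (13 9-mers); v3's protein gives shorter ones
  p1 <- fx$paired[fx$paired$variant_id == "v1", ]
  expect_equal(nrow(p1), 13L)
  expect_false(anyNA(p1$wt_ic50_nm))
  expect_equal(p1$fold_change, p1$wt_ic50_nm / p1$mt_ic50_nm)
  expect_equal(p1$log2_fold_change, log2(p1$fold_change))
  # WT and MT peptides are aligned to the same window coordinates
  expect_equal(nchar(p1$wt_peptide), nchar(p1$mt_peptide))

  # WT-only rows pair with nothing
  wt_only <- fx$preds[fx$preds$allele_class == "WT", ]
  expect_equal(nrow(pair_wt_mt(wt_only, fx$pairs)), 0L)

  # an MT row lacking its WT partner is kept with a missing WT score
  holed <- fx$preds[!(fx$preds$allele_class == "WT" &
                        fx$preds$variant_id == "v1" &
                        fx$preds$start_offset == 5L), ]
  paired <- suppressMessages(pair_wt_mt(holed, fx$pairs))
  gap <- paired[paired$variant_id == "v1" & paired$start_offset == 5L, ]
  expect_true(is.na(gap$wt_ic50_nm))
  expect_true(is.na(gap$fold_change))

  expect_error(pair_wt_mt(rbind(fx$preds, fx$preds[1, ]), fx$pairs),
               "duplicate")
})

test_that("the binding filter is strict at the threshold and requires localization", {
  base <- data.frame(variant_id = "v", gene = "g", hla_allele = "HLA-A02:01",
                     k = 9L, start_offset = c(5L, 6L, 1L, 7L),
                     mt_peptide = "ACDEFGHIK", wt_peptide = "ACDEFGHIR",
                     mt_ic50_nm = c(499.9, 500.0, 10, NA),
                     wt_ic50_nm = 1000, mutant_offset = 11L,
                     stringsAsFactors = FALSE)
  base$localized <- is_localized(base$start_offset, base$k, base$mutant_offset)
  base$fold_change <- base$wt_ic50_nm / base$mt_ic50_nm
  base$log2_fold_change <- log2(base$fold_change)
  kept <- apply_binding_filter(base, 500)
  expect_equal(kept$start_offset, 5L)          # 499.9 nM, localized
  d <- dropped_records(kept)
  expect_setequal(d$reason, c("MT IC50 above threshold", "not localized",
                              "missing MT score"))
  expect_error(apply_binding_filter(base, 0), "positive")
})

test_that("best-candidate selection takes the global minimum across alleles and lengths", {
  rows <- data.frame(variant_id = "v", gene = "g",
                     hla_allele = c("HLA-A02:01", "HLA-A02:01", "HLA-B07:02"),
                     k = 9L, start_offset = 1:3,
                     mt_peptide = "P", wt_peptide = "Q",
                     mt_ic50_nm = c(320, 45, 210), wt_ic50_nm = 500,
                     stringsAsFactors = FALSE)
  expect_equal(select_best_candidates(rows)$mt_ic50_nm, 45)

  rows$mt_ic50_nm <- c(120, 130, 80)  # other allele wins
  expect_equal(select_best_candidates(rows)$hla_allele, "HLA-B07:02")

  # documented deterministic tie-breaks
  tie <- data.frame(variant_id = "v", gene = "g",
                    hla_allele = c("HLA-B07:02", "HLA-A02:01", "HLA-A02:01"),
                    k = c(9L, 10L, 9L), start_offset = c(2L, 1L, 5L),
                    mt_peptide = "P", wt_peptide = "Q",
                    mt_ic50_nm = 100, wt_ic50_nm = 500,
                    stringsAsFactors = FALSE)
  best <- select_best_candidates(tie)
  expect_equal(best$k, 9L)                      # shorter k first
  expect_equal(best$hla_allele, "HLA-A02:01")   # then allele order
  expect_equal(best$start_offset, 5L)
})

test_that("candidate counts are monotone in the binding threshold", {
  fx <- make_paired_fixture(alleles = c("HLA-A02:01", "HLA-B07:02"),
                            lengths = 8:11)
  thresholds <- c(50, 150, 500, 1500, 5000, 50000)
  counts <- vapply(thresholds, function(t) {
    nrow(select_best_candidates(apply_binding_filter(fx$paired, t)))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a 21-mer window with a central mutation has exactly 9 localized 9-mers", {
  fx <- make_paired_fixture()
  p1 <- fx$paired[fx$paired$variant_id == "v1", ]  # central mutation
  expect_equal(p1$mutant_offset[1], 11L)
  expect_equal(sum(p1$localized), 9L)
})
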