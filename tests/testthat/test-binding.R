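test_that("k-mer enumeration matches the sliding-window oracle", {
  expect_equal(nrow(enumerate_kmers(rand_protein(21), 9)), 13L)
  w <- rand_protein(21)
  expect_equal(enumerate_kmers(w, 21)$peptide, w)
  expect_equal(nrow(enumerate_kmers(rand_protein(8), 9)), 0L)
  expect_error(enumerate_kmers(w, 0), "k must be")

  set.seed(7)
  for (L in 1:30) {
    w <- rand_protein(L)
    for (k in 1:12) {
      km <- enumerate_kmers(w, k)
      expect_identical(km$peptide, oracle_kmers(w, k))
      expect_equal(km$start_offset, seq_len(max(0L, L - k + 1L)))
    }
  }
})

test_that("the mock predictor is deterministic, keyed, bounded and log-uniform", {
  expect_identical(mock_predict("SIINFEKL", "HLA-A02:01", 42),
                   mock_predict("SIINFEKL", "HLA-A02:01", 42))
  # golden value pinned at first implementation
  expect_equal(mock_predict("SIINFEKL", "HLA-A02:01", 42), 3135.27839334511,
               tolerance = 1e-12)
  # different allele or seed generally shifts the value
  expect_false(mock_predict("SIINFEKL", "HLA-A02:01", 42) ==
                 mock_predict("SIINFEKL", "HLA-B07:02", 42))
  expect_false(mock_predict("SIINFEKL", "HLA-A02:01", 42) ==
                 mock_predict("SIINFEKL", "HLA-A02:01", 43))
  expect_error(mock_predict("SIINFEKZ", "HLA-A02:01"), "nonstandard residue")
  expect_error(mock_predict("", "HLA-A02:01"), "empty")

  set.seed(3)
  peps <- vapply(1:10000, function(i)
    paste(sample(AA20, 9, replace = TRUE), collapse = ""), character(1))
  ic <- mock_predict(peps, "HLA-A02:01", 1)
  expect_true(all(ic >= 1 & ic <= 50000))
  # share below 500 nM implied by log-uniformity on [1, 50000]
  expect_lt(abs(mean(ic < 500) - log(500) / log(50000)), 0.03)
})

test_that("HLA allele names normalize and unsupported alleles fail fast", {
  expect_equal(normalize_hla_allele(c("HLA-A02:01", "HLA-A*02:01", "A0201")),
               rep("HLA-A02:01", 3))
  expect_equal(normalize_hla_allele("B0702"), "HLA-B07:02")
  expect_error(normalize_hla_allele("HLA-DRB1*01:01"), "unrecognized")
  expect_error(run_predictions(data.frame(), c("HLA-A99:99")),
               "unsupported HLA allele")
})

test_that("prediction row counts follow the closed-form formula", {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  pairs <- build_peptide_pairs(v[1, , drop = FALSE])
  p1 <- run_predictions(pairs, "HLA-A02:01", lengths = 9)
  expect_equal(nrow(p1), 26L)  # 13 WT + 13 MT
  expect_equal(as.vector(table(p1$allele_class)), c(13L, 13L))

  p2 <- run_predictions(pairs, c("HLA-A02:01", "HLA-B07:02"),
                        lengths = c(9, 10))
  expect_equal(nrow(p2), 2L * 2L * (13L + 12L))
  expect_error(run_predictions(pairs, character(0)), "at least one")

  # randomized window lengths against the count formula
  set.seed(5)
  for (i in 1:20) {
    L <- sample(5:30, 1)
    wt <- rand_protein(L)
    off <- sample(L, 1)
    mt <- wt
    substr(mt, off, off) <- sample(setdiff(AA20, substr(wt, off, off)), 1)
    pr <- data.frame(variant_id = "x", gene = "g", transcript_id = "t",
                     wt_window = wt, mt_window = mt, mutant_offset = off,
                     window_start = 1L, flank = 10L, stringsAsFactors = FALSE)
    lens <- sample(8:11, sample(1:4, 1))
    na <- sample(1:3, 1)
    alleles <- c("HLA-A02:01", "HLA-B07:02", "HLA-C07:01")[seq_len(na)]
    got <- nrow(run_predictions(pr, alleles, lens))
    expect_equal(got, sum(2L * na * pmax(0L, L - unique(lens) + 1L)))
  }
})

test_that("every prediction row quotes a true substring of its window", {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  pairs <- build_peptide_pairs(v)
  preds <- run_predictions(pairs, "HLA-A02:01", lengths = 8:11)
  win <- ifelse(preds$allele_class == "WT",
                pairs$wt_window[match(preds$variant_id, pairs$variant_id)],
                pairs$mt_window[match(preds$variant_id, pairs$variant_id)])
  expect_identical(preds$peptide,
                   substring(win, preds$start_offset,
                             preds$start_offset + preds$k - 1L))
})

test_that("the prediction-file dialect round-trips through its parser", {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  pairs <- build_peptide_pairs(v)
  fa <- tempfile(); key <- tempfile()
  write_fasta_and_key(pairs, fa, key)
  preds <- run_predictions(pairs, c("HLA-A02:01", "HLA-B07:02"), lengths = 9)
  pfile <- tempfile(fileext = ".tsv")
  write_predictions(preds, key, pfile)
  back <- parse_prediction_output(pfile, key)
  ord <- function(df) {
    df <- df[do.call(order, df[c("variant_id", "allele_class", "hla_allele",
                                 "k", "start_offset")]), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(back), ord(preds))
})

test_that("the parser rejects unknown record indices and accepts empty files", {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  pairs <- build_peptide_pairs(v)
  fa <- tempfile(); key <- tempfile()
  write_fasta_and_key(pairs, fa, key)
  pfile <- tempfile(fileext = ".tsv")
  writeLines(c("record_index\tstart_offset\tpeptide\tallele\tic50_nm",
               "99\t1\tACDEFGHIK\tHLA-A02:01\t100"), pfile)
  expect_error(parse_prediction_output(pfile, key), "99")
  writeLines("record_index\tstart_offset\tpeptide\tallele\tic50_nm", pfile)
  expect_equal(nrow(parse_prediction_output(pfile, key)), 0L)
})
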