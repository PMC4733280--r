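test_that("VAF is the variant fraction, missing at zero depth", {
  expect_equal(compute_vaf(0, 50), 0)
  expect_equal(compute_vaf(20, 50), 0.40)
  expect_true(is.na(compute_vaf(0, 0)))
  expect_error(compute_vaf(7, 0), "exceeds")
  expect_error(compute_vaf(-1, 10), "non-negative")
  expect_equal(compute_vaf(c(12, 0), c(30, 0)), c(0.4, NA))
})

make_joined <- function() {
  v <- read_annotated_variants(write_variant_tsv(tiny_variants()))
  cand <- data.frame(variant_id = c("v1", "v2", "v3"),
                     mt_ic50_nm = c(100, 200, 300), stringsAsFactors = FALSE)
  coverage <- data.frame(
    chrom = c("chr7", "chr7", "chr7", "chr12", "chr12"),
    pos = c(140453136L, 140453136L, 140453136L, 25398284L, 25398284L),
    track = c("normal_dna", "tumor_dna", "tumor_rna", "normal_dna",
              "tumor_dna"),
    ref_count = c(30L, 18L, 20L, 25L, 40L),
    var_count = c(0L, 12L, 15L, 0L, 0L),
    total_depth = c(30L, 30L, 35L, 25L, 40L), stringsAsFactors = FALSE)
  expression <- data.frame(gene = c("BRAF", "BRAF", "KRAS"),
                           transcript_id = c("", "T1", ""),
                           fpkm = c(9.9, 5.5, 2.2), stringsAsFactors = FALSE)
  join_coverage_and_expression(cand, coverage, expression, v)
}

test_that("coverage and expression join by site and transcript, missing stays missing", {
  j <- make_joined()
  r1 <- j[j$variant_id == "v1", ]
  expect_equal(r1$normal_dna_depth, 30L)
  expect_equal(r1$normal_dna_vaf, 0)
  expect_equal(r1$tumor_dna_vaf, 0.40)  # 12 / 30
  expect_equal(r1$tumor_rna_depth, 35L)
  expect_equal(r1$gene_fpkm, 5.5)       # transcript-level preferred

  r2 <- j[j$variant_id == "v2", ]
  expect_true(is.na(r2$tumor_rna_depth))  # no RNA row: missing, not zero
  expect_true(is.na(r2$tumor_rna_vaf))
  expect_equal(r2$gene_fpkm, 2.2)         # gene-level fallback

  r3 <- j[j$variant_id == "v3", ]         # site and gene absent everywhere
  expect_true(all(is.na(unlist(
    r3[c("normal_dna_depth", "tumor_dna_vaf", "gene_fpkm")]))))
  expect_equal(nrow(j), 3L)               # joining never removes candidates
})

test_that("depth filters enforce every printed boundary in the stated direction", {
  keep1 <- apply_depth_filters(candidate_row(normal_depth = 6, normal_vaf = 0,
                                             tumor_depth = 30, tumor_vaf = 0.45))
  expect_equal(nrow(keep1), 1L)

  cases <- list(
    list(row = candidate_row(normal_depth = 5), reason = "normal_coverage_low"),
    list(row = candidate_row(normal_vaf = 0.02), reason = "normal_vaf_high"),
    list(row = candidate_row(tumor_depth = 9), reason = "tumor_dna_coverage_low"),
    list(row = candidate_row(tumor_vaf = 0.39), reason = "tumor_dna_vaf_low"),
    list(row = candidate_row(rna_depth = NA, rna_vaf = NA),
         reason = "insufficient_data"))
  for (cs in cases) {
    out <- apply_depth_filters(cs$row,
                               tracks_required = c("tumor_dna", "tumor_rna"))
    expect_equal(nrow(out), 0L)
    expect_equal(dropped_records(out)$reason, cs$reason)
  }
  # the same rows pass just inside each boundary
  expect_equal(nrow(apply_depth_filters(candidate_row(normal_vaf = 0.019))), 1L)
  expect_equal(nrow(apply_depth_filters(candidate_row(tumor_depth = 10))), 1L)
  expect_equal(nrow(apply_depth_filters(candidate_row(tumor_vaf = 0.40))), 1L)
  # lowering the tumor VAF cutoff captures subclonal variants
  expect_equal(nrow(apply_depth_filters(candidate_row(tumor_vaf = 0.25),
                                        tumor_vaf_min = 0.20)), 1L)
  # RNA track only constrains when required
  expect_equal(nrow(apply_depth_filters(candidate_row(rna_vaf = 0.1),
                                        tracks_required = "tumor_dna")), 1L)
})

test_that("expression filter is strictly greater-than and treats missing as removable", {
  expect_equal(nrow(apply_expression_filter(candidate_row(fpkm = 1.5))), 1L)
  out10 <- apply_expression_filter(candidate_row(fpkm = 1.0))
  expect_equal(nrow(out10), 0L)
  expect_equal(dropped_records(out10)$reason, "fpkm_below_threshold")
  expect_equal(nrow(apply_expression_filter(candidate_row(fpkm = 0.4),
                                            fpkm_min = 0)), 1L)
  expect_equal(nrow(apply_expression_filter(candidate_row(fpkm = 0),
                                            fpkm_min = 0)), 0L)
  outna <- apply_expression_filter(candidate_row(fpkm = NA))
  expect_equal(dropped_records(outna)$reason, "no_expression_data")
})

test_that("filters conserve records, give one reason each, and commute", {
  set.seed(9)
  n <- 400
  cands <- candidate_row(variant_id = sprintf("v%03d", 1:n))
  cands$normal_dna_depth <- sample(c(0:40, NA), n, replace = TRUE)
  cands$normal_dna_vaf <- sample(c(seq(0, 0.5, 0.01), NA), n, replace = TRUE)
  cands$tumor_dna_depth <- sample(0:60, n, replace = TRUE)
  cands$tumor_dna_vaf <- sample(seq(0, 1, 0.01), n, replace = TRUE)
  cands$tumor_rna_depth <- sample(c(0:60, NA), n, replace = TRUE)
  cands$tumor_rna_vaf <- sample(c(seq(0, 1, 0.01), NA), n, replace = TRUE)
  cands$gene_fpkm <- sample(c(0, 0.5, 1, 1.5, 20, NA), n, replace = TRUE)

  d <- apply_depth_filters(cands, tracks_required = c("tumor_dna", "tumor_rna"))
  expect_equal(nrow(d) + nrow(dropped_records(d)), n)
  de <- apply_expression_filter(d)
  e <- apply_expression_filter(cands)
  ed <- apply_depth_filters(e, tracks_required = c("tumor_dna", "tumor_rna"))
  expect_equal(de$variant_id, ed$variant_id)  # order-independent kept set

  # independent brute-force oracle over the kept set
  ok <- !is.na(cands$normal_dna_depth) & cands$normal_dna_depth > 5 &
    !is.na(cands$normal_dna_vaf) & cands$normal_dna_vaf < 0.02 &
    !is.na(cands$tumor_dna_depth) & cands$tumor_dna_depth >= 10 &
    !is.na(cands$tumor_dna_vaf) & cands$tumor_dna_vaf >= 0.40 &
    !is.na(cands$tumor_rna_depth) & cands$tumor_rna_depth >= 10 &
    !is.na(cands$tumor_rna_vaf) & cands$tumor_rna_vaf >= 0.40 &
    !is.na(cands$gene_fpkm) & cands$gene_fpkm > 1
  expect_equal(de$variant_id, cands$variant_id[ok])
})
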