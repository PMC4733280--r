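# neoepitopes

Prioritization of candidate tumor neoantigens from annotated somatic missense
variants.

Tumor-specific missense mutations produce mutant peptides that, when presented
by a patient's HLA class I molecules, can be recognized by CD8+ T cells as
neoantigens — the raw material of personalized cancer vaccines. Picking the
handful of peptides worth synthesizing out of hundreds of somatic mutations
requires combining predicted peptide–MHC binding with the sequencing evidence
behind each variant. This package is for bioinformaticians running that
triage: it takes a list of annotated missense SNVs (amino-acid change plus
full wild-type transcript protein sequence), the patient's HLA class I
alleles, per-site read counts for normal DNA / tumor DNA / tumor RNA, and
gene/transcript FPKM values, and produces a ranked, auditable candidate list.

## Method

For each variant with protein change `X{p}Y` the package extracts the peptide
window of 10 flanking residues on each side of position `p` (a 21-mer;
windows near a protein terminus are extended on the other side to keep full
length), in both wild-type (WT) and mutant (MT) form. All k-mers with
k = 8–11 are scored per HLA allele by a pluggable predictor returning IC50
binding affinities in nM (built-in deterministic mock predictor, or a parser
for external prediction output). Candidates are then filtered:

1. **Binding:** keep MT peptides with IC50 < 500 nM (strict) that contain the
   mutated residue ("localized"); the WT score is reported alongside as the
   fold change FC = IC50_WT / IC50_MT (FC > 1: mutant binds more strongly).
2. **Depth/VAF:** remove candidates with normal coverage ≤ 5× or normal
   VAF ≥ 2% (germline evidence); require tumor DNA (and RNA, when provided)
   coverage ≥ 10× with VAF ≥ 40% (founder-clone mutations).
3. **Expression:** require gene/transcript FPKM > 1.

The single *best candidate* per mutation is the filtered row with the lowest
MT IC50 across all lengths and alleles (ties: shorter peptide, then allele
name, then start offset). Every removed record is logged once with a
machine-readable reason code.

A standalone rule engine additionally implements three post-calling somatic
variant filter sets (5 pileup rules, 9 read-evidence false-positive rules,
4 caller-confidence removal rules) over a per-site metrics table.

## Worked example

The synthetic fixture generator produces all five inputs with planted truth,
so the example is fully self-contained:

```r
library(neoepitopes)

cfg   <- fixture_config(seed = 7)                 # 200 missense variants
paths <- generate_fixture_set(cfg, tempdir())
pc    <- pipeline_config(c("HLA-A02:01", "HLA-B07:02"), seed = 7)
res   <- run_pipeline(pc, paths$variants, paths$coverage, paths$expression)
res$report
#>      input_variants   accepted_missense       peptide_pairs       fasta_records
#>                 200                 200                 200                 400
#>     raw_predictions         paired_rows    binding_filtered      depth_filtered
#>               40000               20000                7856                3209
#> expression_filtered  candidate_variants
#>                2378                  60

head(res$best[, c("variant_id", "hla_allele", "k", "mt_peptide",
                  "mt_ic50_nm", "fold_change", "gene_fpkm")], 3)
#>   variant_id hla_allele  k  mt_peptide mt_ic50_nm fold_change gene_fpkm
#> 1    VAR0003 HLA-B07:02  9   ERIIGMWYD   1.083864 1283.621864  3.711232
#> 2    VAR0004 HLA-A02:01 11 VYWSVHGQGME   1.034361 30469.408887  4.548883
#> 3    VAR0006 HLA-A02:01  8    RGHMDNST  42.531756    6.409472  6.564711
```

Reading the report: 200 variants yield 200 WT/MT window pairs (400 FASTA
records), scored as 40,000 (peptide, allele, length) predictions; pairing
leaves 20,000 MT rows, of which 7,856 are localized binders under 500 nM;
depth/VAF and expression filters cut these to 2,378 rows over 60 distinct
mutations, and `res$best` holds the strongest binder for each. Every stage's
removals are in `res$dropped` with reason codes.

A thin command-line wrapper with `simulate`, `run` and `somatic-filter`
subcommands is installed at
`system.file("cli", "neoepitopes.R", package = "neoepitopes")`.

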