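---
title: "Prioritizing neoantigen candidates from somatic missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing neoantigen candidates from somatic missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tumor's somatic missense mutations each change one amino acid in one
protein. Some of the resulting mutant peptides bind the patient's HLA class I
molecules well enough to be presented on the cell surface, where CD8+ T cells
can recognize them as foreign — these are neoantigens, and they are the
payload of personalized cancer vaccines. Melanomas and other
mutation-rich tumors carry hundreds of candidate mutations; peptide synthesis
and immunological screening are expensive, so the computational task is
triage: combine predicted peptide–MHC binding with the sequencing evidence
behind each variant and produce a short, defensible candidate list.

`neoepitopes` implements that triage as a pipeline of small, independently
testable stages, plus a standalone rule engine for post-calling somatic
variant filtering and a synthetic data generator that makes every stage
testable without sequencing data.

## The model and its stages

### Inputs

The pipeline deliberately does not call or annotate variants. Its seed input
is a TSV with one row per missense variant carrying the two facts everything
else derives from: the amino-acid change (`p.V600E` style, 1-based protein
coordinates) and the full wild-type transcript protein sequence. Alongside it:
the patient's HLA class I alleles; per-site read counts for three tracks
(normal DNA, tumor DNA, tumor RNA); and gene/transcript FPKM values.
Validation is strict about the invariants later stages rely on — the protein
must actually carry the stated wild-type residue at the stated position — and
in lenient mode each failing row is dropped with a recorded reason rather
than silently.

### Peptide windows

For a mutation at protein position $p$ with flank $f$ (default 10), the
window is

$$\text{start} = \max(1, p-f), \quad \text{end} = \min(L, p+f),$$

and if the resulting window is shorter than $2f+1$ the deficient side is
compensated: $\text{start} = \max(1, \text{end}-2f)$, then
$\text{end} = \min(L, \text{start}+2f)$. The result is the unique
$\min(2f+1, L)$-length window containing $p$, as centered as possible — a
21-mer by default, the whole protein when the protein is shorter. The flank
of 10 is chosen so that every possible 11-mer (the longest class I epitope
length scored by default) containing the mutant residue lies inside the
window; smaller flanks (8–9) are configurable and only reduce the candidate
space. Both the wild-type and mutant form of each window are written to
FASTA (WT first, a package convention recorded in the key file so order
never matters downstream). Prediction tools strip FASTA headers, so the key
file — record index, variant, WT/MT class — is what re-associates their
output with variants.

Windows overlapping `X` (unknown) or `U` (selenocysteine) are excluded at
this stage with a logged reason: binding predictors do not score nonstandard
residues reliably, and an affinity computed over a wrong residue is worse
than a recorded gap.

### Binding predictions

Class I molecules present peptides of roughly 8–11 residues, so all k-mers
of each window at those lengths are scored per allele. The predictor is a
plug-in — any function from (peptide, allele) to IC50 in nM. Two
implementations ship:

* **Mock predictor.** A keyed hash of (peptide, allele, seed) mapped onto a
  log-uniform IC50 range of 1–50000 nM. It encodes no binding biology at
  all; its purpose is to give the whole pipeline a deterministic,
  distribution-controlled stand-in so filtering, ranking and the end-to-end
  contract are testable. Under log-uniformity the expected share of random
  peptides under 500 nM is $\log 500 / \log 50000 \approx 0.574$, which the
  tests check empirically.
* **File parser.** Reads a tab-separated prediction file (record index,
  start offset, peptide, allele, IC50) and re-associates rows via the key
  file, failing loudly on unknown record indices. Real predictors slot in
  here without touching any downstream stage.

Allele names are normalized (`HLA-A*02:01`, `A0201` → `HLA-A02:01`) and
validated against a configurable allow-list, since allele-specific
predictors support finite panels; unsupported names fail fast rather than
mid-run.

### Filtering and best-candidate selection

The mutant and wild-type predictions are joined at identical
(variant, allele, length, offset) coordinates. Retention then requires:

1. **Localization** — the peptide contains the mutated residue. For a
   21-mer window with a central mutation and $k=9$ exactly 9 of the 13
   9-mers qualify. Non-localized k-mers of the mutant window are wild-type
   sequence and carry no tumor specificity.
2. **Binding** — mutant IC50 strictly below 500 nM, the conventional
   strong-to-intermediate binder threshold (configurable). The wild-type
   score never affects retention; it is reported as the fold change
   $\mathrm{FC} = \mathrm{IC50}_{WT}/\mathrm{IC50}_{MT}$ for interpretation
   only. When the WT partner is missing the fold change is missing, never
   imputed.
3. **Depth/VAF** — two independent normal-track disqualifiers: depth
   $\le 5\times$ (too shallow to establish absence from the germline) or
   VAF $\ge 2\%$ (evidence the allele is germline or the normal is
   tumor-contaminated). The sentence defining these cutoffs could also be
   read as a single conjunctive rule; the two-disqualifier reading is this
   package's design choice because each condition independently undermines
   the somatic call, and per-reason logging lets users audit it. Tumor
   tracks (DNA always; RNA when RNA coverage is supplied) must reach
   $\ge 10\times$ depth with VAF $\ge 40\%$ — the founder-clone regime;
   lowering the tumor VAF floor admits subclonal variants. Missing values
   on a required track remove the candidate as `insufficient_data`:
   missingness is never treated as passing evidence.
4. **Expression** — FPKM strictly greater than 1. Any positive FPKM is
   nominal expression; the unit threshold trims noise, and transcript-level
   values are preferred over gene-level when both exist (the variant lives
   on a specific transcript).

All boundary comparisons follow the stated inequality directions exactly
(e.g. 500.0 nM fails the "< 500" test; normal VAF of exactly 2% is
removed; tumor VAF of exactly 40% passes). The filters commute — the kept
set is the conjunction — and each removed row carries exactly one
first-failing reason code, so stage counts always reconcile.

The **best candidate** per mutation is the surviving row with the lowest
mutant IC50 across all lengths and alleles. Exact ties are possible (scores
are real numbers, but file-parsed predictions are often rounded), so the
tie-break is fixed: smaller $k$, then lexicographically smaller allele,
then smaller start offset. Both the full filtered table and the
one-per-mutation table are emitted; validation labs need the former, vaccine
design shortlists start from the latter.

### Somatic filter rule engine

Three rule sets commonly applied after somatic variant calling are
implemented as pure functions over a per-variant metrics table (computing
those metrics from alignments is upstream of this package, so the rules are
testable with no BAMs):

* a 5-rule pileup filter (indel proximity, mapping quality, SNV density,
  depth bounds, consensus/SNP quality — "consensus and SNP quality ≥ 20" is
  implemented as both qualities ≥ 20);
* a 9-rule false-positive filter (strand support, VAF, read count, read
  position, quality and read-length differentials, 3' distance,
  homopolymer adjacency);
* a 4-rule high-confidence filter whose conditions have the opposite
  polarity: they describe what is *removed* (weak p value, normal support,
  low tumor VAF, < 2 reads), joined by OR.

Each verdict lists the violated rule codes, and the tests flip every one of
the 18 boundaries individually to confirm exactly that code responds. One
printed bound — "fewer than $10^9$ reads" — is effectively unbounded and is
implemented literally. The strand rule is read as each strand contributing
≥ 1% of *variant-supporting* reads (the alternative, 1% of all reads, is
grammatically possible but would make the rule depend on total depth in a
way the other rules do not).

## The synthetic cohort

The generator emulates the input data shapes with planted truth, not
sequencing physics. Defaults, chosen once as a realistic desk-scale cohort:

| parameter | default | rationale |
|---|---|---|
| proteins | 50, lengths 30–800 | spans short peptides to large proteins |
| variants | 200 | a post-filter missense load for a mutation-rich tumor; end-to-end runs in seconds |
| near-terminus fraction | 0.2 | exercises the window edge rule routinely |
| normal / tumor depth | 30× / 60× (negative binomial, size 8) | exome-like overdispersed coverage |
| somatic VAF | beta, mean 0.5 | founder-clone heterozygous variants |
| germline contamination | 10% of sites | planted failures for the normal-VAF filter |
| FPKM | log-normal(1, 1), 30% at exactly 0 | skewed expression with a silent fraction; silent genes also get zero RNA depth |

One global seed is split per component through a keyed hash, so proteome,
variants and coverage are independently reproducible. What the generator
does **not** emulate: sequencing error profiles, mapping artifacts, real HLA
binding motifs (the mock predictor is motif-free), isoform structure, or
correlated depth along the genome. Passing end-to-end tests therefore
demonstrate that the plumbing, filters and selection logic are correct under
known truth — not that the pipeline's biological predictions are accurate,
which is entirely the province of the binding predictor plugged in and the
upstream variant calls.

## Numerical and degenerate-input choices

* IC50 values are strictly positive; the mock range [1, 50000] nM avoids
  log-of-zero issues in fold changes.
* Zero-depth sites yield missing VAF (0/0 is not 0), which required tracks
  treat as removal with `insufficient_data`.
* Proteins shorter than a k-mer yield an empty enumeration, not an error;
  a variant whose every peptide fails simply drops out of the candidate
  list.
* Equal-score ties and join order are fully determinized, and re-running the
  pipeline with the same configuration is byte-identical on disk.

## Interface decisions

Every stage is an exported function and the end-to-end orchestration is
`run_pipeline()` over a validated `pipeline_config()`; the shell wrapper in
`inst/cli/` keeps only three subcommands (`simulate`, `run`,
`somatic-filter`) because each intermediate stage is more usefully scripted
in R, where its inputs and outputs are data frames rather than file
handshakes. Exit codes: 0 success, 2 input/schema error, 3 stage failure.
The CLI accepts VAF thresholds as percentages (as they are usually quoted)
and converts to fractions internally.

## Known limitations

* Missense SNVs only: frameshifts, in-frame indels, splice aberrations and
  fusions — all plausible neoantigen sources — need window logic this
  version does not implement.
* The 500 nM / 40% VAF / FPKM > 1 defaults are sensible starting points,
  not universal constants; cohort-specific tuning is expected and exposed.
* Binding affinity is a presentation proxy; immunogenicity, TCR
  recognition, and peptide manufacturability are downstream concerns outside
  this package.
* The acceptance and test problem sizes (10,000 random windows, 1,000
  randomized selection tables, a 200-variant cohort) are the package's
  chosen desk-scale verification sizes; all run in well under a minute.
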