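# pgxscreen

Universal germline pharmacogenomic screening for cancer cohorts.

Germline variants in drug-metabolism genes change how patients tolerate
common anti-cancer agents: UGT1A1 poor/intermediate metabolizers clear
irinotecan's active metabolite slowly, DPYD-deficient patients
accumulate fluoropyrimidines (5-fluorouracil, capecitabine), TPMT-null
patients develop profound cytopenia on mercaptopurine, and CYP2D6
activity governs tamoxifen activation. CPIC assigns these six drug–gene
pairs level-A evidence — strong enough to change prescribing — yet
pre-treatment genotyping is still not routine. `pgxscreen` implements
the analysis layer of a universal screening strategy that reuses
germline whole-exome data (originally produced for somatic-variant
quality control) to genotype a 15-gene CPIC level-A panel and to ask,
per patient and per cohort: who carries an actionable variant, for whom
is it *disease-relevant* (an NCCN preferred/other regimen for their
cancer type contains the associated drug), who actually received the
drug, and did genotype-related toxicity follow.

The package is aimed at translational pharmacogenomics groups who have
per-sample germline variant calls (VCF) plus a clinical manifest, and at
methodologists who want a fully synthetic, ground-truthed testbed for
star-allele calling and actionability logic.

## What it computes

- **Star-allele diplotype calling** (`readVariantCalls`, `callPanel`).
  Variant dosages at knowledge-base positions (GRCh37, minimal
  representation) are matched against every unordered pair of defined
  alleles per gene. Unphased multi-variant genotypes that admit several
  diplotypes — the classic TPMT c.460G>A + c.719A>G heterozygote, which
  is either *1/*3A (cis) or *3B/*3C (trans) — are returned with the
  full candidate set, ranked by population-frequency product
  `f(a1)·f(a2)`. Positions without coverage assertions are *uncallable*,
  never silently wild-type.
- **Phenotype translation** (`metabolizerPhenotype`). Count-of-
  nonfunctional rules for UGT1A1/TPMT (0/1/2 variant alleles →
  normal/intermediate/poor), CPIC activity scores for DPYD and CYP2D6
  (allele values 1.0 / 0.5 / 0.0, summed and banded), carrier reporting
  for the rest of the panel, hemizygous X handling for G6PD.
- **Actionability** (`potentialRisk`, `actualRisk`,
  `attributeToxicity`). A disease → drug → gene indication matrix with
  NCCN preferred/other tiers classifies *potential* risk (carrier with
  a relevant indication, regardless of treatment) and *actual* risk
  (carrier actually treated on site). Toxicity is genotype-related only
  when a drug-specific adverse event (e.g. diarrhea or cytopenia for
  irinotecan) triggered a clinical action (dose reduction, delay,
  discontinuation, hospitalization, death) and the triggering cause is
  not excluded (allergy, fatigue, patient request).
- **Cohort statistics** (`tallyAlleles`, `alleleFrequency`,
  `carrierRate`, `fisherExact2x2`, `summarizeCohort`). Variant
  landscape with expected-frequency comparison (exact binomial 95% CI),
  the risk matrix, and the 2×2 genotype-by-toxicity association tested
  with a two-sided Fisher exact test (small-p-values summation;
  `p = Σ { P(T) : P(T) ≤ P(observed) }` over all tables with the
  observed margins).
- **Synthetic cohorts** (`defaultCalibration`, `generateCohort`,
  `emitVcf`, `emitClinicalTables`). Cohorts with the study's disease
  mix, per-gene genotype frequencies, indication-consistent treatment
  exposure and genotype-dependent toxicity rates (7/9 for non-normal
  vs 13/36 for normal metabolizers), with planted ground truth —
  so the entire pipeline is testable without any protected patient
  data.

## Worked example

Simulate a 291-patient cohort, call it, and summarize:

```r
library(pgxscreen)
cmdSimulate("demo", n = 291, seed = 11)          # VCF + clinical tables
s <- cmdCohort("demo/cohort.vcf", "demo/manifest.tsv",
               "demo/treatments.tsv", "demo_out")

round(100 * s$carrier_rate_any, 1)
#> 90.7                  # % of patients carrying any panel variant

l <- s$landscape
l[l$gene == "UGT1A1", c("allele", "n_hom", "n_het", "frequency")]
#>  allele n_hom n_het frequency
#>     *28    24   133     0.311   # vs expected population 0.3165
#>   Total    NA    NA     0.311

s$risk_matrix[s$risk_matrix$disease == "Colon/rectal", ]
#>    gene         drug      disease      tier  a  A b  B
#>  UGT1A1   irinotecan Colon/rectal preferred 29 53 2 28
#>    DPYD capecitabine Colon/rectal preferred  2 53 0  2
#>    DPYD fluorouracil Colon/rectal preferred  2 53 0  2

s$fisher_note
#> "two-sided Fisher exact p = 0.6649"
```

`a/A` reads "29 of the 53 colorectal patients carry a UGT1A1 variant"
(potential risk); `b/B` reads "2 of the 28 on-site variant carriers
received irinotecan" (actual risk). The Fisher p compares
genotype-related toxicity between variant and wild-type metabolizers
among treated patients; at n = 291 treated numbers are small, so the
p-value is noisy — on the reference contingency table (7, 2, 13, 23)
the implementation returns `fisherExact2x2(7, 2, 13, 23)` = 0.0567.

A per-patient report (written by `cmdCall`) looks like:

```
Pharmacogenomic screening report -- P000002
Primary cancer site: Colon/rectal

Gene panel results:
  UGT1A1   *1/*28    heterozygous    intermediate
  DPYD     *1/*1     wild_type       normal
  ...
Disease-relevant drug considerations:
  irinotecan (preferred tier): UGT1A1 variant carrier, phenotype intermediate
```

A shell entry point with `simulate` / `call` / `cohort` subcommands is
installed at `inst/scripts/pgxscreen.R`:

```sh
Rscript inst/scripts/pgxscreen.R simulate --out demo --n 291 --seed 11
Rscript inst/scripts/pgxscreen.R cohort --vcf demo/cohort.vcf \
    --manifest demo/manifest.tsv --treatments demo/treatments.tsv \
    --out demo_out --fisher two-sided
```

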