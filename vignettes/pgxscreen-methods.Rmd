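---
title: "pgxscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pgxscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxscreen)
```

`pgxscreen` analyses germline pharmacogenomic screening data for cancer
cohorts: it calls star-allele diplotypes over a 15-gene CPIC level-A
panel from VCF variant calls, translates them to metabolizer
phenotypes, classifies disease-relevant actionability against an
NCCN-derived indication matrix, attributes treatment toxicity to
genotype, and summarizes cohorts. This vignette documents the model,
its tunable parameters, the synthetic-data calibration, and the design
decisions taken where the problem admitted several defensible answers.

## The panel as data

Everything gene-specific is configuration, not code
(`inst/extdata/kb/default_kb.yaml`): allele definitions with their
defining GRCh37 variants, CPIC function classes and activity values,
expected population frequencies (CPIC, falling back to gnomAD/ExAC),
the six anti-cancer level-A drug–gene pairs with their
genotype-related adverse-event vocabularies, and the disease → drug →
gene indication matrix with preferred/other tiers. A CPIC revision or
an assay change is a config edit; `validateKnowledgeBase()` checks
every structural invariant (coordinate sanity, cross-gene variant-key
uniqueness, the mandatory anti-cancer pairs, activity values present
exactly for activity-score genes) and reports violations as data.

Three encoding choices deserve a note:

- **TPMT.** *3A is the two-variant haplotype (c.460G>A + c.719A>G);
  *3B and *3C are its single-variant components. Sharing defining
  variants *within* a gene is what creates unphased cis/trans
  ambiguity and is deliberately allowed; uniqueness is enforced across
  genes only.
- **SLCO1B1.** The assay cannot separate *15 from *17, so the panel
  reports one combined allele "*15 or *17". To keep variant→allele
  lookup unambiguous alongside *5, the combined allele is keyed to the
  c.388A>G tag and *5 to c.521T>C. This mirrors the reporting
  structure of the assay rather than the true haplotype structure
  (real *15/*17 also carry c.521T>C); with genotype frequencies
  supplied at the patient level this has no effect on any downstream
  count.
- **HLA-B.** Risk alleles (*57:01, *15:02, *58:01) are presence/absence
  calls keyed to proxy tag SNPs; no HLA typing is attempted.

## Diplotype calling

For each gene the caller enumerates, once, every unordered pair of
defined alleles (reference included) and indexes pairs by the implied
dosage vector over the gene's defining variants. A sample's observed
dosage vector then resolves by lookup:

- exactly one pair → an unambiguous call;
- several pairs → an ambiguous call carrying the full candidate set;
- no pair → *uncallable* (`no_consistent_diplotype`): more than two
  variant allele copies have no two-allele explanation, and the panel
  has no copy-number support, so this is reported as an error state
  rather than guessed at.

**Missing is not reference.** A knowledge-base position absent from
the VCF is read as homozygous reference only when the position lies in
a covered region asserted in the header (`##coveredregion=...`) or a
supplied coverage mask; otherwise the gene is uncallable. Silent
wild-type calls under dropout would inflate normal-metabolizer counts
in exactly the patients whose toxicity risk the screen exists to find.

**Normalization.** Records are reduced to minimal representation
(common suffix then common prefix trimming, one anchor base kept)
before matching. Full left-alignment against a reference sequence is
not performed — the package ships no genome — so knowledge-base
spellings are stored already left-aligned, and the emitter writes
exactly those spellings. Minimal representation absorbs
padding-dialect differences between callers; a caller that
right-aligns an indel inside a repeat tract would need upstream
normalization (e.g. `bcftools norm`) first, which is the standard
practice this package assumes.

**Ambiguity.** Unphased candidates are ranked by the product of allele
population frequencies, with the reference frequency taken as one
minus the gene's summed variant frequencies (floored at zero), weights
normalized to one, and exact ties broken lexicographically. For the
TPMT double heterozygote this ranks *1/*3A (product ≈ 0.956 × 0.0343)
far above *3B/*3C (0.0027 × 0.0047) — the population-likelihood answer.
Because the rarer trans resolution is precisely the clinically severe
one (poor instead of intermediate metabolizer), the call (i) keeps the
complete candidate list, (ii) computes the phenotype of every
candidate and flags disagreement, and (iii) the report recommends
confirmatory genotyping. An alternative `trans` ambiguity policy
(`applyAmbiguityPolicy`) re-ranks toward the compound-heterozygous
resolution for replaying a confirmed trans call; neither policy ever
discards candidates.

**X linkage.** G6PD is called haploid for non-female samples (sex from
the manifest); a hemizygous deficiency allele is labelled
`deficient`. Ploidy inconsistencies (diploid male X, haploid
autosome) warn and mark the observation missing rather than guessing.

## Phenotype translation

- UGT1A1, TPMT — count of non-functional alleles: 0 → normal,
  1 → intermediate, 2 → poor.
- DPYD, CYP2D6 — activity score: allele values 1.0 (normal), 0.5
  (decreased), 0.0 (none), summed. Bands are knowledge-base data:
  DPYD ≤ 0.5 poor, ≤ 1.5 intermediate, 2 normal; CYP2D6 0 poor,
  ≤ 1.0 intermediate, else normal — so a *1/*6 score of 1.0 is
  intermediate, the current CPIC convention; the older one is a
  config switch.
- Remaining genes — carrier report: any non-reference allele →
  carrier (deficient when hemizygous with a deficiency allele).

Three properties are enforced by tests over the full enumerable
diplotype space: exhaustiveness (every expressible diplotype maps to
exactly one phenotype), symmetry in allele order, and monotonicity
(adding a non-functional allele never moves a phenotype toward
normal).

## Actionability and toxicity attribution

*Potential risk* joins carriers to the indication matrix for their own
primary site, independent of treatment; *actual risk* is the treated
subset (on-site treatments only; patients treated elsewhere are kept
in potential-risk numerators but excluded from actual-risk
denominators). Findings are per (patient, drug): a patient may appear
in several drug analyses, and carrier-level summaries deduplicate
separately. Tamoxifen–CYP2D6 is efficacy-associated: it produces risk
findings but is excluded from the toxicity table, which would
otherwise mix outcome types.

A treated course is *genotype-related toxic* when three conditions
hold: at least one adverse event belongs to the drug's
genotype-associated list (cytopenia/diarrhea for irinotecan;
cytopenia, diarrhea, hepatotoxicity, mucositis/stomatitis,
cardiotoxicity for fluoropyrimidines; cytopenia for mercaptopurine); a
clinical action occurred (dose reduction, delay, discontinuation,
hospitalization, death); and the recorded triggering cause is not on
the exclusion list (allergic reaction, fatigue, patient request).
Attribution is monotone in qualifying events by construction.

## Cohort statistics

**Frequencies.** Allele frequency is
(2·hom + het + hemi) / (2·N) — the uniform 2N denominator for every
gene, X-linked ones included, reproducing the published reporting
convention; an `x-aware` denominator (2·females + males) is available
but non-default. Displayed per-gene totals follow the source table's
convention of summing the *rounded* per-allele rows, which is why a
displayed DPYD total of 0.0240 can coexist with a full-precision
14/582 = 0.02405; computation always uses full precision and rounds
only for display.

**Expected-frequency comparison.** "Similar to expected" is
operationalized as containment of the expected population frequency in
the exact binomial central 95% CI of the observed allele count
(`binom.test`); zero-expected alleles flag on any observation. The
rule (and its level) is a parameter, because the judgment it encodes
is inherently a convention.

**Fisher's exact test.** `fisherExact2x2` implements the two-sided
small-p-values definition — the sum of hypergeometric point
probabilities (via `stats::dhyper`) no greater than the observed
table's, with the customary 1 + 1e-7 relative tolerance on the
equality comparison. Mid-p and one-sided variants sit behind a flag.
The test suite checks exact agreement (1e-12) against an independent
log-binomial-coefficient enumeration oracle — exhaustively for all
tables with N ≤ 28 and on seeded random tables up to N = 60 — and
against `stats::fisher.test`. Degenerate margins raise an error at the
function level; the cohort summary catches this and reports the
association as not computed while still emitting all other tables.

## The synthetic cohort generator

The generator exists so that every stage — VCF parsing, calling,
phenotyping, actionability, statistics — can be exercised end-to-end
with known ground truth, since the motivating cohort's patient-level
data cannot be redistributed. Its defaults *are* the study conditions:

- **Disease mix**: the published site distribution (n = 291), refined
  to indication-matrix granularity so that the coarse demographic
  table and the per-disease risk-matrix denominators hold
  simultaneously (gynecologic 49 = ovary 25 + uterus 22 + cervix 1 +
  vulva 1; leukemia/lymphoma 15 = ALL 3 + other 12; kidney/bladder
  14 = bladder 3 + kidney 11; small bowel 12 = adenocarcinoma 2 +
  carcinoid/neuroendocrine 10; skin 12 = basal 1 + squamous 4 + other
  7; other 21 = hepatobiliary 7 + anus 1 + thyroid 4 + misc 9). The
  split of aggregate rows follows the per-disease denominators printed
  with the risk matrix; each refined count is data in
  `study_calibration.yaml`.
- **Genotypes**: per (gene, allele) patient-level hom/het probabilities
  taken directly from the published genotype counts over 291 — not
  allele frequencies through Hardy–Weinberg — so planted hom/het
  ratios match the study by construction. Genes are independent (only
  marginals are published); alleles within a gene draw independently
  with at most two variant copies enforced by whole-gene redraw, i.e.
  the gene's genotype follows the conditional distribution given a
  valid diploid genotype. That conditioning (which real data obeys by
  construction) shifts multi-allele marginals slightly below their
  unconstrained inputs — at most 0.0018 in allele frequency, for
  SLCO1B1 *5 — and the recovery tests therefore compare against the
  exact conditional expectation, computed in closed form by
  enumerating per-gene copy configurations.
- **Treatments**: exposure probabilities per (drug, tier) — e.g.
  irinotecan 0.15 and fluorouracil 0.25 for preferred indications,
  0.02 for other-tier, mercaptopurine 0.34 for ALL — chosen as rough
  rates so that about 16% of patients receive a genotype-relevant
  anti-cancer drug, matching the scale of exposure the screen is
  designed around; a 10% treated-elsewhere rate exercises the
  follow-up exclusions. These are free knobs, not estimates.
- **Toxicity**: genotype-related toxicity probability 7/9 for
  non-normal metabolizers and 13/36 for normal ones (the study's
  observed rates); a 10% nuisance-event rate (fatigue, allergic
  reaction) plants courses whose actions must be *excluded* by the
  attribution rules; treatment-related death is sampled at 2% of toxic
  courses and never required by any test.

All randomness flows from the single config seed. Under these defaults
the expected any-variant carrier rate is ~90% and the expected
disease-relevant rate ~26% (closed-form products over the per-gene
carrier probabilities; the acceptance script recomputes both by
simulation).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: linkage between genes and correlation
between genotype and disease (draws are independent); true phase
(plants are phase-known, VCFs are emitted unphased); sequencing error,
coverage dropout and caller disagreement (dosages are exact, coverage
is always asserted; the missing-data paths are tested through
synthetic masks instead); population structure (one set of
frequencies; the study population is predominantly non-Hispanic
white); real adverse-event records (events are drawn from the
drug-specific vocabularies, not abstracted from charts); and CYP2D6
copy-number/hybrid alleles, which the panel excludes.

## Problem sizes and numerical choices

The shipped tests run the generator at n = 100,000 for frequency
recovery (3-SE binomial bands), a pooled 500 × 291 design for the
carrier-rate means, and 1,000 emitted-and-reread samples for diplotype
round-trip — sizes at which the binomial error bands are a few times
smaller than the effects they guard, while the whole suite stays
around a minute. Exact Fisher enumeration is exhaustive to N = 28 and
sampled to N = 60. Frequencies are displayed at 4 decimals and
percentages at 1, as in the source tables; all comparisons happen at
full precision. Deterministic outputs (reports, summary tables,
emitted VCFs) are byte-stable across reruns for a fixed seed, which
the CLI tests assert literally.

## Known limitations

- The panel is positional: novel alleles or variants outside the
  knowledge base are invisible, and limited-testing genes (CFTR,
  CYP2C19, CACNA1S, HLA-B) are screened only at their listed sites.
- Unphased ambiguity is resolved by population priors, which by
  design favour the benign cis resolution for TPMT; the severe trans
  case is surfaced, not asserted. Confirmatory testing is the stated
  recommendation, not an afterthought.
- The indication matrix is a snapshot of guideline tiers; NCCN
  regimens change, and the matrix must be re-versioned with them.
- Toxicity attribution is rule-based on abstracted events and
  actions; it does not grade severity and cannot adjudicate competing
  causes beyond the exclusion list.
- The 2N frequency denominator understates X-linked allele
  frequencies when males are present; it is kept as the default for
  comparability with the published convention, with the x-aware
  denominator one flag away.
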