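---
title: "Methods: variant prioritisation and reporting for a targeted neurodegeneration panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritisation and reporting for a targeted neurodegeneration panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropanel)
library(dplyr)
```

## The problem

Targeted resequencing panels are the pragmatic middle ground between
single-gene testing and exome/genome sequencing for heterogeneous disease
groups. This package implements the downstream half of such a design for
neurodegeneration: an 80-gene panel spanning four disease categories —
ALS/FTD (a joint category of 29 genes), Alzheimer's disease / mild
cognitive impairment (21), Parkinson's disease (23) and vascular cognitive
impairment (7) — applied to a cohort of patients carrying one of five
clinical diagnoses (AD/MCI, ALS, FTD, PD, VCI). Given per-sample variant
calls and an annotation resource, it prioritises variants, dichotomises
them into *clinically relevant* versus *uncertain significance*, calls
APOE diplotypes, audits sequencing runs, checks cross-platform
concordance, and assembles the cohort-level tables a genomics core would
report.

The total target size of the packaged panel is fixed at 971,388 bp. (Two
nearby figures circulate for panels of this design, 971,388 and 972,388;
we adopt 971,388 throughout because it is the figure the downstream
Sanger-cost arithmetic is built on: `ceiling(971388 / 500) = 1943`
amplicons.) The shipped target BED is an explicitly *synthetic* fixture —
one interval per gene, lengths summing to exactly 971,388 bp — because
probe coordinates are proprietary to a given design; no downstream
computation uses anything but the total and the per-gene placement.

## Classification model

A called variant joined to its annotation record is pushed through three
gates, in order:

1. **Panel membership.** The gene must be on the panel (aliases PRKN,
   DJ1, STH resolve to PARK2, PARK7, MAPT). Off-panel: `excluded`
   (`OFF_PANEL`).
2. **Rarity.** Default rule (`all_dbs`): the variant is rare iff *every*
   database MAF that is present (1000 Genomes, ESP, ExAC) is below the
   threshold (default 1%). A missing MAF means "not observed in that
   database" and never disqualifies; absence from all three is itself
   evidence of rarity. An `exac_only` variant of the rule consults only
   ExAC — both conventions appear in practice and the table footnotes of
   cohort reports often use the ExAC-only form. Failing: `excluded`
   (`NOT_RARE`).
3. **Consequence.** Missense, nonsense, frameshift, in-frame indel and
   splicing qualify; synonymous and noncoding do not
   (`NOT_QUALIFYING_CONSEQUENCE`).

Survivors are dichotomised:

- `clinically_relevant` iff the variant is in a disease database (HGMD
  **or** ClinVar) **and** the in-silico predictions support damage;
- `uncertain_significance` otherwise — including the case where the
  predictors are all missing. Requiring positive prediction support for
  the relevant class is the conservative ACMG-style reading.

**Prediction aggregation.** The predictors are combined as
*(PolyPhen-2 ∈ {possibly, probably damaging} OR SIFT = deleterious)*,
with CADD acting as a veto only: a present CADD below the cutoff blocks
the damaging call, a missing CADD never does. When PolyPhen-2 and SIFT
are both missing but CADD is present the call is `false`, not
CADD-alone: CADD is calibrated as a ranking score and we do not let it
establish support by itself. All three are missing → `unknown`.

**CADD scale.** The default is the phred-like scale with cutoff 20. A
raw-scale mode (cutoff 0) is provided because published case reports
sometimes quote raw scores — e.g. a well-described APP p.Ala713Thr
missense variant quoted with "CADD 5.483", a value that only makes sense
as a raw score (its phred-scale equivalent is far above 20). The worked
example in the README and the packaged fixture use the raw mode for
exactly this reason.

**Recurrent artifacts.** A variant carried by more than
`artifact_cohort_fraction` (default 0.10) of the whole cohort is more
plausibly a systematic sequencing/alignment artifact than a shared rare
allele. The threshold is not a published constant; 0.10 is deliberately
conservative, the flag is annotated rather than the variant dropped, and
a per-diagnosis carrier count (`shared_in_diagnosis`) is attached so a
reviewer can distinguish artifacts from founder alleles.

**Zygosity** is carried through but does not alter the category: the
dichotomisation rules are genotype-agnostic, and inheritance-mode-aware
zygosity logic (compound heterozygotes, X-linked males) is out of scope.

## APOE calling

The three common isoforms are haplotypes of rs429358 and rs7412 (both
C/T): E2 = (T,T), E3 = (T,C), E4 = (C,C). The map ships as an explicit
table (`APOE_HAPLOTYPE_MAP`), with a `strand_flip` switch for call sets
reported on the opposite strand. Unphased two-SNP genotypes resolve by
enumerating both phasings and discarding any involving the rare E1
haplotype (C,T):

- seven of the nine genotype pairs resolve uniquely;
- the double heterozygote admits E2/E4 or E1/E3; within the six-genotype
  universe it is called **E2/E4 with `ambiguous = TRUE`** rather than
  silently resolved;
- the two pairs resolvable *only* through E1 (e.g. rs429358 C/C with
  rs7412 T/T) raise `UNRESOLVABLE_HAPLOTYPE` — they indicate a genotyping
  error or a genuinely rare isoform that the model refuses to coerce.

Allele frequencies follow by gene counting,
freq(a) = (2·hom(a) + het(a)) / 2n, reported to three decimals;
genotype percentages to one decimal (cohort table) or to the printed
mixed precision (two decimals below 10%) in the risk table.

## Run QC

Metrics mirror the conventional run sheet: reads passing filter as an
integer percent of total reads; percent mapped and percent ≥ Q30 (of
mapped reads, per-read mean quality) to one decimal; percent of target
bases covered ≥ 30× to one decimal; mean/min/max depth. The ≥ 30×
boundary is inclusive. `run_passes()` evaluates any set of lower bounds
and names the failing metrics; no thresholds are hard-coded, since a run
below a coverage target may still be analysable (an 84.9%-at-30× run is
the canonical example).

## Concordance

Cross-platform comparisons are allele-set based (0/1 vs 1/0 concordant),
computed at the intersection of typed sites; sites typed on only one
platform are reported separately and never count against the rate, and a
missing genotype on either platform removes that sample-site pair from
the denominator into a missingness tally. False positives are discordant
pairs where only the test platform sees the alternate allele; false
negatives are reference-carrier pairs the test platform missed. The
array-marker filter applies the standard validation cascade in order
(noncoding/synonymous → common in *any* database → segmental
duplication → not predicted damaging) with a conservation check that
per-step removals and survivors sum to the input. Note the deliberate
asymmetry with the clinical rarity rule: marker filtering drops a
variant common in *any* database, clinical rarity requires rarity in
*every* database where seen; each convention matches its use.

## Synthetic cohorts

The generator's defaults *are* the study conditions the package is
designed around: 216 samples apportioned 40/22/21/56/77 across AD/MCI /
ALS / FTD / PD / VCI by largest remainder; carrier rate 156/216 = 0.722
with the 1/2/3+ bins at 76/57/23 of 156; disease-database membership
62/266; concordant-gene rate 107/266; APOE allele frequencies
27/432, 333/432, 72/432 (E2/E3/E4) drawn under Hardy–Weinberg;
a 3-in-216 C9orf72 expansion rate drawn among ALS/FTD samples only
(expansions cluster there clinically); mean coverage 76× with
negative-binomial overdispersion (size 8), giving the long-tailed depth
profile of amplicon capture. Within the 3+ bin, counts are 3 or 4
(ratio 3:1); ages are normal per stratum at the published means, clamped
to a plausible 40–90 range; sex is Bernoulli at each stratum's published
ratio; 82.3% Caucasian ethnicity.

Each qualifying variant is placed at a fresh position inside its gene's
target interval (unique keys by construction), with rare MAFs on
(0, 0.005], supportive or non-supportive predictions at the configured
damaging rate, and db-membership flags; non-qualifying decoys (common
missense, or rare synonymous/noncoding) are mixed in at a Poisson rate
per sample so the filters have something to reject. The truth table
records every variant's intended category and every sample's intended
qualifying count; classification is deterministic given annotations, so
recovery must be *exact*, and the tests assert exactly that.

One global seed expands into fixed named sub-streams (metadata, APOE,
variants, QC, replicates), so adding a generator never perturbs existing
streams and bundles are byte-identical under a fixed seed.

What the generator does **not** emulate: linkage disequilibrium beyond
the two APOE SNPs, recurrent shared variants (each simulated variant has
one carrier, so the artifact flagger is exercised by hand-built fixtures
instead), read-level error, multi-allelic sites, and indel left-alignment
pathology. Passing tests therefore demonstrate the correctness of the
rule engine and the statistical calibration of the estimators — not
robustness to the full messiness of production VCFs.

## Numerical choices

- **Rounding** is half-away-from-zero everywhere (printed-table
  convention), not base R's banker's rounding. Percentages are one
  decimal except reads-PF (integer) and small risk-table percentages
  (two decimals below 10%).
- Two printed-percentage discrepancies are resolved in favour of the
  counts, which are authoritative: 23/156 is reported as 14.7% (not the
  sometimes-printed 14.8%), and 3/216 as 1.39% (not 1.40%). Tables never
  store percentages detached from the counts they derive from.
- **Variant keys** are parsimony-trimmed (shared suffix then prefix,
  position shifted accordingly). Left-alignment needs the reference
  genome, which the package does not ship; keys are assumed
  left-aligned upstream, as annotation resources conventionally are.
  Coordinates are VCF 1-based inclusive; BED 0-based half-open; GRCh37.
- **Missing MAF vs zero MAF** are distinct: `NA` means unobserved in
  that database, 0.0 means observed at frequency zero; only the rarity
  rule interprets `NA`.
- Degenerate inputs error early with classed conditions
  (`neuropanel_*`), never silently: empty panels, duplicate annotation
  keys, position 0, zero-read runs, zero-overlap concordance.

## Problem sizes

The shipped tests run cohorts of 8–216 samples; the multi-seed recovery
checks use twenty 216-sample cohorts, and the acceptance script pools
ten. Coverage simulations are down-scaled to ~50k target bases (5% of
the panel) where only the mean is under test; the full 971,388-base
vector is used where the target-size arithmetic itself matters. These
sizes were chosen so the whole suite completes in a couple of minutes on
one core while keeping every binomial check adequately powered.

## Interface note

The package's exported functions compose the entire workflow, and
`run_pipeline()` executes it end to end over a bundle directory,
writing the classified report, the three cohort tables and a JSON
summary with deterministic output. There is no shell executable: the
intended users drive analyses from R, and `scripts/acceptance.R` shows
the headless pattern.

## Known limitations

- No segregation, phasing or compound-heterozygote logic; zygosity does
  not affect categories.
- The full 28-criterion ACMG-AMP engine is out of scope; the
  dichotomisation implemented here is the panel-report reduction of it.
- C9orf72 repeat expansions are consumed as an external assay flag
  (repeat expansions are invisible to short-read panels).
- Array-manifest-specific marker attrition counts depend on the
  proprietary manifest and cannot be reproduced from first principles;
  the filter cascade itself is fully tested on constructed fixtures.
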