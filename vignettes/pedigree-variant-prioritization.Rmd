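---
title: "Pedigree-aware rare-variant prioritization: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware rare-variant prioritization: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftsift)
```

## The problem

Nonsyndromic orofacial cleft (NSOFC) is the most common congenital
craniofacial malformation. Genome-wide association studies explain only a
fraction of its heritability, and in multiplex families — families with two
or more affected members — rare coding variants transmitted under simple
Mendelian models are a leading candidate for the missing contribution.
`cleftsift` implements the standard desk workflow for such cohorts: given a
multi-sample annotated VCF per family, a pedigree, and an inheritance model
per family, prioritize the handful of variants compatible with the family's
disease pattern, grade them with ACMG-style evidence, and account for gene
and pathway contributions across the cohort.

The package operates strictly downstream of alignment, variant calling and
functional annotation: the VCF is expected to carry a gene symbol, a
Sequence-Ontology-style consequence term, a population minor-allele
frequency (MAF) and in-silico predictor calls per record. Which population
database supplies the MAF is a study choice, so the INFO field names are
configurable rather than fixed.

## The filtering cascade

Four conjunctive stages are applied per family, in a fixed order that
defines the attrition trace:

1. **Frequency (a1).** A variant is excluded when its population MAF is
   *strictly higher than* the model threshold: 0.5% for autosomal dominant
   (AD) families, 5% for autosomal recessive (AR) families. The strict
   inequality means boundary values (exactly 0.5%/5%) are retained. A
   variant with *no* recorded MAF passes by default: novel variants absent
   from population databases are precisely the interesting ones, and the
   reader never conflates "absent" with "frequency zero". The policy is
   reversible (`missingMafPolicy = "drop"`) for conservative reanalyses.
2. **Consequence (a2).** Only protein-altering or splicing terms are kept:
   missense, stop-gain, start-loss, in-frame and frameshift indels, and
   splice donor/acceptor/region. Terms outside the package's known
   vocabulary are dropped *with a warning*, so annotation drift surfaces
   instead of silently shrinking the candidate set.
3. **Segregation (a3).** Under AD, every genotyped affected member must be
   heterozygous and every genotyped unaffected member homozygous reference.
   Under AR, every genotyped affected member must be homozygous-alternate,
   every *obligate carrier* — an unaffected parent of an affected
   individual — heterozygous, and no genotyped unaffected member
   homozygous-alternate. This operationalization mirrors the classic
   recessive multiplex pattern (homozygous affected children, heterozygous
   unaffected parents) without forcing distant relatives to be carriers.
   Because published analyses differ on whether *all* unaffected members
   were required heterozygous in AR families, the stricter reading is
   available as `arCarrierScope = "all"`; the default is `"parents"`.
4. **Relevance (a4).** A case-folded membership test against a curated
   craniofacial/OFC gene list. The shipped list is a literature-curated
   stand-in for a phenotype-driven screen (crawler/Phenolyzer-style gene
   ranking in the original workflow); it is a data file, versioned and
   replaceable through the cohort config, never code.

Two policy decisions deserve emphasis. **Missing genotypes** are
non-informative by default: an ungenotyped member neither supports nor
vetoes segregation. `missingGenotypePolicy = "strict"` instead requires
every constrained member genotyped — higher specificity, lower recall under
real-world missingness (the simulator demonstrates exactly this trade-off).
**De-novo-like AD patterns** (all affected het, all unaffected hom-ref, yet
no affected parent anywhere) satisfy the AD rule as stated; they are kept
and flagged (`denovo_flag`) rather than silently removed, since dominant
candidates arising in the founder generation merit review, not exclusion.

Only autosomes are processed by default; X-linked and mitochondrial models
are out of scope.

## Classification

Survivors are graded with a deliberately restricted ACMG-style classifier:
only evidence derivable from the annotations and the pedigree itself is
assigned (PVS1, PM2, PP1, PP3 and the benign mirrors BA1, BS1, BP4, plus a
generic `PS_any` slot for user-supplied strong evidence). Criteria that
need external case databases or functional assays (PS1, PS3, PS4, PM5, …)
are intentionally absent — with no per-variant evidence worksheet to
reproduce, pretending to compute them would be false precision.

* PVS1 fires for null consequences only in genes where loss of function is
  an established mechanism (a curated data file, like the relevance list).
* PM2's rarity bound defaults to the active model's own cascade threshold —
  a variant rare enough to survive stage a1 is rare enough for PM2 — and
  can be tightened (`pm2Bound`).
* PP1 requires both a passing segregation filter and at least
  `minSegregations` informative meioses (genotyped parent–child pairs,
  default 3), so a lone genotyped sib-pair cannot claim co-segregation
  support.
* The in-silico consensus is a strict majority over non-absent predictor
  calls; ties are inconclusive. A damaging consensus yields PP3, a benign
  consensus BP4.
* BA1 is stand-alone benign above 5%; BS1 covers the band between
  `bs1Bound` (default 1%) and 5%, so a common variant earns BA1 alone.

The combining table ships as a JSON fixture and is applied by a pure
function; evidence in both directions is resolved to VUS (a conservative
reading of the guideline's conflict clause, extended from the stand-alone
code to any benign-direction evidence). The test suite sweeps all 2^8
evidence subsets against an independently stated version of the rules.

Under these restrictions a rare, segregating, in-silico-damaging missense
variant earns {PM2, PP1, PP3} — one moderate plus two supporting — which
combines to VUS. That is the correct desk verdict for such a variant
(it is "possibly pathogenic", not "likely pathogenic", without functional
data); reaching P/LP requires PVS1-grade consequences or external strong
evidence.

## Cohort accounting

Per-gene and per-pathway statistics count *distinct families* with at least
one pathogenic/likely-pathogenic candidate — a family with two P/LP hits in
one pathway contributes once. Percentages are reported against the full
cohort denominator and rounded half *up* to two decimals (7/30 → 23.33%,
2/30 → 6.67%, 1/30 → 3.33%), matching how such tables are conventionally
printed; base R's round-half-even would print 0.125 as 0.12. The
gene-to-pathway map is a one-to-one data fixture; genes whose pathway
assignment is genuinely uncertain can be reassigned there without touching
code, and the package errors — listing the genes — rather than guessing
when a P/LP gene is missing from the map.

## The simulator

Because family WES data are protected and rarely deposited, every stage is
validated against a gene-dropping simulator:

* **Templates.** A trio (affected parent + affected child), a
  three-generation AD family with a vertical transmission chain, and a
  four-generation, 14-member AR family whose only two affected members are
  second cousins with unaffected parents. The AR template reproduces the
  textbook recessive multiplex pattern: planting a causal variant yields
  two homozygous affected, four heterozygous parents, and a heterozygous
  chain through one shared great-grandparent. Note this transmission needs
  *three* founder introductions (the shared ancestor plus the two
  marry-in parents) — the minimum for non-consanguineous second cousins —
  and `plantCausal` finds a minimal consistent path rather than assuming
  consanguinity. Both templates carry ≥2 affected members because the
  inclusion rule for multiplex families demands it; a single-affected trio
  would additionally force a de novo dominant event, which the simulator
  refuses by design (every emitted allele must trace to a parent).
* **Gene dropping.** Founders draw two alleles Bernoulli(MAF) — i.e.
  Hardy–Weinberg genotype frequencies — and each child receives one allele
  per parent chosen uniformly. Mendelian consistency is checked
  exhaustively in the tests; founder hom-alt frequency and the
  het × hom-ref → het transmission rate are verified against their closed
  forms within 3σ binomial error.
* **Background variants.** Independent sites (no linkage disequilibrium —
  defensible because the cascade treats sites independently) whose MAFs
  span both sides of both thresholds, with a mix of whitelisted and
  non-whitelisted consequences and in-/out-of-list genes, genotyped by
  gene-dropping. By default every background variant is guaranteed to fail
  at least one cascade stage (a background site that would by chance
  segregate perfectly has one affected genotype set to reference), so
  planted-variant recovery can be scored as precision and recall against
  the truth table; both are 1.0 over 100 seeded simulations per model at
  500 background variants each. Penetrance defaults to 1.0 — the
  segregation rules assume it — and lowering it exists to demonstrate the
  filters' failure modes, not to model any study.
* **Determinism.** The seed fixes all randomness; identical configurations
  emit byte-identical VCF/PED/truth files.

What passing these tests does *not* show: performance on real exomes with
linkage structure, annotation errors, pipeline-specific genotype-quality
artifacts, locus heterogeneity or reduced penetrance. The simulator
validates the logic of the cascade, not the biology of any cohort.

## Numerical and interface choices

* Coordinates are 1-based and REF-anchored throughout (VCF convention);
  multiallelic records are split into biallelic sites *before* filtering,
  with per-allele annotations distributed positionally and genotypes
  recoded per alternate (dosage is conserved across the split set), because
  the genotype rules are defined per allele.
* Problem sizes in the shipped tests — 3^5 genotype vectors per model for
  the exhaustive segregation check, 100 seeds × 500 background variants per
  model for recovery, 12,000 founder draws for the Hardy–Weinberg check —
  were chosen as the smallest sizes at which the checks are sharp
  (exhaustive where the space is enumerable, 3σ bounds elsewhere).
* `runFamily`/`runCohort` write a run manifest (tool version, config hash,
  input checksums, per-stage counts) so any candidate table can be traced
  to its inputs; logs and manifests carry attrition counts only, never
  genotypes, as a pedigree-privacy precaution.
* The R functions are the primary interface; `inst/scripts/cleftsift.R` is
  a thin command-line wrapper over them (`simulate`, `filter`, `report`,
  `run-all`).

## Known limitations

No compound-heterozygous, X-linked or mitochondrial models; no kinship or
IBD verification of the declared pedigree; no re-implementation of
network-based phenotype ranking (the relevance list is static data); ACMG
criteria restricted to the annotation-derivable subset; verdicts for real
variants will generally be more pathogenic than this package reports when
external case or functional evidence exists.
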