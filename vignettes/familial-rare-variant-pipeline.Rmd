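---
title: "Familial rare-variant discovery: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial rare-variant discovery: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`famvar` implements a shared-variant prioritization strategy for cohorts
in which each family contributes two or more *affected* relatives and no
unaffected controls. The underlying genetic model is autosomal dominant
with incomplete penetrance: a causal allele is expected to be carried
(usually heterozygous) by every affected member of a family, to be rare
in reference populations, and — across a cohort of families with the
same phenotype — to concentrate in a limited set of genes. This
vignette records the model assumptions, every tunable that matters, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the procedure was genuinely open.

## The filtering cascade

Variants enter as per-family jointly called records, split to one
alternate allele per record with left-aligned, parsimonious alleles
(keys are `chrom:pos:ref:alt`, "chr"-less). Five stages run in order;
each is a conjunction, so the per-record stages commute and the order
only affects where the per-stage counts fall:

1. **Quality** (`quality_filter`). In every affected member with a
   non-reference genotype: depth ≥ 20 reads, alternate-read fraction
   ≥ 0.25, site quality ≥ Q20 and, when genotype qualities are present,
   GQ ≥ 20. The Q20 rule is stated ambiguously in common practice
   (site-level vs genotype-level); we enforce *both*, the conservative
   reading. One failing member removes the family's record: a
   shared-variant candidate with even one unreliable carrier call is
   not trustworthy evidence of co-segregation. A carrier call without
   depth information is an error, never a silent pass.
2. **Sharing** (`sharing_filter`). Every affected member must carry a
   non-reference, non-missing genotype. Missing counts as *not shared*:
   the design requires presence in all affected individuals, and a
   no-call cannot establish presence. Het and hom-alt count alike.
3. **Rarity** (`rarity_filter`). Population MAF ≤ 0.01 *and* fewer than
   5 reported homozygotes (a dominant-model symptom: a truly dominant
   pathogenic allele should essentially never be seen homozygous in
   reference data). Variants absent from the reference database pass:
   absence is stronger evidence of rarity than a borderline frequency.
4. **Consequence / splicing** (`splice_filter`). Only coding and
   splicing classes continue (missense, stop-gain, frameshift,
   in-frame indel, splice). Canonical GT-AG splice-site variants are
   exempt from prediction; splice-*region* variants pass only when an
   upstream splice predictor flagged them damaging, and a missing flag
   removes the variant (reported via a message).
5. **Cross-family exclusion** (`cross_family_exclusion`). If any family
   carries a variant in *some but not all* of its affected members, the
   variant is removed from every family's shared set — partial sharing
   in one family undermines the co-segregation evidence everywhere
   (artefact or non-tracking allele). This is the strictest reading of
   the rule; identical variants *fully* shared in several families are
   retained in each and become the recurrent-variant candidates.

## Control enrichment

Each surviving variant is tested against a population-specific control
cohort with a one-sided Fisher's exact test on allele counts: case
alleles are summed carrier dosages (het = 1, hom-alt = 2) over all
analyzed affected individuals; the case total is twice the analyzed
sample count; control counts come from the control frequency table
(counts reconstructed as `round(AF × allele_total)` when the source
publishes frequencies — the exact test needs integers). The p-value is
the exact hypergeometric upper tail (`stats::phyper`), and the test
suite verifies it against brute-force enumeration of the support and
against `fisher.test(alternative = "greater")`. The cut-off is a raw
p ≤ 0.05 — deliberately no multiple-testing correction at this stage,
which acts as a *filter* tuned for sensitivity, not an inference; FDR
control appears only in the term-enrichment module. Carrier dosage is
summed per individual (not per family); the case total is configurable
for sensitivity analyses.

## Deleteriousness rules

Six predictor calls (SIFT, PolyPhen, MutationTaster, MutationAssessor,
FATHMM, FATHMM-MKL) are ternary; a missing call counts as a
*non-damaging* vote, the conservative choice given incomplete predictor
coverage, and is never imputed. Two rules:

* **strict**: population alternate-allele count < 590 AND
  (loss-of-function ∨ CADD PHRED > 25 ∨ ≥ 5 of 6 damaging votes).
  LoF = stop-gain, frameshift, canonical splice site — splice-region
  variants are *not* LoF, consistent with the splice handling above.
* **recurrent-variant rule**: CADD > 20 AND ≥ 4 of 6 votes. The
  conjunction (rather than CADD alone) is the only rule consistent with
  the shipped five-row worked example, in which a CADD-22.5 variant
  with 3/6 votes is non-damaging.

All "over" thresholds are strict inequalities (`> 25`, `> 20`,
`> 0.75`). The 590 ceiling is *pinned* as a constant: it is described as
the expected allele count under a dominant model at an incidence of
1:3400, but no combination of the reference allele total and that
incidence reproduces it exactly without an unstated penetrance /
heterogeneity factor, so `expected_allele_ceiling()` exposes the formula
for sensitivity analyses while the shipped rule uses the literal value.
A missing CADD score is treated as 0 (and reported); a missing
phenotype rank fails the rank filter.

## Burden, recurrence and CNVs

`gene_overlap()` counts, per gene, the families carrying qualifying
shared variants (a family counts once regardless of how many variants it
carries in the gene) and the family-variant occurrences (an identical
variant shared by two families contributes one occurrence to each; a
multi-family variant total therefore counts per family-occurrence —
the alternative, counting distinct keys once, is recoverable from the
`variant_keys` list column). The gene-length check uses Pearson
correlation by default (`cor`'s default for continuous data; Spearman is
an option) between gene length (summed UTRs + CDS) and the two counts.

CNV screening retains family-level events with ≥ 4 exons, population
frequency ≤ 0.02, present in every affected member; "the same CNV"
across members is ≥ 50% reciprocal overlap with identical copy state —
the matching rule is not specified by the upstream caller conventions,
and reciprocal overlap is the field's standard. Recurrence across
families is by shared overlapped gene when a gene map is supplied,
otherwise by reciprocal overlap between family events.

## Term enrichment

For a query gene set (the multi-family genes), each term is tested with
the hypergeometric upper tail; the effect size is
`strength = log10(observed / expected)` with
`expected = |query| × |term| / |background|`. Strength is undefined
(reported `NA`) at zero overlap. The background defaults to the union of
genes in the loaded collection (the convention of network-based
annotation servers) and is configurable to an exome-wide universe — the
choice shifts p-values, which is why the default is recorded here.
Benjamini–Hochberg runs *within each category* (biological process,
cellular component, molecular function, keyword), delegated to
`stats::p.adjust(method = "BH")` and verified against a hand-rolled
step-up in the tests. Only over-representation is tested. P-values from
interaction-database servers will not numerically match (their internal
test is not documented); only the strength formula is portable.

## Quality control

* **Ti/Tv** is transitions (A↔G, C↔T) over transversions among
  biallelic SNVs; ~2.0–3.0 is healthy for exomes. Zero transversions is
  an explicit error (not `Inf`); zero transitions is a plain 0.
* **Het/hom ratio** excludes indels and multi-allelic sites inside the
  operation; zero hom-alt calls is an error.
* **VAF screen**: at heterozygous calls the alternate-read fraction
  should mass near 0.5; the flag raises when more than 10% (tunable) of
  het calls fall in (0.1, 0.35) ∪ (0.65, 0.9), the signature of reads
  from a second individual.
* **KING-robust kinship** uses the between-family estimator
  φ̂ = (N_het,het − 2 N_opp) / (N_het(i) + N_het(j)) over mutually
  observed biallelic SNPs, with the standard powers-of-two degree bins
  (0.354 / 0.177 / 0.0884 / 0.0442). The implementation is validated by
  Mendelian pedigree simulation (duplicates → 0.5, parent-offspring and
  full siblings → 0.25, unrelated → 0) rather than by numerical
  equality with any particular external tool. The default floor of 1000
  overlapping SNPs guards against noisy estimates.
* **PCA**: cohort-MAF ≥ 0.05 variants, mean-imputed missing dosages,
  centred and variance-standardized, `stats::prcomp`, top 10
  components. A sample is an outlier beyond 6 MADs from the cohort
  median on PC1/PC2 (configurable components). The *pipeline* excludes
  a family only when more than half its members are outliers **on PC1
  alone**: in cohorts of relatives the later components separate family
  cliques rather than ancestry, and family exclusion driven by PC2
  would discard genuine families. This automates what is usually a
  visual-inspection call, so the MAD rule is plumbing, not biology.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end: 29
families — 23 sibling duos, 5 parent+2-children trios, one 5-member
family — totalling 66 affected samples with 54 females (the published
cohort composition); a control cohort of 2000 diploid individuals
simulated at the allele-count level only (the analysis uses nothing but
its frequencies); population annotations anchored to a reference of
125,748 diploid exomes. Family-shared rare variants are planted at the
sharing stage with Poisson means 104 (duos) and 52 (trios) — the
reported per-family means; the 5-member family uses 30, a value the
source material does not constrain — drawn from the cascade-passing
stratum of a 20,000-variant background panel (~2,600 genes, gene
assignment weighted by gene length so a length–burden correlation
emerges naturally). Downstream totals (after artifacts, cross-family
exclusion and the Fisher screen) are therefore emergent draws, not
calibrated constants. Planted causal genes (default 5, each fully
shared in 3 families) get MAF in (1e-4, 1.5e-3), CADD in (26, 35),
~damaging predictor profiles, phenotype rank > 0.8 and zero control
alleles, so they are constructed to survive every stage — tests assert
100% recovery, which validates the plumbing, not the statistics.
Planted QC defects: one contaminated sample (mixing fraction 0.15,
implemented as a het-VAF shift on ~45% of its calls), one
divergent-ancestry family (Balding–Nichols frequencies at Fst 0.05 on
the common panel), and a 5% low-VAF artifact rate on shared variants.
Predictor calls are tied to CADD through a logistic link
(p = logit⁻¹((CADD − 22)/2.5)) so the ensemble vote and CADD agree the
way real annotations do. All frequencies are emitted at 6 significant
digits so tables round-trip through text files.

What the generator does **not** emulate: linkage disequilibrium,
regional mutation-rate structure, sequencing-error haplotypes,
annotation errors, relatedness *between* families, CNV signal in read
depth (CNV fixtures are call tables), and the ascertainment quirks of
real allele-frequency databases. Passing tests on synthetic data
therefore demonstrate that the rules are implemented as specified and
recover what they are designed to recover — not that the thresholds are
optimal for any real cohort.

## Numerical and degenerate-input conventions

Determinism: one integer seed fixes every simulated quantity
(`withr::with_seed`), writers emit fixed column and row orders, and the
pipeline is deterministic given its inputs, so reruns are
byte-identical. Fisher and hypergeometric p-values are exact tail sums,
not approximations; the suite pins them to enumeration at 1e-12.
Degenerate inputs error loudly rather than return sentinels: empty
allele totals, missing carrier depths, kinship below the SNP floor,
fewer than 3 samples for PCA, fewer than 3 genes for correlation, empty
query gene sets. Allele normalization trims the common suffix then
prefix (keeping one base each side) and is idempotent. Problem sizes in
the shipped tests — a 6-family unit cohort, the 29-family default
cohort, 50k-SNP kinship pedigrees, 6000-SNP PCA panels, 4000-variant
null screens — were chosen as the smallest sizes at which the sampling
distributions of the checked statistics are comfortably inside their
asserted tolerances.

## Known limitations

Only autosomes are handled (no X-specific allele totals). The dominant,
fully-shared model will miss recessive, compound-heterozygous and
mosaic architectures by construction. The cross-family exclusion is
global and strict: a single genotyping error in one family can remove a
true variant everywhere. The Fisher screen treats control frequencies
as fixed (no sampling error on the control side beyond the exact test's
margins). Kinship degrees beyond third are not distinguished, and the
PCA outlier rule assumes a predominantly homogeneous cohort.
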