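---
title: "Methods: the RDReanalysis re-prioritization engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RDReanalysis re-prioritization engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its model and design choices:
what the filter stack computes, which parameters matter and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and where the design was genuinely open.

## The re-prioritization model

The engine addresses periodic reanalysis of undiagnosed rare-disease cases.
Its unit of work is one *index case* (the affected proband of a family)
with a multi-sample VCF, a pedigree, and a standardized phenotype record
(HPO terms, ORDO/OMIM codes, submitting-network tag, reported
consanguinity). Queries run sequentially per case; one corrupt input
isolates that case, never the cohort.

A variant survives the default first-round preset — designed to surface
clear, already-known pathogenic variants at minimal interpretation cost —
iff all of the following hold:

1. **Rarity, external**: population allele frequency strictly below
   `af_external_max` (default 0.01). A variant absent from the frequency
   table is treated as frequency 0: absence from a large reference
   population is itself evidence of rarity, and the filter is on *observed*
   frequency.
2. **Rarity, internal**: cohort allele frequency strictly below
   `af_internal_max` (default 0.02), computed over one representative per
   family — the index — so that a large sequenced family cannot push its own
   causal variant over the threshold. An index whose per-family VCF lacks
   the site is counted homozygous-reference (a sequenced experiment with no
   alt call), whereas an explicit `./.` leaves the denominator. This
   family-deduplicated definition is a documented package choice; upstream
   systems do not specify one.
3. **Panel membership**: the gene carries the variant and belongs to the
   case's panel — a curated network panel, or an on-the-fly panel built from
   the case's HPO terms.
4. **Known pathogenicity**: some assertion for the variant is pathogenic or
   likely pathogenic (P/LP). Aggregation is deliberately
   sensitivity-oriented (`any` assertion qualifies, even when the collapsed
   significance is `conflicting`), because the output feeds human review;
   a `concordant` mode is available for stricter rounds. Disorder match is
   *not* enforced at filter time — the condition string travels to the
   report for the interpreter, who judges clinical fit.
5. **Carrier status**: the index carries at least one alt allele.

Segregation verdicts, compound-het pairs, ROH membership, consanguinity and
the CNV cross-check are attached to surviving rows but never filter in the
preset: interpreters see inconsistent-segregation rows too. A
`segregation_filter` switch enables hard filtering for later rounds, and a
consequence whitelist exists but is off by default (the P/LP requirement
subsumes an impact filter).

The conjunction is evaluated as a pure per-variant predicate, which gives
two useful invariants for free: application order cannot change the result,
and tightening any threshold (or shrinking the panel) can only remove rows.

## Genotype representation

Genotypes are stored as alt-allele dosages with an explicit per-cell ploidy
(2 for autosomes and female X; 1 for male X and mitochondrial calls), taken
from the GT string itself. Multi-allelic sites are decomposed on read into
one record per alternate allele; inputs are assumed left-aligned and
normalized by the upstream calling pipeline — the package does not
re-normalize indels, and documents that as a requirement. Coordinates are
1-based inclusive (VCF convention) everywhere; BED-dialect CNV input is
converted on read, and `chr` prefixes are stripped (`MT` for mitochondria).

A missing genotype (`./.`) is *unknown*, never homozygous-reference. The
consequences are deliberate: an uncalled index is always inconsistent; a
parent who is in the pedigree but uncalled at a site cannot *confirm* a de
novo event (the AD-de-novo verdict fails with that reason); for every other
model an uncalled relative is simply non-constraining.

## Segregation semantics

Model rules operate on the genotyped members available:

* **AD-denovo** — index heterozygous, both parents genotyped hom-ref.
* **AD-inherited** — index heterozygous, at least one affected relative
  carries the alt, no unaffected relative does. With
  `allow_reduced_penetrance`, an unaffected carrier parent is accepted as
  transmission evidence instead of a contradiction — some pathogenic
  variants are not fully penetrant.
* **AR-hom** — index homozygous alt, every genotyped parent heterozygous.
* **XL** — on X only: male index hemizygous alt with mother het or hom-ref
  (de novo); female index homozygous alt; an unaffected carrier father is
  inconsistent.
* **MT** — on MT only: the index carries the alt.
* **mosaic-candidate** — index carries the alt with allelic fraction below
  `mosaic_af_bound` (default 0.30). Purely a reporting flag.

Singletons (no genotyped relatives at all) return consistent for every
model with reason "no relatives — unconstrained", *gated by the index
genotype*: an index that is heterozygous can never be AR-hom-consistent,
relatives or not. This gate is a package decision: vacuous consistency
should not leak rows whose index genotype already contradicts the model.
For non-trio, non-singleton families the trio rules generalize to whatever
relatives are genotyped.

Compound-het pairing requires, with both parents genotyped, one
paternal-only and one maternal-only heterozygous variant in the same gene
(trans by parental origin); a variant carried by both parents cannot anchor
a phase-known pair. Without parents, all `C(k, 2)` het pairs are reported
phase-unknown.

## Runs of homozygosity and consanguinity

ROH are called greedily per contig on the index's called diploid sites:
runs start and end on homozygous sites, tolerate at most `roh_max_het`
embedded heterozygous calls (default 1, absorbing isolated genotyping
errors), and must span at least `roh_min_length_bp` (default 1 Mb, the
conventional floor for autozygosity in outbred-to-consanguineous exomes)
*and* contain at least `roh_min_sites` called sites (default 25). The
site-count minimum matters because exome sites are sparse: a 1 Mb window
with three sites says nothing about homozygosity. Greedy left-to-right
extension makes segments non-overlapping and maximal, and two qualifying
runs separated by more than `roh_max_het` hets never merge.

FROH is the fraction of the autosome covered by ROH; a case at or above
`froh_threshold` (default 0.03, parental relatedness closer than second
cousins) is called consanguineous, alongside the *reported* consanguinity
flag from the phenotype record. The package validates the estimator by
gene-dropping a three-generation first-cousin pedigree over a human-scale
genome (22 × 130 Mb, Poisson crossovers at 1 cM/Mb, markers every 50 kb
with allele frequencies 0.1–0.5): expected F = 1/16, and the mean inferred
FROH over 20 replicates recovers it within ±0.02. Per-genome variance of F
is real and large — single replicates legitimately range roughly 0.02–0.12.

X pseudo-autosomal handling is out of scope of the ROH caller (X is
excluded from autosomal ROH entirely), a simplification documented here.

## The candidate table

One row per (case, variant), 31 fixed columns (`candidateTableColumns()`),
sorted by case id then genomic position, with knowledge-table version
stamps as `##` header lines. Frequencies print to 6 significant digits;
everything else round-trips bit-exactly. The report is TSV only: a
spreadsheet mirror would be convenient for distribution but cannot be
byte-compared, and TSV imports everywhere.

Case-level accounting follows the precedence
`solved > under_evaluation > het_AR_candidate > unsolved`; a case carries
exactly one tag. Reported percentages use half-up rounding at the printed
precision (`roundHalfUp`), and means print to two decimals.

## What the synthetic cohort emulates

`simulateCohort()` generates, from a single seed, a fully self-contained
cohort: per-family VCFs, PED, phenopacket-style JSON, knowledge tables with
controlled assertion years, per-network panels, a small ontology, CNV
decoys and a planted-variant truth table. Its defaults are the study
conditions the engine is tested under:

* 200 families; structure mix 28% trio / 68% singleton / 4% other.
* A toy genome of two 10 Mb autosomes, a 5 Mb X and MT, carrying 60
  autosomal disease genes (15 AD + 15 AR per autosome), 12 decoy genes
  outside every panel, 6 X-linked genes and one mitochondrial gene — small
  enough that ROH logic is exercised cheaply.
* Background variants drawn from a shared pool with log-uniform population
  frequencies over [1e-5, 0.5], so both rarity filters have bite; 120
  records per family; background assertions are benign/VUS only.
* Planted causative variants under AD-de-novo, AD-inherited, AR-hom,
  AR-hom-in-ROH (with a ≥ 1.2 Mb homozygous flank and reported
  consanguinity), AR compound-het (trans by parental origin), X-linked
  (male index, carrier mother), mitochondrial, mosaic (allelic fraction
  0.05–0.25) and lone-het AR models, at a mix dominated by dominant and
  recessive disease; plus 10% lone-het-AR and 10% negative-control
  families. Planted variants carry P/LP assertions (P:LP ≈ 70:30), panel
  membership and rare frequencies (log-uniform over [1e-5, 5e-3], 20%
  unobserved), so the preset detects them by construction; negative-control
  decoys are P/LP and in-panel but drawn at frequency 0.02–0.10, failing
  rarity.
* First-report years are drawn per bin to mirror realistic knowledge lag
  (genes: 13% ≥ 2017, 9% 2015–2016, 31% 2010–2014, 47% earlier; variant
  assertions: 39/21/31/9).

What it does **not** emulate: sequencing error and coverage dropout,
linkage disequilibrium, realistic mutation-rate or gene-length effects,
population structure in the internal frequency, multi-allelic sites, or
annotation noise (every planted assertion is correct). Passing the
end-to-end tests therefore demonstrates the *logic* of the stack — recall
of detectable planted variants is exactly 1.0 by construction, lone-het
flags and negative controls behave — not robustness to dirty real-world
annotation. The property suites (brute-force ROH equivalence, exhaustive
segregation truth tables, interval-overlap and set-union oracles) carry the
correctness burden the simulator cannot.

Internal-frequency note for small cohorts: a homozygous planted variant
contributes 2/(2N) to the internal frequency, so below ~60 families a
recessive causative variant legitimately exceeds the 0.02 ceiling and is
filtered. The shipped test and acceptance cohorts use N = 200, where every
planted class passes with margin.

## Numerical and degenerate-input choices

* Duplicate assertion keys collapse order-independently: concordant
  pathogenic-direction sets to the most severe label, concordant benign to
  the most severe benign label, anything mixed to `conflicting`; the
  `any_plp` flag and the earliest P/LP year are kept separately.
* Duplicate frequency keys keep the maximum (conservative for rarity).
* On-the-fly panels match a patient term against genes annotated to the
  term or any descendant (a patient coded "Seizure" recruits genes
  annotated to seizure subtypes); the ontology root and the
  inheritance/modifier/frequency branches never match; `expand = FALSE`
  disables descendant expansion. Ranked mode orders by match count, ties
  broken lexicographically for reproducibility. Zero usable terms yield an
  empty panel plus a warning, and the engine refuses to run such a case
  without an explicit panel.
* Every output is deterministically ordered (case id, then contig rank,
  position, ref, alt); reruns on identical inputs are byte-identical.
* Genotype-quality knobs (`min_depth`, `min_gq`) exist but default to off;
  the preset's P/LP requirement already excludes most artefacts, and the
  upstream pipeline is assumed to have applied its own QC.

## Problem sizes

The shipped test suite runs the full stack on one 200-family cohort
(simulated once per run, ~50 s to reanalyse), exhaustive 27-genotype
segregation enumerations, 20-replicate FROH recovery, and randomized
oracle comparisons at a few hundred items each — sizes chosen so the whole
suite completes in a few minutes while every code path is exercised.

## Known limitations

* ACMG classification is consumed as an annotation, never computed.
* No liftover; a single genome build is assumed throughout.
* ORDO codes are carried as labels; no ontology reasoning is done on them.
* The ROH caller is exome-grade (site counts, not LOD scores) and will
  under-call in cohorts with very uneven capture.
* Phasing is parental-origin only; no statistical phasing for parent-less
  compound hets — those pairs stay phase-unknown by design.
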