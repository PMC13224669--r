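---
title: "Quantifying tissue-specific gene dosage disruption by structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-specific gene dosage disruption by structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrsv)
```

## The problem

A structural variant (SV) that removes or duplicates coding sequence changes
the dosage of the genes it touches — but not uniformly across the body. A
gene expresses different isoform mixtures in different tissues, so a deletion
that destroys the dominant isoform of a gene in cerebellum may barely dent
the same gene's output in retina. Interpreting SVs in Mendelian disease
therefore needs a *tissue-aware* measure of dosage impact, not just a binary
"exonic / non-exonic" label.

`tdrsv` centres on the **Transcript Disruption Ratio (TDR)**: for a variant
$v$, gene $g$ and tissue $t$,

$$
\mathrm{TDR}_{g,t}(v) \;=\;
\frac{\sum_{i \in D(v,g)} \mathrm{TPM}_{i,t}}
     {\sum_{i \in A(g)} \mathrm{TPM}_{i,t}},
$$

where $A(g)$ is the set of all annotated transcripts of $g$, $D(v,g)
\subseteq A(g)$ the subset the variant disrupts, and $\mathrm{TPM}_{i,t}$
the tissue-median expression of transcript $i$. TDR lies in $[0,1]$: 0
means the variant spares every expressed isoform in that tissue, 1 means it
hits all of the gene's expressed output. A whole-gene deletion has TDR 1 in
every tissue where the gene is expressed; the interesting cases are partial
deletions whose TDR swings with the tissue's isoform mixture.

## What counts as "disrupted"

The disruption predicate differs by variant class, reflecting the physical
consequence of each rearrangement:

* **Deletions and duplications** disrupt a transcript when the SV interval
  overlaps at least one base of its **coding sequence** (CDS). Partial
  duplications are treated like deletions here: a tandem copy of part of a
  CDS breaks the reading frame of the duplicated allele's product just as a
  deletion does.
* **Non-coding transcripts** carry no CDS yet belong to the gene's
  expression denominator (short-read quantification cannot cleanly separate
  them, and they can be a substantial expression fraction). For these,
  disruption is defined on **exon** overlap. The package exposes
  `protein_coding_ratio()` to inspect how much of a gene's expression the
  coding isoforms carry; for most genes the coding share exceeds one half,
  so this reconciliation rarely dominates a TDR value.
* **Insertions** are stored as zero-width anchors with a declared inserted
  length. An insertion disrupts a transcript when its anchor point $p$ falls
  inside a qualifying CDS/exon interval $[s, e)$, i.e. $s \le p < e$. The
  same containment convention is used when classifying an insertion's
  positional context.
* **Inversions** disrupt a transcript only when at least one breakpoint
  falls strictly inside the transcript span *and* the inverted segment
  overlaps qualifying sequence. An inversion that contains an entire gene
  relocates it intact — reading frame and exon structure survive — so it
  disrupts nothing, regardless of how much expression the gene has.
* **Stop-gain point variants** (`compute_tdr_stopgain()`) disrupt the
  transcripts whose CDS contains the variant position, modelling
  nonsense-mediated decay of exactly those isoforms. No 50-nt last-exon
  escape rule is applied: disruption is CDS containment only. This slightly
  overestimates decay for last-exon stop codons, a deliberate simplification
  while the escape rule's tissue behaviour remains hard to calibrate.

A gene with zero total TPM in a tissue yields an **undefined** TDR (`NA`),
never 0. A silent gene cannot be dosage-disrupted in that tissue, but
reporting 0 would be indistinguishable from "the variant misses every
expressed isoform" and would silently absorb annotation errors. Undefined
rows are excluded from prioritization.

## The quality-control workflow

Raw breakpoint calls are noisy, and the error mode depends on SV size. The
workflow in `apply_qc_workflow()` treats each size tier with the evidence
type that is reliable there:

| Tier | Definition | Retention rule |
|---|---|---|
| SHORT | < 200 bp (DEL/DUP/INS) | re-genotyped call is HET or HOM in ≥ 1 sample |
| MEDIUM | 200 bp ≤ length < 100 kb, DEL/DUP | same-type interval from either supporting caller with reciprocal overlap > 0.8 |
| LONG | ≥ 100 kb, DEL/DUP | same-type read-depth (CNVnator-style) interval with reciprocal overlap > 0.8 |
| OTHER | INV, INS ≥ 200 bp | retained unconditionally |

Reciprocal overlap is `min(ov/len(a), ov/len(b))`; all thresholds are
applied with their stated strictness — RO of exactly 0.8 does **not**
corroborate, 200 bp is MEDIUM, not SHORT. Corroboration is type-matched: a
duplication call cannot validate a deletion, even with perfect overlap,
because the two imply opposite copy-number changes. Inversions shorter than
200 bp fall outside every rule; they pass through flagged `untested_tier`
rather than being dropped, mirroring the pass-through treatment of
inversions generally while keeping the decision visible downstream. Calls in
problematic regions (HLA, decoys, high copy number) are removed beforehand
by `exclude_regions()` on an any-overlap basis. Sample-level alignment
quality (`bam_qc_gate()`) requires coverage > 15x, chimeric fraction
< 0.05% and contamination < 5%, all strict.

## The background allele-frequency database

Rarity is assessed against multiple ancestry cohorts because an SV common
in any one population is unlikely to cause a rare dominant disorder.
`cluster_svs()` merges per-cohort call sets with single-linkage clustering
inside each SV type, linking two calls when their reciprocal overlap
strictly exceeds 0.8. Single linkage (rather than clique merging) matches
the behaviour of the standard cross-sample SV mergers and makes the result
independent of cohort input order; the package verifies the clustering
against naive connected components in its tests. Insertions are zero-width,
so interval overlap is meaningless; they merge on anchor distance ≤ 100 bp
plus inserted-length ratio > 0.8, both exposed as parameters.

Each cluster's representative is the member with the most carriers (ties:
smallest start, then end). Per-population AF counts one allele per HET and
two per HOM over twice the non-missing genotypes; a population with no
member contributes AF 0 — an SV unseen in a genotyped cohort is evidence of
rarity there, not missing data. The combined **background AF is the maximum
across populations**, and an SV is *rare* when that maximum is strictly
below 0.01. Patient call sets are annotated against the database by the
same same-type RO > 0.8 match (`annotate_background_af()`).

## The prioritization cascade

`run_cascade()` applies, in order: **RAW** (calls carried by the patient) →
**QC** (tiered workflow above) → **RARE** (background AF < 0.01) →
**DOSAGE_CLASS** (exonic/whole-gene DEL or DUP, or exonic INV — the
categories with strong expression-outlier enrichment; insertions and purely
intronic CNVs do not qualify) → **TDR_GENELIST** (some curated disease gene
with defined TDR > 0.25 in the disease tissue) → **INHERITANCE** →
**REPORT**. Counts are reported per stage and every input SV is traced to
the stage where it stopped.

The inheritance stage checks zygosity consistency: a heterozygous hit
passes for a dominant gene (OMIM mode AD) or one that is dosage-sensitive
in the disease tissue (MoDs percentile < 0.3, strict); a recessive-only
gene needs a homozygous hit or a supplied second hit in the same gene.
Three deliberate design choices here:

* Genes absent from the annotation tables **pass flagged** `unannotated` —
  curated panels include candidate genes without OMIM entries, and dropping
  them silently would hide exactly the novel findings the cascade exists
  for.
* True pedigree segregation needs family genotypes, which are out of scope;
  a hook accepts an external per-SV segregation verdict that overrides the
  zygosity logic.
* Overlap with known pathogenic SVs (same type, RO > 0.8) is **annotation
  only**, never a gate: final pathogenicity calls remain a manual,
  phenotype-aware step.

The TDR > 0.25 reporting threshold is an empirical operating point for
"likely dosage-relevant"; it is a parameter (`tdr_threshold`) everywhere it
appears.

## Expression outliers and validation statistics

The statistics that validate TDR against observed expression live in the
outlier module. Per tissue, log-scale expression is residualized against
**supplied covariates** by ordinary least squares and standardized per gene
(`residualize_and_zscore()`). Hidden-factor estimation (PEER-style) is an
external preprocessing method, not re-implemented here; callers may supply
top expression principal components as covariates to the same effect.
Outliers are strict: $|z| > 2$ single-tissue, $|\mathrm{median}_t z| > 2$
multi-tissue.

Carrier–outlier enrichment uses the 2×2 odds ratio with a Woolf
confidence interval, $\exp(\log \mathrm{OR} \pm 1.96\sqrt{\sum 1/n_{ij}})$,
Haldane-corrected (+0.5 all cells, flagged) when a cell is empty, and a
two-sided Fisher exact p-value; tables with an empty margin are reported
undefined rather than corrected into existence. The TDR–expression
correlation defaults to Spearman — the relationship is monotone but has no
reason to be linear, and Spearman is robust to the heavy left tail that
homozygous deletions produce — with Pearson available. For non-coding
deletions (TDR = 0), `tss_bin_enrichment()` bins carriers by distance to
the nearest strand-aware TSS; default bin edges 0, 2 kb, 10 kb, 100 kb,
1 Mb are a package choice spanning promoter-proximal to distal regulatory
space.

## The synthetic-data generator

Every input the toolkit consumes can be produced deterministically by the
fixture module: a toy two-chromosome genome (`generate_annotation()`) with
multi-isoform genes of mixed biotype, UTR-trimmed CDS, one MANE transcript
per gene, and per-tissue log-normal TPM with forced dominant-isoform
switches between tissues; background cohorts with planted SVs
(`generate_cohort()`) whose context class, first-tissue TDR (by rejection
sampling of breakpoints, tolerance ±0.05) and per-population AF (exact
carrier counts) are all known; patient cohorts (`generate_patient_cohort()`)
hiding one pathogenic SV per patient among ~90 benign calls spanning every
failure mode of the cascade; and expression (`generate_expression()`) in
which a heterozygous deletion carrier's linear expression is multiplied by
$1 - 0.5\,\mathrm{TDR}$ — one of two copies lost over the disrupted
fraction, the simplest model consistent with haploinsufficiency — with
$1 - \mathrm{TDR}$ for homozygous loss and $1 + 0.5\,\mathrm{TDR}$ per
extra duplicated copy, plus log-scale Gaussian noise (sd 0.3 by default)
and an optional known batch confounder.

The generator guarantees its own truth labels: quality-control decoys are
re-placed until they do not sit on a validated SV's footprint, and a
decoy's deliberately weak support interval is suppressed if it would
corroborate any other planted SV.

What the generator does **not** emulate matters for interpreting green
tests: breakpoint uncertainty and caller-specific biases, genotyping error
correlated with SV size, linkage between variants, population structure
within a cohort, mosaicism, and the full complexity of real gene annotation
(overlapping genes, readthrough transcripts, pseudogene parents). Passing
tests show the implementation is faithful to its stated rules and recovers
planted signal under the stated noise model — not that the thresholds are
optimal on real cohorts.

## Numerical and scale choices

All coordinates are 0-based half-open internally; conversion to and from
VCF/GTF 1-based inclusive happens only at I/O boundaries. Clustering and
representative selection break ties deterministically (carrier count, then
start, then end) and the member pool is canonically sorted first, so
results are independent of input order. Problem sizes in the test suite —
1,000+ random SV–gene pairs against a per-base brute-force oracle, 200-SV
clustering against naive connected components, 100 validated + 100 decoy
SVs through QC, 50 synthetic patients through the cascade, n = 500 carriers
for direction-of-effect recovery, 100 replicates for null CI coverage —
are chosen so the whole suite exercises every rule at comfortable
statistical resolution while remaining quick to run on a laptop.

## Known limitations

TDR measures disruption of transcript structure only; it is blind to
regulatory losses (a promoter deletion has TDR 0 yet can abolish
expression — the TSS-distance module quantifies exactly this blind spot),
to gain-of-function and fusion effects of duplications and inversions, and
to dosage effects mediated by topological domain disruption. MoDs scores,
constraint scores and disease gene lists are consumed as inputs and
inherit their sources' biases. The compound-heterozygous logic accepts a
user-supplied second-hit list rather than integrating an SNV pipeline.
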