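# tdrsv — tissue-specific gene dosage impact of structural variants

Structural variants (SVs) — deletions, duplications, insertions,
inversions — alter gene dosage, but how much dosage a given SV removes
depends on the tissue: genes express different isoform mixtures in
different tissues, so a deletion can destroy most of a gene's output in
one tissue while sparing it in another. `tdrsv` is an R toolkit for
interpreting SVs in that tissue-aware way, aimed at rare-disease genomics:
given SV call sets, gene annotation and tissue expression tables, it
quantifies per-variant dosage impact and prioritizes candidate pathogenic
SVs in patient cohorts.

The core metric is the **Transcript Disruption Ratio (TDR)**: for variant
*v*, gene *g* and tissue *t*,

```
TDR_{g,t}(v) = Σ_{i ∈ disrupted(v,g)} TPM_{i,t}  /  Σ_{i ∈ transcripts(g)} TPM_{i,t}
```

the fraction of the gene's total tissue expression carried by the
transcripts the variant disrupts (CDS overlap for coding isoforms, exon
overlap for non-coding ones; breakpoint rules for inversions; CDS
containment for stop-gain SNVs). TDR ∈ [0, 1], is 1 for whole-gene
deletions wherever the gene is expressed, and is undefined (`NA`) where
the gene is silent.

Around the metric the package implements the full interpretation workflow:

* **sv I/O** — Manta-style SV VCF reading/writing (BND pairs converted to
  inversions), BED intervals, flat TSV; 0-based half-open coordinates
  internally.
* **Quality control** — size-tiered filtering: short SVs by re-genotyping
  confirmation, medium/long CNVs by > 80% reciprocal-overlap corroboration
  from independent callers, problematic-region exclusion.
* **Background allele frequencies** — cross-cohort single-linkage merging
  of same-type SVs (RO > 0.8), per-population AFs, maximum-AF assignment,
  rare = AF < 0.01.
* **Prioritization cascade** — QC → rarity → dosage class (exonic or
  whole-gene CNVs, exonic inversions) → TDR > 0.25 in the disease tissue
  within curated gene lists → inheritance/dosage-sensitivity consistency
  (OMIM modes, MoDs < 0.3) → per-patient report with full stage trace.
* **Outlier statistics** — covariate residualization and Z-scores, strict
  |Z| > 2 outlier calls, carrier–outlier enrichment odds ratios (Woolf CI,
  Fisher p), TDR–expression correlation, TSS-distance enrichment for
  non-coding deletions.
* **Synthetic data** — a deterministic generator producing every input
  format with planted ground truth (contexts, target TDRs, exact allele
  frequencies, validated/decoy support evidence, dosage-responsive
  expression), used throughout the tests.

## Worked example

Everything below runs on synthetic data generated by the package itself.

```r
library(tdrsv)

spec <- fixture_spec(seed = 42)          # 30 genes, 3 tissues, 2 cohorts
ann  <- generate_annotation(spec)        # gene models + transcript TPM
co   <- generate_cohort(spec, ann)       # planted SVs + support evidence

# tiered QC: re-genotype confirmation / reciprocal-overlap corroboration
pool <- do.call(rbind, lapply(co$cohorts, function(x) x$variants))
pool <- sv_set(pool[!duplicated(pool$id), ])
qc   <- apply_qc_workflow(pool, co$evidence)
head(qc$audit, 3)
#>         id   tier                 rule pass                    reason
#> 1 plant001 MEDIUM ro_lumpy_or_cnvnator TRUE best same-type RO = 0.970
#> 2 plant003 MEDIUM ro_lumpy_or_cnvnator TRUE best same-type RO = 0.970
#> 3 plant005 MEDIUM ro_lumpy_or_cnvnator TRUE best same-type RO = 0.970

# background AF database and TDR per SV x gene x tissue
db  <- build_background_db(co$cohorts)
svs <- annotate_background_af(qc$passed, db)
tab <- compute_tdr(svs, ann$genes, ann$tpm, c("tissueA", "tissueB"))
head(subset(tab, tissue == "tissueA"), 5)
#>   variant_id gene_id  tissue n_disrupted tpm_disrupted tpm_total   tdr
#> 1   plant001    G001 tissueA           3         146.5     147.5 0.993
#> 3   plant003    G003 tissueA           4         106.3     107.3 0.991
#> 5   plant005    G005 tissueA           2          54.0     154.0 0.351
#> 7   plant007    G007 tissueA           3          93.9      93.9 1.000
#> 9   plant009    G009 tissueA           2          50.6      50.6 1.000
```

`plant005` illustrates the point of the metric: it removes only 35% of
G005's expression in tissueA — whether it matters depends on the tissue,
and the same SV can score differently in tissueB.

A patient cohort with one planted pathogenic SV each, run through the
cascade:

```r
pc  <- generate_patient_cohort(spec, ann, co, n_patients = 3)
pat <- annotate_background_af(pc$patients, db)
res <- run_cascade(pat, "patient001", ann$genes, ann$tpm, pc$tissue,
                   pc$gene_list, pc$annotations, evidence = pc$evidence)
res
#> candidate SV cascade:
#>   RAW           87
#>   QC            84
#>   RARE          36
#>   DOSAGE_CLASS  16
#>   TDR_GENELIST  4
#>   INHERITANCE   1
#>   REPORT        1
res$report[, c("sv_id", "svtype", "genes", "max_tdr", "context", "genotype")]
#>      sv_id svtype genes   max_tdr context genotype
#> 1 patho001    DEL  G001 0.9932193  EXONIC      HET
```

Of 87 carried calls, common polymorphisms die at RARE, non-coding and
unlisted-gene variants at the dosage/TDR stages, a heterozygous
recessive-gene hit at INHERITANCE — and the report contains exactly the
planted pathogenic deletion.

A command-line front end over the same functions is provided at
`inst/cli/tdrsv.R` (subcommands `convert`, `filter`, `popfreq-build`,
`popfreq-annotate`, `tdr`, `prioritize`, `simulate`).

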