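#' Bundle per-gene annotation tables for prioritization
#'
#' @param mods numeric matrix of dosage-sensitivity percentiles in `[0, 1]`
#'   (rownames = gene ids, columns = tissues); values < 0.3 mark a gene as
#'   dosage-sensitive (likely haploinsufficient) in that tissue.
#' @param omim data.frame with columns `gene_id` and `modes` (`;`-joined
#'   subset of `AD`, `AR`, `XL`).
#' @param constraint optional data.frame of gene constraint scores
#'   (`gene_id` plus score columns); annotation only, never a gate.
#' @param clinvar_svs optional data.frame of known pathogenic SVs (`chrom`,
#'   `start`, `end`, `svtype`, `id`); matches (same type, reciprocal overlap
#'   > 0.8) are annotated, never used as a filter.
#' @return An object of class `gene_annotations`.
#' @export
gene_annotations <- function(mods = NULL, omim = NULL, constraint = NULL,
                             clinvar_svs = NULL) {
  if (!is.null(mods)) {
    stopifnot(is.matrix(mods), all(mods >= 0 & mods <= 1, na.rm = TRUE))
  }
  structure(list(mods = mods, omim = omim, constraint = constraint,
                 clinvar_svs = clinvar_svs), class = "gene_annotations")
}

#' Dosage-class stage of the cascade
#'
#' An SV is a plausible dosage disruptor when it is a deletion or
#' duplication with an exonic or whole-gene context for some gene, or an
#' inversion with an exonic context. Insertions and purely intronic or
#' intergenic CNVs do not pass this stage.
#'
#' @param svs an [sv_set()].
#' @param contexts data.frame from [classify_context()].
#' @return data.frame: `sv_id`, `pass`, `genes` (`;`-joined qualifying
#'   genes).
#' @export
dosage_class_filter <- function(svs, contexts) {
  v <- svs$variants
  res <- lapply(seq_len(nrow(v)), function(i) {
    cx <- contexts[contexts$sv_id == v$id[i], , drop = FALSE]
    ok <- if (v$svtype[i] %in% c("DEL", "DUP")) {
      cx$context %in% c("EXONIC", "WHOLE_GENE")
    } else if (v$svtype[i] == "INV") {
      cx$context == "EXONIC"
    } else rep(FALSE, nrow(cx))
    data.frame(sv_id = v$id[i], pass = any(ok),
               genes = paste(cx$gene_id[ok], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' TDR and disease-gene-list stage of the cascade
#'
#' An SV passes when at least one gene on the curated disease gene list has
#' a defined TDR strictly greater than `threshold` in the disease-relevant
#' tissue. Genes silent in the tissue (undefined TDR) cannot qualify.
#'
#' @param tdr_table data.frame from [compute_tdr()].
#' @param gene_list character vector of disease gene ids/symbols.
#' @param tissue the disease-relevant tissue.
#' @param threshold TDR cutoff (strict `>`; default 0.25).
#' @return data.frame: `sv_id`, `pass`, `genes`, `max_tdr`, `reason`.
#' @export
tdr_genelist_filter <- function(tdr_table, gene_list, tissue,
                                threshold = 0.25) {
  tt <- tdr_table[tdr_table$tissue == tissue, , drop = FALSE]
  res <- lapply(split(tt, tt$variant_id), function(d) {
    d <- d[!is.na(d$tdr), , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(sv_id = NA_character_, pass = FALSE, genes = "",
                        max_tdr = NA_real_, reason = "no expressed gene",
                        stringsAsFactors = FALSE))
    }
    ok <- d$gene_id %in% gene_list & d$tdr > threshold
    data.frame(sv_id = d$variant_id[1], pass = any(ok),
               genes = paste(d$gene_id[ok], collapse = ";"),
               max_tdr = max(d$tdr),
               reason = if (any(ok)) "listed gene with TDR above threshold"
                        else "no listed gene exceeds TDR threshold",
               stringsAsFactors = FALSE)
  })
  ids <- names(res)
  out <- do.call(rbind, res)
  out$sv_id <- ids
  rownames(out) <- NULL
  out
}

#' Inheritance / dosage-sensitivity consistency stage
#'
#' Checks that the observed zygosity is consistent with the gene's mode of
#' inheritance or tissue dosage sensitivity: a heterozygous (or homozygous)
#' hit passes for a dominant gene (`AD` in OMIM modes) or a gene that is
#' dosage-sensitive in the tissue (MoDs percentile < `mods_threshold`); a
#' recessive-only gene requires a homozygous hit or a supplied second hit in
#' the same gene. Genes absent from the annotation tables pass flagged
#' `unannotated` so that novel candidate genes are not silently dropped.
#'
#' @param gene_id gene identifier.
#' @param genotype carrier genotype (`HET` or `HOM`).
#' @param annotations a [gene_annotations()] bundle.
#' @param tissue tissue used for the MoDs lookup.
#' @param second_hits character vector of gene ids with an independent
#'   second hit (e.g. an SNV) in this patient, or `NULL`.
#' @param mods_threshold dosage-sensitivity cutoff (strict `<`; default 0.3).
#' @return list: `pass` (logical), `rationale` (string).
#' @export
inheritance_consistency <- function(gene_id, genotype, annotations, tissue,
                                    second_hits = NULL, mods_threshold = 0.3) {
  stopifnot(inherits(annotations, "gene_annotations"))
  if (!genotype %in% c("HET", "HOM")) {
    return(list(pass = FALSE, rationale = "no confident carrier genotype"))
  }
  modes <- character(0)
  if (!is.null(annotations$omim)) {
    row <- annotations$omim[annotations$omim$gene_id == gene_id, , drop = FALSE]
    if (nrow(row)) modes <- strsplit(row$modes[1], ";", fixed = TRUE)[[1]]
  }
  mods_val <- NA_real_
  if (!is.null(annotations$mods) && gene_id %in% rownames(annotations$mods) &&
      tissue %in% colnames(annotations$mods)) {
    mods_val <- annotations$mods[gene_id, tissue]
  }
  if (!length(modes) && is.na(mods_val)) {
    return(list(pass = TRUE, rationale = "unannotated"))
  }
  dosage_sensitive <- !is.na(mods_val) && mods_val < mods_threshold
  if (("AD" %in% modes || dosage_sensitive)) {
    return(list(pass = TRUE, rationale = if ("AD" %in% modes)
      "dominant gene, confident carrier" else
      sprintf("dosage-sensitive in %s (MoDs %.2f)", tissue, mods_val)))
  }
  if ("AR" %in% modes || "XL" %in% modes) {
    if (genotype == "HOM") {
      return(list(pass = TRUE, rationale = "biallelic hit in recessive gene"))
    }
    if (gene_id %in% second_hits) {
      return(list(pass = TRUE,
                  rationale = "heterozygous hit with supplied second hit"))
    }
    return(list(pass = FALSE,
                rationale = "single heterozygous hit in recessive gene"))
  }
  list(pass = FALSE,
       rationale = sprintf("gene dosage-tolerant in %s and not dominant", tissue))
}

# Known-pathogenic SV overlap annotation (same type, RO > 0.8); never a gate.
.known_pathogenic_overlap <- function(v_row, clinvar_svs, ro_threshold = 0.8) {
  if (is.null(clinvar_svs)) return(NA_character_)
  cand <- clinvar_svs[clinvar_svs$svtype == v_row$svtype &
                      clinvar_svs$chrom == v_row$chrom, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  hit <- reciprocal_overlap(v_row, cand) > ro_threshold
  if (!any(hit)) return(NA_character_)
  paste(cand$id[hit], collapse = ";")
}

#' Run the candidate-pathogenic-SV cascade for one patient
#'
#' Applies the staged filters in order, each stage operating on the
#' survivors of the previous one:
#' `RAW` (all calls carried by the patient) -> `QC` (tiered quality control)
#' -> `RARE` (background AF strictly < `rare_threshold`) -> `DOSAGE_CLASS`
#' (exonic/whole-gene DEL/DUP or exonic INV) -> `TDR_GENELIST` (a listed
#' disease gene with TDR > `tdr_threshold` in the disease tissue) ->
#' `INHERITANCE` (zygosity consistent with OMIM mode or MoDs dosage
#' sensitivity, or a supplied segregation verdict) -> `REPORT`. Every input
#' SV appears exactly once in the trace with the stage at which it stopped.
#'
#' @param svs an [sv_set()] annotated with `background_af` (see
#'   [annotate_background_af()]); genotypes must include `sample`.
#' @param sample patient sample id.
#' @param genes a [gene_models()] object.
#' @param tpm transcript-by-tissue TPM matrix.
#' @param tissue disease-relevant tissue.
#' @param gene_list character vector of disease genes.
#' @param annotations a [gene_annotations()] bundle.
#' @param evidence a [support_evidence()] bundle for the QC stage, or
#'   `NULL` to accept precomputed QC via `qc_pass_ids`.
#' @param qc_pass_ids optional character vector of SV ids that passed QC
#'   (used when `evidence` is `NULL`).
#' @param second_hits optional character vector of genes with an independent
#'   second hit in this patient.
#' @param segregation optional named logical vector of external per-SV
#'   segregation verdicts overriding the inheritance stage.
#' @param tdr_threshold TDR cutoff (strict `>`; default 0.25).
#' @param rare_threshold background-AF rarity cutoff (strict `<`; default
#'   0.01).
#' @return list of class `cascade_result`: `report` (data.frame of
#'   candidate SVs with TDR, context, genes, rationale and known-pathogenic
#'   overlap), `trace` (per-SV stage outcome), `stage_counts` (named vector
#'   of survivors after each stage).
#' @export
run_cascade <- function(svs, sample, genes, tpm, tissue, gene_list,
                        annotations = gene_annotations(), evidence = NULL,
                        qc_pass_ids = NULL, second_hits = NULL,
                        segregation = NULL, tdr_threshold = 0.25,
                        rare_threshold = 0.01) {
  stopifnot(inherits(svs, "sv_set"))
  stages <- c("RAW", "QC", "RARE", "DOSAGE_CLASS", "TDR_GENELIST",
              "INHERITANCE", "REPORT")
  if (!sample %in% colnames(svs$genotypes)) {
    stop("sample '", sample, "' not in genotypes")
  }
  carried <- svs$variants$id[svs$genotypes[, sample] %in% c("HET", "HOM")]
  trace <- data.frame(id = carried,
                      stopped_at = rep(NA_character_, length(carried)),
                      reason = rep(NA_character_, length(carried)),
                      stringsAsFactors = FALSE)
  counts <- stats::setNames(integer(length(stages)), stages)
  alive <- carried
  counts["RAW"] <- length(alive)
  fail <- function(ids, stage, reason) {
    hit <- trace$id %in% ids & is.na(trace$stopped_at)
    trace$stopped_at[hit] <<- stage
    trace$reason[hit] <<- reason
  }

  # QC
  if (!is.null(evidence)) {
    qc <- apply_qc_workflow(sv_subset(svs, alive), evidence)
    keep <- qc$passed$variants$id
  } else if (!is.null(qc_pass_ids)) {
    keep <- intersect(alive, qc_pass_ids)
  } else {
    keep <- alive
  }
  fail(setdiff(alive, keep), "QC", "failed tiered quality control")
  alive <- keep; counts["QC"] <- length(alive)

  # RARE
  if (length(alive)) {
    v <- svs$variants[match(alive, svs$variants$id), , drop = FALSE]
    af <- v$background_af
    if (anyNA(af)) stop("background_af not annotated; run annotate_background_af()")
    keep <- alive[af < rare_threshold]
    fail(setdiff(alive, keep), "RARE", "common in background cohorts")
    alive <- keep
  }
  counts["RARE"] <- length(alive)

  # DOSAGE_CLASS
  dosage_genes <- character(0)
  if (length(alive)) {
    sub <- sv_subset(svs, alive)
    ctx <- classify_context(sub, genes)
    dc <- dosage_class_filter(sub, ctx)
    keep <- dc$sv_id[dc$pass]
    fail(setdiff(alive, keep), "DOSAGE_CLASS",
         "not an exonic/whole-gene CNV or exonic inversion")
    alive <- keep
  }
  counts["DOSAGE_CLASS"] <- length(alive)

  # TDR_GENELIST
  tdr_tab <- NULL; tg <- NULL
  if (length(alive)) {
    sub <- sv_subset(svs, alive)
    tdr_tab <- compute_tdr(sub, genes, tpm, tissue)
    tg <- tdr_genelist_filter(tdr_tab, gene_list, tissue, tdr_threshold)
    keep <- tg$sv_id[tg$pass]
    no_rows <- setdiff(alive, tg$sv_id)
    fail(no_rows, "TDR_GENELIST", "no expressed gene")
    fail(setdiff(alive, c(keep, no_rows)), "TDR_GENELIST",
         "no listed gene with TDR above threshold")
    alive <- keep
  }
  counts["TDR_GENELIST"] <- length(alive)

  # INHERITANCE
  report_rows <- list()
  if (length(alive)) {
    keep <- character(0)
    for (id in alive) {
      gt <- svs$genotypes[id, sample]
      genes_hit <- strsplit(tg$genes[tg$sv_id == id], ";", fixed = TRUE)[[1]]
      if (!is.null(segregation) && id %in% names(segregation)) {
        ok <- isTRUE(segregation[[id]])
        rationale <- sprintf("external segregation verdict: %s", ok)
        gene_ok <- genes_hit
      } else {
        verdicts <- lapply(genes_hit, inheritance_consistency,
                           genotype = gt, annotations = annotations,
                           tissue = tissue, second_hits = second_hits)
        ok_v <- vapply(verdicts, `[[`, logical(1), "pass")
        ok <- any(ok_v)
        gene_ok <- genes_hit[ok_v]
        rationale <- paste(vapply(verdicts, `[[`, character(1), "rationale"),
                           collapse = " | ")
      }
      if (ok) {
        keep <- c(keep, id)
        v_row <- svs$variants[svs$variants$id == id, , drop = FALSE]
        tr <- tdr_tab[tdr_tab$variant_id == id & tdr_tab$gene_id %in% gene_ok &
                        !is.na(tdr_tab$tdr), , drop = FALSE]
        report_rows[[id]] <- data.frame(
          sample = sample, sv_id = id, svtype = v_row$svtype,
          chrom = v_row$chrom, start = v_row$start, end = v_row$end,
          svlen = v_row$svlen, genotype = gt,
          background_af = v_row$background_af,
          genes = paste(gene_ok, collapse = ";"),
          max_tdr = max(tr$tdr), tissue = tissue,
          context = paste(unique(tr$context_class), collapse = ";"),
          rationale = rationale,
          known_pathogenic = .known_pathogenic_overlap(
            v_row, annotations$clinvar_svs),
          stringsAsFactors = FALSE)
      }
    }
    fail(setdiff(alive, keep), "INHERITANCE",
         "zygosity inconsistent with inheritance mode / dosage sensitivity")
    alive <- keep
  }
  counts["INHERITANCE"] <- length(alive)
  counts["REPORT"] <- length(alive)
  trace$stopped_at[is.na(trace$stopped_at)] <- "REPORT"
  trace$reason[is.na(trace$reason)] <- "reported candidate"

  report <- if (length(report_rows)) do.call(rbind, report_rows) else
    data.frame(sample = character(0), sv_id = character(0),
               svtype = character(0), chrom = character(0),
               start = integer(0), end = integer(0), svlen = numeric(0),
               genotype = character(0), background_af = numeric(0),
               genes = character(0), max_tdr = numeric(0),
               tissue = character(0), context = character(0),
               rationale = character(0), known_pathogenic = character(0),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  structure(list(report = report, trace = trace, stage_counts = counts),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("candidate SV cascade:\n")
  for (s in names(x$stage_counts)) {
    cat(sprintf("  %-13s %d\n", s, x$stage_counts[[s]]))
  }
  invisible(x)
}
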