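#' Size-tier classification of structural variants
#'
#' The QC workflow treats SVs by size class: `SHORT` variants (< 200 bp
#' DEL/DUP/INS) are confirmed by re-genotyping; `MEDIUM` copy-number variants
#' (200 bp <= length < 100 kb, DEL/DUP) and `LONG` CNVs (>= 100 kb, DEL/DUP)
#' require reciprocal-overlap corroboration from read-depth callers; `OTHER`
#' (inversions, and insertions >= 200 bp) pass without overlap-based
#' filtering. Inversions under 200 bp also fall in `OTHER` and are flagged
#' `untested_tier` by [apply_qc_workflow()], since re-genotyping of
#' inversions is not part of the workflow. For insertions, "length" is the
#' inserted-sequence length (`svlen`), not the (zero) anchor width.
#'
#' @param svs an [sv_set()] or its `variants` data.frame.
#' @return Character vector (`SHORT`/`MEDIUM`/`LONG`/`OTHER`), one per SV.
#' @export
size_tier <- function(svs) {
  v <- if (inherits(svs, "sv_set")) svs$variants else svs
  len <- v$svlen
  tier <- rep("OTHER", nrow(v))
  cnv <- v$svtype %in% c("DEL", "DUP")
  tier[len < 200 & v$svtype %in% c("DEL", "DUP", "INS")] <- "SHORT"
  tier[cnv & len >= 200 & len < 1e5] <- "MEDIUM"
  tier[cnv & len >= 1e5] <- "LONG"
  tier
}

#' Remove SVs overlapping problematic regions
#'
#' Drops every SV whose interval shares at least one base with an exclusion
#' interval (HLA, reference decoys, high-copy-number regions and the like).
#' Insertion anchors count as covering the base they point at. Removal counts
#' are reported with a message.
#'
#' @param svs an [sv_set()].
#' @param exclusion data.frame of exclusion intervals (`chrom`, `start`,
#'   `end`, 0-based half-open), e.g. from [read_interval_bed()].
#' @return The filtered [sv_set()].
#' @export
exclude_regions <- function(svs, exclusion) {
  stopifnot(inherits(svs, "sv_set"))
  if (nrow(exclusion) == 0L || length(svs) == 0L) return(svs)
  hit <- .overlaps_any(svs$variants, exclusion)
  if (any(hit)) {
    message(sum(hit), " SV(s) removed in excluded regions")
  }
  sv_subset(svs, svs$variants$id[!hit])
}

#' Bundle external support evidence for the QC workflow
#'
#' @param lumpy,cnvnator data.frames of caller intervals with columns
#'   `chrom`, `start`, `end`, `svtype` (typed so a DEL is only corroborated
#'   by DEL evidence).
#' @param paragraph_genotypes character matrix of re-genotyped calls
#'   (rownames = SV ids, columns = samples; values `HOMREF`/`HET`/`HOM`/
#'   `MISSING`), or `NULL`.
#' @return An object of class `support_evidence`.
#' @export
support_evidence <- function(lumpy = NULL, cnvnator = NULL,
                             paragraph_genotypes = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), svtype = character(0))
  structure(list(lumpy = lumpy %||% empty, cnvnator = cnvnator %||% empty,
                 paragraph = paragraph_genotypes),
            class = "support_evidence")
}

# Best same-type reciprocal overlap of one SV against a typed interval set.
.best_ro <- function(sv_row, support) {
  s <- support[support$svtype == sv_row$svtype &
               support$chrom == sv_row$chrom, , drop = FALSE]
  if (nrow(s) == 0L) return(0)
  max(reciprocal_overlap(sv_row, s))
}

#' Tiered SV quality-control workflow
#'
#' Applies the size-tier retention rules to a region-excluded call set:
#' \itemize{
#'   \item `SHORT` (< 200 bp DEL/DUP/INS): retained iff the re-genotyped
#'     (Paragraph-style) call is a confident non-reference genotype (`HET` or
#'     `HOM`) in at least one sample.
#'   \item `MEDIUM` (200 bp–100 kb DEL/DUP): retained iff some same-type
#'     interval from either breakpoint+read-depth caller (Lumpy) or the
#'     read-depth caller (CNVnator) has reciprocal overlap strictly > 0.8.
#'   \item `LONG` (>= 100 kb DEL/DUP): retained iff a same-type CNVnator
#'     interval has reciprocal overlap strictly > 0.8 (read-depth methods are
#'     the robust signal at this scale).
#'   \item `OTHER` (INV, INS >= 200 bp): retained unconditionally; INV
#'     < 200 bp is also passed through, flagged `untested_tier`.
#' }
#' Every SV receives exactly one audit row recording the tier, the rule fired
#' and the decision.
#'
#' @param svs an [sv_set()] (already region-excluded).
#' @param evidence a [support_evidence()] bundle.
#' @param ro_threshold reciprocal-overlap corroboration threshold (strict
#'   inequality; default 0.8).
#' @return list with `passed` (the retained [sv_set()]) and `audit`
#'   (data.frame: `id`, `tier`, `rule`, `pass`, `reason`).
#' @export
apply_qc_workflow <- function(svs, evidence, ro_threshold = 0.8) {
  stopifnot(inherits(svs, "sv_set"), inherits(evidence, "support_evidence"))
  v <- svs$variants
  tier <- size_tier(v)
  n <- nrow(v)
  pass <- logical(n); rule <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    row <- v[i, , drop = FALSE]
    if (tier[i] == "SHORT") {
      rule[i] <- "regenotype_confident"
      pg <- evidence$paragraph
      gt <- if (!is.null(pg) && row$id %in% rownames(pg)) pg[row$id, ] else character(0)
      pass[i] <- any(gt %in% c("HET", "HOM"))
      reason[i] <- if (pass[i]) "confident re-genotype in >=1 sample"
                   else "no confident re-genotyped carrier"
    } else if (tier[i] == "MEDIUM") {
      rule[i] <- "ro_lumpy_or_cnvnator"
      ro <- max(.best_ro(row, evidence$lumpy), .best_ro(row, evidence$cnvnator))
      pass[i] <- ro > ro_threshold
      reason[i] <- sprintf("best same-type RO = %.3f", ro)
    } else if (tier[i] == "LONG") {
      rule[i] <- "ro_cnvnator"
      ro <- .best_ro(row, evidence$cnvnator)
      pass[i] <- ro > ro_threshold
      reason[i] <- sprintf("best same-type CNVnator RO = %.3f", ro)
    } else {
      rule[i] <- "passthrough"
      pass[i] <- TRUE
      reason[i] <- if (row$svtype == "INV" && row$svlen < 200)
        "untested tier (INV < 200 bp)" else "INV/INS not overlap-filtered"
    }
  }
  audit <- data.frame(id = v$id, tier = tier, rule = rule, pass = pass,
                      reason = reason, stringsAsFactors = FALSE)
  passed <- sv_subset(svs, v$id[pass])
  flag_rows <- which(passed$variants$svtype == "INV" & passed$variants$svlen < 200)
  if (length(flag_rows)) {
    passed$variants <- .add_flag(passed$variants, flag_rows, "untested_tier")
  }
  list(passed = passed, audit = audit)
}

#' Per-sample alignment quality gate
#'
#' A sample's alignment passes iff mean coverage > 15x, chimeric-read
#' fraction < 0.05% (0.0005) and cross-sample contamination < 5% (0.05), all
#' strict inequalities. Insert-size normality is accepted as an upstream
#' boolean column `insert_size_ok` when present. Samples with a missing
#' metric are flagged `UNEVALUATED`.
#'
#' @param metrics data.frame with columns `sample`, `mean_coverage`,
#'   `chimeric_fraction`, `contamination`, optional `insert_size_ok`.
#' @return data.frame with `sample`, `status` (`PASS`/`FAIL`/`UNEVALUATED`)
#'   and `pass` (logical; `NA` when unevaluated).
#' @export
bam_qc_gate <- function(metrics) {
  need <- c("mean_coverage", "chimeric_fraction", "contamination")
  miss_col <- setdiff(need, names(metrics))
  if (length(miss_col)) stop("metrics missing columns: ",
                             paste(miss_col, collapse = ", "))
  complete <- stats::complete.cases(metrics[need])
  ok <- metrics$mean_coverage > 15 &
        metrics$chimeric_fraction < 0.0005 &
        metrics$contamination < 0.05
  if (!is.null(metrics$insert_size_ok)) {
    ok <- ok & metrics$insert_size_ok
    complete <- complete & !is.na(metrics$insert_size_ok)
  }
  status <- ifelse(!complete, "UNEVALUATED", ifelse(ok, "PASS", "FAIL"))
  data.frame(sample = metrics$sample, status = status,
             pass = ifelse(complete, ok, NA), stringsAsFactors = FALSE)
}
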