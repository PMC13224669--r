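#' Transcripts disrupted by a structural variant
#'
#' A transcript counts as disrupted when the variant touches the sequence
#' that produces its (functional) product:
#' \itemize{
#'   \item DEL/DUP: the SV interval overlaps >= 1 bp of the transcript's CDS
#'     (coding transcripts) or of its exons (non-coding transcripts, which
#'     carry no CDS but are part of the gene's expression denominator).
#'   \item INS: the anchor point lies inside such a CDS/exon interval.
#'   \item INV: at least one inversion breakpoint lies strictly inside the
#'     transcript span \emph{and} the inversion overlaps >= 1 qualifying
#'     CDS/exon base. An inversion that contains the whole transcript
#'     relocates it intact and disrupts nothing.
#' }
#'
#' @param svs an [sv_set()].
#' @param genes a [gene_models()] object.
#' @param sv_id,gene_id ids selecting one SV-gene pair.
#' @return Character vector of disrupted transcript ids (possibly empty).
#' @export
disrupted_transcripts <- function(svs, genes, sv_id, gene_id) {
  v <- svs$variants[match(sv_id, svs$variants$id), , drop = FALSE]
  if (anyNA(v$id)) stop("unknown sv_id: ", sv_id)
  .disrupted_one(v, genes, gene_id)
}

.qualifying_intervals <- function(genes, tx_id, biotype) {
  if (biotype == "protein_coding") {
    q <- genes$cds[genes$cds$tx_id == tx_id, , drop = FALSE]
    if (nrow(q)) return(q)
  }
  genes$exons[genes$exons$tx_id == tx_id, , drop = FALSE]
}

.disrupted_one <- function(v, genes, gene_id) {
  tx <- genes$transcripts[genes$transcripts$gene_id == gene_id, , drop = FALSE]
  if (!nrow(tx)) stop("unknown gene_id: ", gene_id)
  if (v$chrom != tx$chrom[1]) return(character(0))
  s <- v$start; e <- v$end
  hit <- vapply(seq_len(nrow(tx)), function(j) {
    q <- .qualifying_intervals(genes, tx$tx_id[j], tx$biotype[j])
    if (!nrow(q)) return(FALSE)
    if (v$svtype == "INS") {
      any(q$start <= s & s < q$end)
    } else if (v$svtype == "INV") {
      bp_inside <- (tx$start[j] < s && s < tx$end[j]) ||
                   (tx$start[j] < e && e < tx$end[j])
      bp_inside && any(q$start < e & q$end > s)
    } else {
      any(q$start < e & q$end > s)
    }
  }, logical(1))
  tx$tx_id[hit]
}

.tdr_row <- function(variant_id, gene_id, tissue, disrupted, genes, tpm,
                     context = NA_character_) {
  tx <- genes$transcripts[genes$transcripts$gene_id == gene_id, , drop = FALSE]
  tpm_all <- .tpm_lookup(tpm, tx$tx_id, tissue)
  tpm_total <- sum(tpm_all)
  tpm_dis <- sum(tpm_all[tx$tx_id %in% disrupted])
  data.frame(
    variant_id = variant_id, gene_id = gene_id, tissue = tissue,
    n_disrupted = length(disrupted), tpm_disrupted = tpm_dis,
    tpm_total = tpm_total,
    tdr = if (tpm_total > 0) tpm_dis / tpm_total else NA_real_,
    disrupts_mane = any(tx$is_mane[tx$tx_id %in% disrupted]),
    context_class = context, stringsAsFactors = FALSE)
}

#' Transcript Disruption Ratio of SVs
#'
#' For each SV-gene pair and tissue, the TDR is the proportion of the gene's
#' total expression contributed by the transcripts the variant disrupts:
#' \deqn{TDR_{gene,tissue} = \frac{\sum TPM_{disrupted\ transcripts}}
#'                                {\sum TPM_{all\ transcripts}}}
#' where the sums run over tissue median TPM. The denominator includes every
#' annotated isoform, protein-coding and non-coding. A gene with zero total
#' TPM in the tissue yields `NA` (a silent gene cannot be dosage-disrupted
#' there); such rows are excluded from prioritization rather than treated as
#' 0. `disrupts_mane` records whether any disrupted transcript is the MANE
#' Select transcript.
#'
#' @param svs an [sv_set()].
#' @param genes a [gene_models()] object.
#' @param tpm transcript-by-tissue TPM matrix (see [read_tpm()]).
#' @param tissues character vector of tissue column names to evaluate.
#' @param pairs optional data.frame (`sv_id`, `gene_id`); default is every
#'   pair where the SV overlaps the gene span (insertions by anchor).
#' @return data.frame: `variant_id`, `gene_id`, `tissue`, `n_disrupted`,
#'   `tpm_disrupted`, `tpm_total`, `tdr`, `disrupts_mane`, `context_class`.
#' @export
compute_tdr <- function(svs, genes, tpm, tissues, pairs = NULL) {
  stopifnot(inherits(svs, "sv_set"), inherits(genes, "gene_models"))
  if (is.null(pairs)) pairs <- .default_pairs(svs, genes, overlap_only = TRUE)
  if (!nrow(pairs)) {
    return(.tdr_row("x", genes$genes$gene_id[1], tissues[1], character(0),
                    genes, tpm)[0, ])
  }
  ctx <- classify_context(svs, genes, pairs)$context
  out <- vector("list", nrow(pairs) * length(tissues))
  k <- 0L
  for (p in seq_len(nrow(pairs))) {
    v <- svs$variants[match(pairs$sv_id[p], svs$variants$id), , drop = FALSE]
    dis <- .disrupted_one(v, genes, pairs$gene_id[p])
    for (tis in tissues) {
      k <- k + 1L
      out[[k]] <- .tdr_row(v$id, pairs$gene_id[p], tis, dis, genes, tpm, ctx[p])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcript Disruption Ratio of stop-gain point variants
#'
#' Premature stop codons trigger nonsense-mediated decay of the transcripts
#' that carry them, so the disrupted set of a stop-gain variant is the set of
#' transcripts whose CDS contains the variant position; the TDR is then
#' computed exactly as for SVs. Positions inside the gene span but in UTR or
#' intron for every transcript give TDR 0; a pair whose position falls
#' outside the gene span gets TDR 0 and qc flag `outside_gene`.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (0-based);
#'   extra columns (`sample`, `consequence`) are carried along unused.
#' @param genes a [gene_models()] object.
#' @param tpm transcript-by-tissue TPM matrix.
#' @param tissues tissue column names to evaluate.
#' @param pairs optional data.frame (`variant_id`, `gene_id`); default pairs
#'   each variant with every gene whose span contains its position.
#' @return data.frame as [compute_tdr()], plus a `flag` column.
#' @export
compute_tdr_stopgain <- function(variants, genes, tpm, tissues, pairs = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  variants$id <- as.character(variants$id)
  if (is.null(pairs)) {
    g <- genes$genes
    pairs <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
      gi <- g[g$chrom == variants$chrom[i] & g$start <= variants$pos[i] &
                variants$pos[i] < g$end, , drop = FALSE]
      if (!nrow(gi)) return(NULL)
      data.frame(variant_id = variants$id[i], gene_id = gi$gene_id,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) {
      return(cbind(.tdr_row("x", genes$genes$gene_id[1], tissues[1],
                            character(0), genes, tpm)[0, ],
                   flag = character(0)))
    }
  }
  out <- list(); k <- 0L
  for (p in seq_len(nrow(pairs))) {
    i <- match(pairs$variant_id[p], variants$id)
    gid <- pairs$gene_id[p]
    g <- genes$genes[genes$genes$gene_id == gid, , drop = FALSE]
    pos <- variants$pos[i]
    outside <- variants$chrom[i] != g$chrom || pos < g$start || pos >= g$end
    dis <- character(0)
    if (!outside) {
      tx <- genes$transcripts[genes$transcripts$gene_id == gid, , drop = FALSE]
      hit <- vapply(tx$tx_id, function(t) {
        cd <- genes$cds[genes$cds$tx_id == t, , drop = FALSE]
        nrow(cd) > 0 && any(cd$start <= pos & pos < cd$end)
      }, logical(1))
      dis <- tx$tx_id[hit]
    }
    for (tis in tissues) {
      k <- k + 1L
      row <- .tdr_row(variants$id[i], gid, tis, dis, genes, tpm)
      if (outside) row$tdr <- 0
      row$flag <- if (outside) "outside_gene" else ""
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' MANE-disruption versus TDR comparison
#'
#' Partitions SVs by whether they disrupt the MANE Select transcript of any
#' overlapped gene, and reports per partition the fraction of SVs with a
#' high TDR (strictly > `threshold`) in each of two tissues, together with
#' the per-SV tissue TDR pairs. An SV hitting several genes contributes its
#' maximum TDR per tissue. Highlights isoform-dependent effects: an SV can
#' spare the canonical transcript yet still remove most of the gene's
#' expression in some tissue.
#'
#' @inheritParams compute_tdr
#' @param tissue_a,tissue_b the two tissues compared.
#' @param threshold high-TDR cutoff (strict `>`; default 0.25).
#' @return list with `summary` (per partition x tissue: `n`,
#'   `frac_high_tdr`; `NA` fraction for an empty partition) and `pairs`
#'   (per SV: `tdr_a`, `tdr_b`, `disrupts_mane`).
#' @export
mane_tdr_comparison <- function(svs, genes, tpm, tissue_a, tissue_b,
                                threshold = 0.25, pairs = NULL) {
  tab <- compute_tdr(svs, genes, tpm, c(tissue_a, tissue_b), pairs)
  if (!nrow(tab)) stop("no SV-gene pairs to compare")
  per_sv <- do.call(rbind, lapply(split(tab, tab$variant_id), function(d) {
    data.frame(
      variant_id = d$variant_id[1],
      tdr_a = .max_or_na(d$tdr[d$tissue == tissue_a]),
      tdr_b = .max_or_na(d$tdr[d$tissue == tissue_b]),
      disrupts_mane = any(d$disrupts_mane), stringsAsFactors = FALSE)
  }))
  rownames(per_sv) <- NULL
  summ <- do.call(rbind, lapply(c(TRUE, FALSE), function(m) {
    sub <- per_sv[per_sv$disrupts_mane == m, , drop = FALSE]
    data.frame(
      disrupts_mane = m, n = nrow(sub),
      frac_high_tdr_a = .frac_high(sub$tdr_a, threshold),
      frac_high_tdr_b = .frac_high(sub$tdr_b, threshold))
  }))
  list(summary = summ, pairs = per_sv)
}

.max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) max(x) else NA_real_
}

.frac_high <- function(x, threshold) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x > threshold)
}

#' Protein-coding share of a gene's expression
#'
#' The fraction of a gene's total tissue TPM contributed by its
#' protein-coding transcripts; `NA` when the gene is silent in the tissue.
#' For most genes this ratio exceeds 0.5, which motivates computing TDR over
#' all isoforms while defining disruption on coding sequence.
#'
#' @param genes a [gene_models()] object.
#' @param tpm transcript-by-tissue TPM matrix.
#' @param tissue tissue column name.
#' @param gene_ids genes to evaluate (default: all).
#' @return Named numeric vector of ratios in `[0, 1]` (or `NA`).
#' @export
protein_coding_ratio <- function(genes, tpm, tissue, gene_ids = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  if (is.null(gene_ids)) gene_ids <- genes$genes$gene_id
  vapply(gene_ids, function(gid) {
    tx <- genes$transcripts[genes$transcripts$gene_id == gid, , drop = FALSE]
    v <- .tpm_lookup(tpm, tx$tx_id, tissue)
    tot <- sum(v)
    if (tot <= 0) return(NA_real_)
    sum(v[tx$biotype == "protein_coding"]) / tot
  }, numeric(1))
}
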