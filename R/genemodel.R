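#' Construct a gene-model set
#'
#' Table-backed container for gene annotation, 0-based half-open throughout:
#' `genes` (one row per gene with the span = union of its transcript spans),
#' `transcripts` (with biotype, MANE flag and strand-aware TSS), `exons` and
#' `cds` (per-transcript intervals; `cds` is empty for non-coding
#' transcripts).
#'
#' @param genes data.frame: `gene_id`, `symbol`, `chrom`, `strand`, `start`,
#'   `end`.
#' @param transcripts data.frame: `tx_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype`, `is_mane`, `tss`.
#' @param exons,cds data.frames: `tx_id`, `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons, cds) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("tx_id", "gene_id", "biotype", "is_mane", "tss") %in%
                  names(transcripts)),
            all(c("tx_id", "start", "end") %in% names(exons)))
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan)) stop("transcripts reference unknown genes: ",
                           paste(orphan, collapse = ", "))
  noncoding <- transcripts$tx_id[transcripts$biotype != "protein_coding"]
  if (any(cds$tx_id %in% noncoding)) stop("non-coding transcripts cannot have CDS")
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts (%d coding), %d exons\n",
              nrow(x$genes), nrow(x$transcripts),
              sum(x$transcripts$biotype == "protein_coding"), nrow(x$exons)))
  invisible(x)
}

#' Read Gencode-style GTF annotation
#'
#' Parses gene/transcript/exon/CDS features via `rtracklayer`, converting
#' GTF's 1-based inclusive coordinates to 0-based half-open. Transcript
#' biotype comes from the `transcript_type` attribute, the MANE flag from a
#' `tag` attribute containing `MANE_Select`. Transcripts lacking exons are
#' dropped with a warning; records missing `gene_id`/`transcript_id` raise
#' an error. Gene spans are recomputed as the union of transcript spans.
#'
#' @param path path to a GTF file.
#' @return A [gene_models()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (is.null(df$gene_id) || anyNA(df$gene_id)) {
    stop("GTF record(s) missing gene_id attribute (record ",
         paste(utils::head(which(is.na(df$gene_id)), 3), collapse = ", "), ")")
  }
  feat <- df[df$type %in% c("transcript", "exon", "CDS"), , drop = FALSE]
  if (is.null(feat$transcript_id) || anyNA(feat$transcript_id)) {
    stop("GTF transcript/exon/CDS record(s) missing transcript_id attribute")
  }

  ex <- df[df$type == "exon", , drop = FALSE]
  cd <- df[df$type == "CDS", , drop = FALSE]
  txf <- df[df$type == "transcript", , drop = FALSE]
  tx_ids <- unique(c(txf$transcript_id, ex$transcript_id))
  no_exon <- setdiff(txf$transcript_id, ex$transcript_id)
  if (length(no_exon)) {
    warning("dropped ", length(no_exon), " transcript(s) without exons: ",
            paste(no_exon, collapse = ", "))
    tx_ids <- setdiff(tx_ids, no_exon)
  }

  tx_list <- lapply(tx_ids, function(t) {
    e <- ex[ex$transcript_id == t, , drop = FALSE]
    tstart <- min(e$start0); tend <- max(e$end0)
    strand <- e$strand[1]
    biotype <- if (!is.null(e$transcript_type)) e$transcript_type[1] else "protein_coding"
    tag <- if (!is.null(e$tag)) paste(e$tag, collapse = ",") else ""
    trow <- txf[txf$transcript_id == t, , drop = FALSE]
    if (nrow(trow) && !is.null(trow$tag) && !is.na(trow$tag[1])) {
      tag <- paste(tag, trow$tag[1], sep = ",")
    }
    data.frame(tx_id = t, gene_id = e$gene_id[1], chrom = e$seqnames[1],
               strand = strand, start = tstart, end = tend,
               biotype = ifelse(is.na(biotype), "protein_coding", biotype),
               is_mane = grepl("MANE_Select", tag),
               tss = if (strand == "-") tend - 1L else tstart,
               stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, tx_list)

  exons <- data.frame(tx_id = ex$transcript_id, start = ex$start0,
                      end = ex$end0, stringsAsFactors = FALSE)
  exons <- exons[exons$tx_id %in% tx_ids, , drop = FALSE]
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  cds <- data.frame(tx_id = if (nrow(cd)) cd$transcript_id else character(0),
                    start = cd$start0, end = cd$end0, stringsAsFactors = FALSE)
  cds <- cds[cds$tx_id %in% tx_ids, , drop = FALSE]
  cds <- cds[order(cds$tx_id, cds$start), , drop = FALSE]

  gsp <- lapply(split(transcripts, transcripts$gene_id), function(t) {
    data.frame(gene_id = t$gene_id[1],
               symbol = t$gene_id[1], chrom = t$chrom[1], strand = t$strand[1],
               start = min(t$start), end = max(t$end), stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gsp)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) && !is.null(gene_rows$gene_name)) {
    m <- match(genes$gene_id, gene_rows$gene_id)
    sym <- gene_rows$gene_name[m]
    genes$symbol <- ifelse(is.na(sym), genes$gene_id, sym)
  }
  gene_models(genes, transcripts, exons, cds)
}

#' Read a transcript-by-tissue median TPM table
#'
#' First column `transcript_id`, one column per tissue; values are cohort
#' median TPM (non-negative).
#'
#' @param path path to a TSV file.
#' @return Numeric matrix, transcripts in rows, tissues in columns.
#' @export
read_tpm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("TPM values must be non-negative")
  m
}

#' @rdname read_tpm
#' @param tpm numeric matrix as returned by `read_tpm()`.
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(transcript_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TPM lookup tolerant of unannotated transcripts (0 with one warning).
.tpm_lookup <- function(tpm, tx_ids, tissue) {
  if (!tissue %in% colnames(tpm)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(tpm), collapse = ", "))
  }
  idx <- match(tx_ids, rownames(tpm))
  if (anyNA(idx)) {
    warning("transcript(s) absent from TPM table, treated as 0 TPM: ",
            paste(tx_ids[is.na(idx)], collapse = ", "))
  }
  val <- numeric(length(tx_ids))
  val[!is.na(idx)] <- tpm[idx[!is.na(idx)], tissue]
  val
}

# All same-chromosome SV x gene pairs (default pairing).
.default_pairs <- function(svs, genes, overlap_only = FALSE) {
  v <- svs$variants; g <- genes$genes
  out <- lapply(seq_len(nrow(v)), function(i) {
    gi <- g[g$chrom == v$chrom[i], , drop = FALSE]
    if (overlap_only) {
      s <- v$start[i]; e <- if (v$svtype[i] == "INS") v$start[i] + 1 else v$end[i]
      gi <- gi[gi$start < e & gi$end > s, , drop = FALSE]
    }
    if (!nrow(gi)) return(NULL)
    data.frame(sv_id = v$id[i], gene_id = gi$gene_id, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(sv_id = character(0), gene_id = character(0)))
  }
  do.call(rbind, out)
}

#' Classify the positional context of SV-gene pairs
#'
#' Mutually exclusive classes per SV-gene pair: `WHOLE_GENE` when the SV
#' interval contains the full gene span; `EXONIC` when it overlaps at least
#' one exon of any transcript (but not the whole gene); `INTRONIC` when it
#' overlaps the gene span but no exon; `INTERGENIC` otherwise (including
#' different chromosomes). Insertions are classified by their anchor point.
#'
#' @param svs an [sv_set()].
#' @param genes a [gene_models()] object.
#' @param pairs optional data.frame (`sv_id`, `gene_id`) restricting the
#'   pairs evaluated; default is every same-chromosome pair.
#' @return data.frame: `sv_id`, `gene_id`, `context`.
#' @export
classify_context <- function(svs, genes, pairs = NULL) {
  stopifnot(inherits(svs, "sv_set"), inherits(genes, "gene_models"))
  if (is.null(pairs)) pairs <- .default_pairs(svs, genes)
  v <- svs$variants
  ctx <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- match(pairs$sv_id[k], v$id)
    g <- genes$genes[genes$genes$gene_id == pairs$gene_id[k], , drop = FALSE]
    if (v$chrom[i] != g$chrom) return("INTERGENIC")
    s <- v$start[i]
    e <- if (v$svtype[i] == "INS") s + 1L else v$end[i]
    if (v$svtype[i] != "INS" && s <= g$start && e >= g$end) return("WHOLE_GENE")
    if (e <= g$start || s >= g$end) return("INTERGENIC")
    tx <- genes$transcripts$tx_id[genes$transcripts$gene_id == g$gene_id]
    ex <- genes$exons[genes$exons$tx_id %in% tx, , drop = FALSE]
    if (any(ex$start < e & ex$end > s)) "EXONIC" else "INTRONIC"
  }, character(1))
  data.frame(pairs, context = ctx, stringsAsFactors = FALSE)
}

#' Distance from an SV to the nearest transcription start site of a gene
#'
#' Strand-aware: the TSS of a `+` transcript is its leftmost base, of a `-`
#' transcript its rightmost. The distance is the gap between the SV interval
#' and the TSS point (0 when the SV covers a TSS), minimized over the gene's
#' transcripts. Insertions are treated as covering the base at their anchor.
#'
#' @inheritParams classify_context
#' @return data.frame: `sv_id`, `gene_id`, `tss_distance` (bp).
#' @export
tss_distance <- function(svs, genes, pairs = NULL) {
  stopifnot(inherits(svs, "sv_set"), inherits(genes, "gene_models"))
  if (is.null(pairs)) pairs <- .default_pairs(svs, genes)
  v <- svs$variants
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- match(pairs$sv_id[k], v$id)
    tx <- genes$transcripts[genes$transcripts$gene_id == pairs$gene_id[k], ,
                            drop = FALSE]
    if (v$chrom[i] != tx$chrom[1]) return(Inf)
    s <- v$start[i]
    e <- if (v$svtype[i] == "INS") s + 1L else v$end[i]
    min(vapply(tx$tss, function(t) {
      if (t >= s && t < e) 0 else if (t < s) s - t else t - (e - 1)
    }, numeric(1)))
  }, numeric(1))
  data.frame(pairs, tss_distance = d, stringsAsFactors = FALSE)
}

#' Write a gene-model set as GTF
#'
#' Emits gene/transcript/exon/CDS features in Gencode dialect (1-based
#' inclusive coordinates, `gene_id`/`transcript_id`/`transcript_type`
#' attributes, `tag "MANE_Select"` on MANE transcripts), the inverse of
#' [read_gtf()].
#'
#' @param genes a [gene_models()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  attrs <- function(gene_id, tx_id = NULL, biotype = NULL, mane = FALSE) {
    a <- sprintf('gene_id "%s";', gene_id)
    if (!is.null(tx_id)) {
      a <- paste(a, sprintf('transcript_id "%s"; transcript_type "%s";',
                            tx_id, biotype))
      if (mane) a <- paste(a, 'tag "MANE_Select";')
    }
    a
  }
  line <- function(chrom, feat, s0, e0, strand, att) {
    sprintf("%s\ttdrsv\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, s0 + 1L, e0, strand, att)
  }
  out <- character(0)
  for (i in seq_len(nrow(genes$genes))) {
    g <- genes$genes[i, ]
    out <- c(out, line(g$chrom, "gene", g$start, g$end, g$strand,
                       attrs(g$gene_id)))
    txs <- genes$transcripts[genes$transcripts$gene_id == g$gene_id, ,
                             drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      att <- attrs(g$gene_id, t$tx_id, t$biotype, t$is_mane)
      out <- c(out, line(t$chrom, "transcript", t$start, t$end, t$strand, att))
      ex <- genes$exons[genes$exons$tx_id == t$tx_id, , drop = FALSE]
      for (k in seq_len(nrow(ex))) {
        out <- c(out, line(t$chrom, "exon", ex$start[k], ex$end[k], t$strand, att))
      }
      cd <- genes$cds[genes$cds$tx_id == t$tx_id, , drop = FALSE]
      for (k in seq_len(nrow(cd))) {
        out <- c(out, line(t$chrom, "CDS", cd$start[k], cd$end[k], t$strand, att))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
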