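# Brute-force oracles, deliberately naive: base-by-base enumeration and
# generic graph components, independent of the package's interval
# arithmetic.

# Reciprocal overlap by counting shared bases.
oracle_ro <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  ov <- length(intersect(ba, bb))
  min(ov / length(ba), ov / length(bb))
}

# Set of bases an interval list covers (small fixtures only).
.bases <- function(df) {
  if (!nrow(df)) return(integer(0))
  unlist(lapply(seq_len(nrow(df)), function(i) seq(df$start[i], df$end[i] - 1)))
}

# Disrupted-transcript set by per-base membership.
oracle_disrupted <- function(v, genes, gene_id) {
  tx <- genes$transcripts[genes$transcripts$gene_id == gene_id, , drop = FALSE]
  if (v$chrom != tx$chrom[1]) return(character(0))
  hit <- vapply(seq_len(nrow(tx)), function(j) {
    cd <- genes$cds[genes$cds$tx_id == tx$tx_id[j], , drop = FALSE]
    q <- if (tx$biotype[j] == "protein_coding" && nrow(cd)) cd else
      genes$exons[genes$exons$tx_id == tx$tx_id[j], , drop = FALSE]
    qb <- .bases(q)
    if (v$svtype == "INS") return(v$start %in% qb)
    svb <- seq(v$start, v$end - 1)
    touches <- length(intersect(svb, qb)) > 0
    if (v$svtype == "INV") {
      span <- seq(tx$start[j] + 1, tx$end[j] - 1)
      bp_in <- (v$start %in% span) || (v$end %in% span)
      return(bp_in && touches)
    }
    touches
  }, logical(1))
  tx$tx_id[hit]
}

# TDR by oracle disruption plus direct summation.
oracle_tdr <- function(v, genes, tpm, tissue, gene_id) {
  tx <- genes$transcripts[genes$transcripts$gene_id == gene_id, , drop = FALSE]
  vals <- vapply(tx$tx_id, function(t)
    if (t %in% rownames(tpm)) tpm[t, tissue] else 0, numeric(1))
  tot <- sum(vals)
  if (tot == 0) return(NA_real_)
  dis <- oracle_disrupted(v, genes, gene_id)
  sum(vals[tx$tx_id %in% dis]) / tot
}

# Positional context by per-base membership.
oracle_context <- function(v, genes, gene_id) {
  g <- genes$genes[genes$genes$gene_id == gene_id, , drop = FALSE]
  if (v$chrom != g$chrom) return("INTERGENIC")
  svb <- if (v$svtype == "INS") v$start else seq(v$start, v$end - 1)
  gene_b <- seq(g$start, g$end - 1)
  if (v$svtype != "INS" && all(gene_b %in% svb)) return("WHOLE_GENE")
  if (!length(intersect(svb, gene_b))) return("INTERGENIC")
  tx <- genes$transcripts$tx_id[genes$transcripts$gene_id == gene_id]
  exb <- .bases(genes$exons[genes$exons$tx_id %in% tx, , drop = FALSE])
  if (length(intersect(svb, exb))) "EXONIC" else "INTRONIC"
}

# Connected components of the merge graph, via igraph.
oracle_components <- function(variants, ro_threshold = 0.8, ins_dist = 100,
                              ins_len_ratio = 0.8) {
  n <- nrow(variants)
  edges <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- variants[i, ]; b <- variants[j, ]
      if (a$svtype != b$svtype || a$chrom != b$chrom) next
      linked <- if (a$svtype == "INS") {
        abs(a$start - b$start) <= ins_dist &&
          min(a$svlen, b$svlen) / max(a$svlen, b$svlen) > ins_len_ratio
      } else {
        oracle_ro(a, b) > ro_threshold
      }
      if (linked) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Random SV table over the synthetic annotation's gene space.
random_svs <- function(annotation, n, seed,
                       types = c("DEL", "DUP", "INV", "INS")) {
  set.seed(seed)
  g <- annotation$genes$genes
  rows <- lapply(seq_len(n), function(i) {
    gi <- g[sample(nrow(g), 1), ]
    svtype <- sample(types, 1)
    width <- gi$end - gi$start
    s <- gi$start + sample(seq(-2000, width - 100), 1)
    len <- sample(c(50:300, seq(500, 8000, by = 37)), 1)
    sv_row(sprintf("r%05d", i), gi$chrom, max(0, s),
           max(0, s) + ifelse(svtype == "INS", 0, len), svtype, svlen = len)
  })
  do.call(rbind, rows)
}
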