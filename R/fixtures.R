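#' Specification for the synthetic-data generator
#'
#' Collects every tunable of the deterministic fixture generator. The same
#' spec and seed always reproduce byte-identical outputs. Defaults describe
#' a small but structurally realistic study: a two-chromosome toy genome
#' with multi-isoform genes of mixed biotype, three tissues with
#' tissue-varying dominant isoforms, and two background populations of 60
#' genotyped samples each.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param tx_per_gene integer range (min, max) of coding transcripts per
#'   gene.
#' @param tissues character vector of tissue names.
#' @param populations named integer vector: samples per background cohort.
#' @param noise_sd sd of Gaussian noise on log2 expression.
#' @param confounder_loading per-gene loading of a known batch confounder on
#'   log2 expression (0 disables it).
#' @param tdr_tol tolerance when rejection-sampling breakpoints toward a
#'   target TDR.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42, n_genes = 30, tx_per_gene = c(2, 4),
                         tissues = c("tissueA", "tissueB", "tissueC"),
                         populations = c(EAS = 60, EUR = 60),
                         noise_sd = 0.3, confounder_loading = 0,
                         tdr_tol = 0.05) {
  stopifnot(n_genes >= 2, length(tx_per_gene) == 2, length(tissues) >= 1,
            !is.null(names(populations)))
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 tx_per_gene = tx_per_gene, tissues = tissues,
                 populations = populations, noise_sd = noise_sd,
                 confounder_loading = confounder_loading, tdr_tol = tdr_tol),
            class = "fixture_spec")
}

#' Generate a toy genome annotation and TPM table
#'
#' Genes are laid out alternately on chr1/chr2 at 100 kb spacing with 5-8
#' exon slots each; every gene has 2-4 protein-coding transcripts (contiguous
#' exon-slot runs, UTR-trimmed CDS, the longest coding transcript tagged
#' MANE Select) and, with probability 0.4, one additional non-coding
#' isoform. Median TPM values are log-normal per transcript and tissue with
#' 10% dropout; a few multi-isoform genes are forced to switch dominant
#' isoform between the first two tissues, so that the same variant can have
#' very different TDR in different tissues.
#'
#' @param spec a [fixture_spec()].
#' @return list: `genes` (a [gene_models()]), `tpm` (transcript x tissue
#'   matrix), `isoform_switch_genes` (character).
#' @export
generate_annotation <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes_l <- list(); tx_l <- list(); ex_l <- list(); cds_l <- list()
  for (i in seq_len(spec$n_genes)) {
    gid <- sprintf("G%03d", i)
    chrom <- if (i %% 2 == 1) "chr1" else "chr2"
    slot <- (ceiling(i / 2) - 1)
    gstart <- 50000 + slot * 100000
    glen <- sample(12000:24000, 1)
    strand <- sample(c("+", "-"), 1)
    n_slots <- sample(5:8, 1)
    block <- glen %/% n_slots
    ex_start <- gstart + (seq_len(n_slots) - 1) * block +
      sample(0:(block %/% 4), n_slots, replace = TRUE)
    ex_len <- sample(120:300, n_slots, replace = TRUE)
    ex_end <- pmin(ex_start + ex_len, gstart + (seq_len(n_slots)) * block - 50)

    n_tx <- sample(spec$tx_per_gene[1]:spec$tx_per_gene[2], 1)
    tx_rows <- list()
    for (j in seq_len(n_tx)) {
      tid <- sprintf("%s_T%d", gid, j)
      lo <- sample(seq_len(n_slots - 1), 1)
      hi <- sample(seq(lo + 1, n_slots), 1)
      slots <- lo:hi
      if (length(slots) > 3 && stats::runif(1) < 0.5) {
        slots <- setdiff(slots, sample(slots[-c(1, length(slots))], 1))
      }
      exs <- data.frame(tx_id = tid, start = ex_start[slots],
                        end = ex_end[slots], stringsAsFactors = FALSE)
      # UTR-trim the outermost exons to get the CDS
      trim5 <- min(60L, exs$end[1] - exs$start[1] - 10L)
      trim3 <- min(60L, exs$end[nrow(exs)] - exs$start[nrow(exs)] - 10L)
      cds <- exs
      cds$start[1] <- cds$start[1] + trim5
      cds$end[nrow(cds)] <- cds$end[nrow(cds)] - trim3
      tstart <- min(exs$start); tend <- max(exs$end)
      tx_rows[[j]] <- data.frame(
        tx_id = tid, gene_id = gid, chrom = chrom, strand = strand,
        start = tstart, end = tend, biotype = "protein_coding",
        is_mane = FALSE, tss = if (strand == "-") tend - 1L else tstart,
        exonic_bp = sum(exs$end - exs$start), stringsAsFactors = FALSE)
      ex_l[[length(ex_l) + 1L]] <- exs
      cds_l[[length(cds_l) + 1L]] <- cds
    }
    txdf <- do.call(rbind, tx_rows)
    txdf$is_mane[which.max(txdf$exonic_bp)] <- TRUE
    if (stats::runif(1) < 0.4) {
      # one non-coding isoform over a random slot run
      tid <- sprintf("%s_NC", gid)
      lo <- sample(seq_len(n_slots - 1), 1)
      hi <- sample(seq(lo + 1, n_slots), 1)
      exs <- data.frame(tx_id = tid, start = ex_start[lo:hi],
                        end = ex_end[lo:hi], stringsAsFactors = FALSE)
      txdf <- rbind(txdf, data.frame(
        tx_id = tid, gene_id = gid, chrom = chrom, strand = strand,
        start = min(exs$start), end = max(exs$end), biotype = "lncRNA",
        is_mane = FALSE,
        tss = if (strand == "-") max(exs$end) - 1L else min(exs$start),
        exonic_bp = sum(exs$end - exs$start), stringsAsFactors = FALSE))
      ex_l[[length(ex_l) + 1L]] <- exs
    }
    txdf$exonic_bp <- NULL
    tx_l[[i]] <- txdf
    genes_l[[i]] <- data.frame(
      gene_id = gid, symbol = gid, chrom = chrom, strand = strand,
      start = min(txdf$start), end = max(txdf$end), stringsAsFactors = FALSE)
  }
  genes <- gene_models(do.call(rbind, genes_l), do.call(rbind, tx_l),
                       do.call(rbind, ex_l), do.call(rbind, cds_l))

  tx <- genes$transcripts
  tpm <- matrix(stats::rlnorm(nrow(tx) * length(spec$tissues),
                              meanlog = log(20), sdlog = 1),
                nrow = nrow(tx), ncol = length(spec$tissues),
                dimnames = list(tx$tx_id, spec$tissues))
  tpm[stats::runif(length(tpm)) < 0.10] <- 0
  # force tissue-switching dominant isoforms in a few multi-isoform genes
  multi <- names(which(table(tx$gene_id[tx$biotype == "protein_coding"]) >= 2))
  switch_genes <- utils::head(multi, min(5, length(multi)))
  if (length(spec$tissues) >= 2) {
    for (g in switch_genes) {
      ids <- tx$tx_id[tx$gene_id == g & tx$biotype == "protein_coding"]
      tpm[ids, spec$tissues[1]] <- 1
      tpm[ids[1], spec$tissues[1]] <- 100
      tpm[ids, spec$tissues[2]] <- 1
      tpm[ids[2], spec$tissues[2]] <- 100
    }
  }
  list(genes = genes, tpm = tpm, isoform_switch_genes = switch_genes)
}

# Place one SV achieving a context class (and optionally a target TDR in
# `tissue`, rejection-sampling breakpoints). Returns a one-row variants df.
.place_sv <- function(annotation, gene_id, context, svtype, id,
                      target_tdr = NA, tissue = NULL, tol = 0.05,
                      min_tdr = NA, size = NULL, max_tries = 400) {
  genes <- annotation$genes
  g <- genes$genes[genes$genes$gene_id == gene_id, , drop = FALSE]
  mk <- function(start, end, svlen = NULL) {
    data.frame(id = id, chrom = g$chrom, start = start, end = end,
               svtype = svtype,
               svlen = if (is.null(svlen)) end - start else svlen,
               source = "synthetic", qc_flags = "", background_af = NA_real_,
               stringsAsFactors = FALSE)
  }
  if (context == "WHOLE_GENE") {
    pad <- if (!is.null(size) && size > (g$end - g$start)) {
      ceiling((size - (g$end - g$start)) / 2)
    } else 500
    return(mk(g$start - pad, g$end + pad))
  }
  if (context == "INTERGENIC") {
    return(mk(g$end + 5000, g$end + 5000 + (size %||% 1000)))
  }
  tx_ids <- genes$transcripts$tx_id[genes$transcripts$gene_id == gene_id]
  ex <- genes$exons[genes$exons$tx_id %in% tx_ids, , drop = FALSE]
  if (context == "INTRONIC") {
    # largest gap of the exon union, strictly inside the gene span
    o <- order(ex$start)
    cover_end <- cummax(ex$end[o])
    gaps <- data.frame(start = cover_end[-length(o)], end = ex$start[o][-1])
    gaps <- gaps[gaps$end - gaps$start > 200, , drop = FALSE]
    if (!nrow(gaps)) stop("gene ", gene_id, " has no intron wide enough")
    gp <- gaps[which.max(gaps$end - gaps$start), ]
    len <- min(size %||% 800, gp$end - gp$start - 100)
    off <- sample.int(max(gp$end - gp$start - len - 100, 1), 1) - 1L
    return(mk(gp$start + 50 + off, gp$start + 50 + off + len))
  }
  # EXONIC, optionally toward a target TDR in `tissue`
  for (try in seq_len(max_tries)) {
    anchor_ex <- ex[sample(nrow(ex), 1), ]
    if (svtype == "INS") {
      cand <- mk(anchor_ex$start + sample(seq_len(max(anchor_ex$end -
                   anchor_ex$start - 1, 1)), 1), NA, svlen = size %||% 300)
      cand$end <- cand$start
    } else {
      len <- size %||% sample(500:5000, 1)
      s <- max(g$start + 1, anchor_ex$start + sample(-len:0, 1) +
                 sample.int(200, 1))
      cand <- mk(s, s + len)
    }
    sv1 <- sv_set(cand)
    ctx <- classify_context(sv1, genes,
                            data.frame(sv_id = id, gene_id = gene_id))$context
    if (ctx != "EXONIC") next
    if (is.na(target_tdr) && is.na(min_tdr)) return(cand)
    tdr <- compute_tdr(sv1, genes, annotation$tpm, tissue,
                       pairs = data.frame(sv_id = id, gene_id = gene_id))$tdr
    if (is.na(tdr)) next
    if (!is.na(target_tdr) && abs(tdr - target_tdr) <= tol) return(cand)
    if (is.na(target_tdr) && !is.na(min_tdr) && tdr >= min_tdr) return(cand)
  }
  stop("could not satisfy TDR target ", target_tdr, " / minimum ", min_tdr,
       " for gene ", gene_id,
       " (", max_tries, " tries); the gene's isoform structure may make it",
       " unattainable")
}

# Cohort genotype matrix hitting a requested allele frequency exactly
# (HET carriers; spills into HOM when af > 0.5).
.af_genotypes <- function(af, samples) {
  n <- length(samples)
  n_alt <- round(af * 2 * n)
  g <- rep("HOMREF", n)
  n_hom <- max(0L, n_alt - n)
  n_het <- n_alt - 2L * n_hom
  carriers <- sample(n, n_het + n_hom)
  if (n_hom > 0) g[carriers[seq_len(n_hom)]] <- "HOM"
  if (n_het > 0) g[carriers[n_hom + seq_len(n_het)]] <- "HET"
  names(g) <- samples
  g
}

#' Default planted-SV plan for a synthetic background cohort
#'
#' One row per SV to plant: common exonic/intronic deletions (AF 0.05 in one
#' population), rare variants of every type and context (including
#' whole-gene and TDR-targeted exonic deletions, duplications, inversions,
#' insertions and short deletions), and overlap decoys whose support
#' evidence deliberately fails the corroboration threshold.
#'
#' @param spec a [fixture_spec()].
#' @param annotation output of [generate_annotation()].
#' @return data.frame understood by [generate_cohort()], columns `id`,
#'   `gene`, `svtype`, `context`, `size`, `target_tdr`, `validated` and one
#'   `af_<population>` column per cohort.
#' @export
default_sv_plan <- function(spec, annotation) {
  gids <- annotation$genes$genes$gene_id
  pops <- names(spec$populations)
  n <- 0L
  row <- function(gene, svtype, context, size = NA, target_tdr = NA,
                  validated = TRUE, af = stats::setNames(rep(0, length(pops)), pops)) {
    n <<- n + 1L
    out <- data.frame(id = sprintf("plant%03d", n), gene = gene,
                      svtype = svtype, context = context, size = size,
                      target_tdr = target_tdr, validated = validated,
                      stringsAsFactors = FALSE)
    for (p in pops) out[[paste0("af_", p)]] <- unname(af[p])
    out
  }
  af1 <- stats::setNames(rep(0, length(pops)), pops)
  # population-specific variants: alternate the carrying cohort
  rare_in <- function(j) {
    a <- af1; p <- (j - 1) %% length(pops) + 1
    a[p] <- 1 / (2 * spec$populations[p]); a
  }
  common_in <- function(j) {
    a <- af1; a[(j - 1) %% length(pops) + 1] <- 0.05; a
  }
  plan <- list()
  g <- 1
  for (k in 1:6) {  # common DELs
    plan <- c(plan, list(row(gids[g], "DEL", if (k %% 2) "EXONIC" else "INTRONIC",
                             size = 2000, af = common_in(k)))); g <- g + 1
  }
  for (k in 1:4) {  # rare whole-gene DELs (one LONG)
    plan <- c(plan, list(row(gids[g], "DEL", "WHOLE_GENE",
                             size = if (k == 1) 120000 else NA,
                             af = rare_in(k))))
    g <- g + 1
  }
  for (k in 1:4) {  # rare exonic DELs
    plan <- c(plan, list(row(gids[g], "DEL", "EXONIC", size = 2500,
                             af = rare_in(k))))
    g <- g + 1
  }
  for (k in 1:3) {  # rare exonic DUPs
    plan <- c(plan, list(row(gids[g], "DUP", "EXONIC", size = 3000,
                             af = rare_in(k))))
    g <- g + 1
  }
  plan <- c(plan, list(
    row(gids[g], "INV", "EXONIC", size = 4000, af = rare_in(1)),
    row(gids[g + 1], "INS", "EXONIC", size = 400, af = rare_in(2)),
    row(gids[g + 2], "DEL", "EXONIC", size = 150, af = rare_in(1)),   # SHORT
    row(gids[g + 3], "DEL", "INTRONIC", size = 150, af = rare_in(2)), # SHORT
    row(gids[g + 4], "DEL", "EXONIC", size = 2500, af = rare_in(1),
        validated = FALSE),                                     # RO decoy
    row(gids[g + 5], "DUP", "EXONIC", size = 3000, af = rare_in(2),
        validated = FALSE),                                     # RO decoy
    row(gids[g + 6], "DEL", "EXONIC", size = 150, af = rare_in(1),
        validated = FALSE)                                      # regenotype decoy
  ))
  do.call(rbind, plan)
}

#' Generate synthetic background cohorts with planted SVs
#'
#' Plants each plan row at breakpoints achieving its context class (and,
#' when requested, its target TDR in the first tissue to within
#' `spec$tdr_tol`, by rejection sampling), generates per-population
#' genotypes hitting the requested allele frequencies exactly, and builds
#' support evidence: validated medium/long CNVs get a same-type jittered
#' interval with reciprocal overlap > 0.8 (Lumpy or CNVnator for medium,
#' CNVnator for long), decoys get an interval with RO about 0.5; validated
#' short SVs get confident re-genotyped calls, decoys HOMREF everywhere.
#'
#' @param spec a [fixture_spec()].
#' @param annotation output of [generate_annotation()].
#' @param plan planted-SV table (default [default_sv_plan()]).
#' @return list: `cohorts` (named list of [sv_set()], one per population,
#'   each holding the SVs with AF > 0 there), `evidence`
#'   (a [support_evidence()]), `exclusion` (data.frame of problematic
#'   regions in gene-free space), `truth` (plan plus realized coordinates,
#'   achieved first-tissue TDR, expected QC and rarity outcomes).
#' @export
generate_cohort <- function(spec, annotation, plan = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  if (is.null(plan)) plan <- default_sv_plan(spec, annotation)
  pops <- names(spec$populations)
  af_cols <- paste0("af_", pops)
  tissue1 <- spec$tissues[1]

  # validated SVs first, so decoy placements can avoid their footprints:
  # a decoy sitting on top of a validated SV would inherit its support
  ord <- order(!plan$validated)
  placed_l <- list()
  for (i in ord) {
    for (try in 1:60) {
      cand <- .place_sv(annotation, plan$gene[i], plan$context[i],
                        plan$svtype[i], plan$id[i],
                        target_tdr = plan$target_tdr[i], tissue = tissue1,
                        tol = spec$tdr_tol,
                        size = if (is.na(plan$size[i])) NULL else plan$size[i])
      if (plan$validated[i]) break
      prev <- do.call(rbind, placed_l)
      prev <- prev[prev$svtype == cand$svtype & prev$svtype != "INS" &
                     plan$validated[match(prev$id, plan$id)], , drop = FALSE]
      if (is.null(prev) || !nrow(prev) || cand$svtype == "INS" ||
          max(reciprocal_overlap(cand, prev)) <= 0.7) break
    }
    placed_l[[length(placed_l) + 1L]] <- cand
  }
  placed <- do.call(rbind, placed_l)
  placed <- placed[match(plan$id, placed$id), , drop = FALSE]
  rownames(placed) <- NULL

  lumpy <- list(); cnvn <- list(); para <- list()
  tier <- size_tier(placed)
  not_ins <- placed[placed$svtype != "INS", , drop = FALSE]
  for (i in seq_len(nrow(placed))) {
    v <- placed[i, ]
    if (tier[i] %in% c("MEDIUM", "LONG")) {
      jit <- if (plan$validated[i]) 0.03 else 0.5
      shift <- round(v$svlen * jit)
      sup <- data.frame(chrom = v$chrom, start = v$start + shift,
                        end = v$end + shift, svtype = v$svtype,
                        stringsAsFactors = FALSE)
      if (!plan$validated[i]) {
        # a decoy's weak support must not accidentally corroborate any
        # other planted SV of the same type
        same <- not_ins[not_ins$svtype == v$svtype, , drop = FALSE]
        if (nrow(same) &&
            max(reciprocal_overlap(sup, same[, c("chrom", "start", "end")])) > 0.8) {
          next
        }
      }
      if (tier[i] == "LONG" || stats::runif(1) < 0.5) {
        cnvn[[length(cnvn) + 1L]] <- sup
      } else {
        lumpy[[length(lumpy) + 1L]] <- sup
      }
    }
  }

  cohorts <- list()
  gt_by_pop <- list()
  for (p in pops) {
    samples <- sprintf("%s_s%03d", p, seq_len(spec$populations[p]))
    afs <- plan[[paste0("af_", p)]]
    keep <- which(afs > 0)
    if (!length(keep)) next
    g <- t(vapply(keep, function(i) .af_genotypes(afs[i], samples),
                  character(length(samples))))
    rownames(g) <- placed$id[keep]
    cohorts[[p]] <- sv_set(placed[keep, , drop = FALSE], g)
    gt_by_pop[[p]] <- g
  }

  # Paragraph-style re-genotyped calls for SHORT SVs
  short_ids <- placed$id[tier == "SHORT"]
  if (length(short_ids)) {
    all_samples <- unlist(lapply(pops, function(p)
      sprintf("%s_s%03d", p, seq_len(spec$populations[p]))))
    para <- matrix("HOMREF", nrow = length(short_ids), ncol = length(all_samples),
                   dimnames = list(short_ids, all_samples))
    for (id in short_ids) {
      i <- match(id, plan$id)
      if (plan$validated[i]) {
        for (p in pops) {
          if (!is.null(gt_by_pop[[p]]) && id %in% rownames(gt_by_pop[[p]])) {
            para[id, colnames(gt_by_pop[[p]])] <- gt_by_pop[[p]][id, ]
          }
        }
      }
    }
  } else para <- NULL

  evidence <- support_evidence(
    lumpy = if (length(lumpy)) do.call(rbind, lumpy) else NULL,
    cnvnator = if (length(cnvn)) do.call(rbind, cnvn) else NULL,
    paragraph_genotypes = para)

  truth <- cbind(plan, placed[, c("chrom", "start", "end")],
                 svlen = placed$svlen)
  truth$tier <- tier
  tdr1 <- compute_tdr(sv_set(placed), annotation$genes, annotation$tpm,
                      tissue1)
  truth$tdr_tissue1 <- vapply(truth$id, function(id) {
    x <- tdr1$tdr[tdr1$variant_id == id]
    .max_or_na(x)
  }, numeric(1))
  truth$expected_qc_pass <- truth$validated | truth$tier == "OTHER"
  truth$expected_rare <- apply(as.matrix(plan[af_cols]), 1, max) < 0.01
  rownames(truth) <- NULL

  exclusion <- data.frame(
    chrom = c("chr1", "chr2"),
    start = c(20000, 25000), end = c(30000, 35000),
    stringsAsFactors = FALSE)

  list(cohorts = cohorts, evidence = evidence, exclusion = exclusion,
       truth = truth)
}

#' Generate a synthetic patient cohort with one planted pathogenic SV each
#'
#' Builds a disease panel (dominant disease genes expressed in the disease
#' tissue, plus listed recessive genes), then gives every patient one
#' pathogenic SV - a rare exonic or whole-gene deletion/duplication of a
#' listed dominant gene with first-tissue TDR above the reporting threshold
#' - hidden among a shared pool of benign calls: common CNVs matching the
#' background database, rare intronic/intergenic variants, rare exonic hits
#' in unlisted genes, heterozygous hits in recessive genes, and a few
#' quality-control decoys without corroborating support.
#'
#' @param spec a [fixture_spec()].
#' @param annotation output of [generate_annotation()].
#' @param cohort output of [generate_cohort()] (supplies the common SVs to
#'   imitate and the background cohorts the database is built from).
#' @param n_patients number of patients.
#' @return list: `patients` (an [sv_set()], one genotype column per
#'   patient), `evidence` (a [support_evidence()]), `gene_list`,
#'   `annotations` (a [gene_annotations()]), `tissue`, `truth` (data.frame
#'   `sample`, `pathogenic_sv_id`, `gene_id`).
#' @export
generate_patient_cohort <- function(spec, annotation, cohort,
                                    n_patients = 50) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  genes <- annotation$genes
  tissue1 <- spec$tissues[1]
  gids <- genes$genes$gene_id

  # genes expressed in the disease tissue, by total TPM
  expr_tot <- vapply(gids, function(g) {
    tx <- genes$transcripts$tx_id[genes$transcripts$gene_id == g]
    sum(annotation$tpm[tx, tissue1])
  }, numeric(1))
  expressed <- gids[expr_tot > 5]
  ad_genes <- utils::head(expressed, 8)
  ar_genes <- utils::head(setdiff(expressed, ad_genes), 3)
  unlisted <- setdiff(expressed, c(ad_genes, ar_genes))
  gene_list <- c(ad_genes, ar_genes)

  omim <- data.frame(gene_id = c(ad_genes, ar_genes),
                     modes = c(rep("AD", length(ad_genes)),
                               rep("AR", length(ar_genes))),
                     stringsAsFactors = FALSE)
  mods <- matrix(0.6, nrow = length(gids), ncol = length(spec$tissues),
                 dimnames = list(gids, spec$tissues))
  mods[ad_genes, tissue1] <- 0.1
  annotations <- gene_annotations(mods = mods, omim = omim)

  patients <- sprintf("patient%03d", seq_len(n_patients))
  pool <- list(); pool_gt <- list()
  add_pool <- function(vrow, gt) {
    pool[[length(pool) + 1L]] <<- vrow
    pool_gt[[length(pool_gt) + 1L]] <<- gt
  }
  het_all <- stats::setNames(rep("HET", n_patients), patients)

  # benign: jittered copies of the background cohort's common SVs
  # (several distinct call representations per common SV, as real merged
  # callsets show)
  common_truth <- cohort$truth[!cohort$truth$expected_rare, , drop = FALSE]
  k <- 0L
  for (i in seq_len(nrow(common_truth))) {
    tr <- common_truth[i, ]
    for (rep_i in 1:8) {
      shift <- round(tr$svlen * 0.01 * rep_i)
      k <- k + 1L
      add_pool(data.frame(id = sprintf("benign_common%03d", k),
                          chrom = tr$chrom,
                          start = tr$start + shift, end = tr$end + shift,
                          svtype = tr$svtype, svlen = tr$svlen,
                          source = "synthetic", qc_flags = "",
                          background_af = NA_real_, stringsAsFactors = FALSE),
               het_all)
    }
  }
  # benign: rare intronic / intergenic
  for (k in seq_len(20)) {
    g <- sample(gids, 1)
    ctx <- if (k %% 2) "INTRONIC" else "INTERGENIC"
    add_pool(.place_sv(annotation, g, ctx, "DEL",
                       sprintf("benign_noncoding%03d", k), size = 700),
             het_all)
  }
  # benign: rare exonic in unlisted genes
  for (k in seq_len(12)) {
    g <- unlisted[(k - 1) %% length(unlisted) + 1]
    add_pool(.place_sv(annotation, g, "EXONIC", "DEL",
                       sprintf("benign_unlisted%03d", k), size = 2200),
             het_all)
  }
  # benign: heterozygous exonic hits in recessive genes
  for (k in seq_along(ar_genes)) {
    add_pool(.place_sv(annotation, ar_genes[k], "EXONIC", "DEL",
                       sprintf("benign_ar%03d", k), size = 2600),
             het_all)
  }
  # benign: QC decoys (medium CNVs that will lack credible support)
  decoy_ids <- sprintf("benign_decoy%03d", 1:3)
  for (k in 1:3) {
    g <- sample(gids, 1)
    add_pool(.place_sv(annotation, g, "EXONIC", "DEL", decoy_ids[k],
                       size = 2400), het_all)
  }

  # one pathogenic SV per patient, distinct breakpoints
  truth <- data.frame(sample = patients, pathogenic_sv_id = NA_character_,
                      gene_id = NA_character_, stringsAsFactors = FALSE)
  for (pi in seq_len(n_patients)) {
    g <- ad_genes[(pi - 1) %% length(ad_genes) + 1]
    id <- sprintf("patho%03d", pi)
    style <- pi %% 3
    vrow <- if (style == 0) {
      .place_sv(annotation, g, "WHOLE_GENE", "DEL", id)
    } else if (style == 1) {
      .place_sv(annotation, g, "EXONIC", "DEL", id, min_tdr = 0.4,
                tissue = tissue1, size = 4000 + pi)
    } else {
      .place_sv(annotation, g, "WHOLE_GENE", "DUP", id)
    }
    gt <- stats::setNames(rep("HOMREF", n_patients), patients)
    gt[patients[pi]] <- "HET"
    add_pool(vrow, gt)
    truth$pathogenic_sv_id[pi] <- id
    truth$gene_id[pi] <- g
  }

  variants <- do.call(rbind, pool)
  gmat <- do.call(rbind, pool_gt)
  rownames(gmat) <- variants$id
  patients_set <- sv_set(variants, gmat)

  # support evidence: everything corroborated except the decoys
  tier <- size_tier(variants)
  sup <- list(); para_ids <- character(0)
  for (i in seq_len(nrow(variants))) {
    if (!tier[i] %in% c("MEDIUM", "LONG")) {
      if (tier[i] == "SHORT") para_ids <- c(para_ids, variants$id[i])
      next
    }
    jit <- if (variants$id[i] %in% decoy_ids) 0.5 else 0.03
    shift <- round(variants$svlen[i] * jit)
    sup[[length(sup) + 1L]] <- data.frame(
      chrom = variants$chrom[i], start = variants$start[i] + shift,
      end = variants$end[i] + shift, svtype = variants$svtype[i],
      stringsAsFactors = FALSE)
  }
  para <- if (length(para_ids)) {
    gmat[para_ids, , drop = FALSE]
  } else NULL
  evidence <- support_evidence(cnvnator = do.call(rbind, sup),
                               paragraph_genotypes = para)

  list(patients = patients_set, evidence = evidence, gene_list = gene_list,
       annotations = annotations, tissue = tissue1, truth = truth)
}

#' Generate per-tissue expression with TDR-proportional dosage effects
#'
#' Baseline linear expression per gene is log-normal; a carrier's value is
#' multiplied by the copy-dosage factor implied by its variant and TDR:
#' heterozygous deletions by `1 - 0.5 * TDR` (one of two copies lost over
#' the disrupted expression fraction), homozygous deletions by `1 - TDR`,
#' duplications by `1 + 0.5 * TDR` per extra copy. Gaussian noise of sd
#' `spec$noise_sd` acts on the log2 scale, plus an optional known batch
#' confounder with loading `spec$confounder_loading`. Values are returned
#' log2-transformed (`log2(x + 1)`).
#'
#' @param spec a [fixture_spec()].
#' @param annotation output of [generate_annotation()].
#' @param carriers data.frame with columns `sample`, `gene_id`, `svtype`,
#'   `genotype` (`HET`/`HOM`) and `tdr` (used in every tissue), or `NULL`
#'   for a null cohort.
#' @param samples character vector of sample names (must cover
#'   `carriers$sample`).
#' @param tissues tissues to simulate (default all in `spec`).
#' @return list: `expr` (named list of samples x genes log2 matrices),
#'   `covariates` (data.frame with the batch confounder), `carriers`.
#' @export
generate_expression <- function(spec, annotation, carriers = NULL,
                                samples = sprintf("s%03d", 1:200),
                                tissues = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 3L)
  if (is.null(tissues)) tissues <- spec$tissues
  gids <- annotation$genes$genes$gene_id
  if (!is.null(carriers) && !all(carriers$sample %in% samples)) {
    stop("carriers reference samples outside `samples`")
  }
  batch <- stats::rnorm(length(samples))
  mult <- matrix(1, nrow = length(samples), ncol = length(gids),
                 dimnames = list(samples, gids))
  if (!is.null(carriers)) {
    for (i in seq_len(nrow(carriers))) {
      tdr <- carriers$tdr[i]
      if (is.na(tdr)) next
      f <- switch(carriers$svtype[i],
        DEL = if (carriers$genotype[i] == "HOM") 1 - tdr else 1 - 0.5 * tdr,
        DUP = if (carriers$genotype[i] == "HOM") 1 + tdr else 1 + 0.5 * tdr,
        1)
      mult[carriers$sample[i], carriers$gene_id[i]] <-
        mult[carriers$sample[i], carriers$gene_id[i]] * f
    }
  }
  expr <- lapply(tissues, function(tis) {
    mu <- stats::rnorm(length(gids), mean = log2(100), sd = 1)
    base <- 2^(matrix(mu, nrow = length(samples), ncol = length(gids),
                      byrow = TRUE) +
               spec$confounder_loading * batch +
               matrix(stats::rnorm(length(samples) * length(gids),
                                   sd = spec$noise_sd),
                      nrow = length(samples)))
    m <- log2(base * mult + 1)
    dimnames(m) <- list(samples, gids)
    m
  })
  names(expr) <- tissues
  list(expr = expr,
       covariates = data.frame(batch = batch, row.names = samples),
       carriers = carriers)
}

#' Write a full synthetic fixture bundle to disk
#'
#' Emits every input format the toolkit consumes: the annotation GTF, the
#' TPM TSV, one SV VCF per background population, support-evidence BEDs
#' (with the SV type in column 4), a re-genotyped short-SV VCF, the
#' exclusion-region BED and the truth table TSV.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_bundle <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(spec)
  cohort <- generate_cohort(spec, ann)
  files <- c(gtf = file.path(out_dir, "annotation.gtf"),
             tpm = file.path(out_dir, "tpm.tsv"),
             exclusion = file.path(out_dir, "exclusion.bed"),
             truth = file.path(out_dir, "truth.tsv"))
  write_gtf(ann$genes, files["gtf"])
  write_tpm(ann$tpm, files["tpm"])
  utils::write.table(cohort$exclusion, files["exclusion"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$truth, files["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in names(cohort$cohorts)) {
    f <- file.path(out_dir, sprintf("cohort_%s.vcf", p))
    write_sv_vcf(cohort$cohorts[[p]], f)
    files[paste0("vcf_", p)] <- f
  }
  ev <- cohort$evidence
  for (nm in c("lumpy", "cnvnator")) {
    f <- file.path(out_dir, paste0(nm, ".bed"))
    utils::write.table(ev[[nm]][, c("chrom", "start", "end", "svtype")], f,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files[nm] <- f
  }
  if (!is.null(ev$paragraph)) {
    ids <- rownames(ev$paragraph)
    truth_rows <- cohort$truth[match(ids, cohort$truth$id), , drop = FALSE]
    pg <- sv_set(data.frame(id = ids, chrom = truth_rows$chrom,
                            start = truth_rows$start, end = truth_rows$end,
                            svtype = truth_rows$svtype,
                            svlen = truth_rows$svlen,
                            stringsAsFactors = FALSE),
                 ev$paragraph)
    f <- file.path(out_dir, "paragraph.vcf")
    write_sv_vcf(pg, f)
    files["paragraph"] <- f
  }
  invisible(files)
}
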