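#' Population allele frequency of SVs
#'
#' Alternate-allele frequency over a cohort: a `HET` genotype contributes one
#' alternate allele, `HOM` two; the denominator is twice the number of
#' samples with a non-`MISSING` genotype. Variants with no genotyped sample
#' get `NA`.
#'
#' @param svs an [sv_set()] with genotypes.
#' @param samples character vector of cohort sample names (default: all
#'   samples in the set).
#' @return Named numeric vector of allele frequencies, one per variant.
#' @export
compute_pop_af <- function(svs, samples = NULL) {
  stopifnot(inherits(svs, "sv_set"))
  g <- svs$genotypes
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(g))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    g <- g[, samples, drop = FALSE]
  }
  if (ncol(g) == 0L) stop("sv_set has no genotypes")
  alt <- rowSums(g == "HET") + 2 * rowSums(g == "HOM")
  denom <- 2 * rowSums(g != "MISSING")
  af <- ifelse(denom > 0, alt / denom, NA_real_)
  names(af) <- svs$variants$id
  af
}

# Minimal union-find.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# Merge predicate between two variant rows of the same svtype.
.merge_edge <- function(a, b, ro_threshold, ins_dist, ins_len_ratio) {
  if (a$chrom != b$chrom) return(FALSE)
  if (a$svtype == "INS") {
    abs(a$start - b$start) <= ins_dist &&
      min(a$svlen, b$svlen) / max(a$svlen, b$svlen) > ins_len_ratio
  } else {
    reciprocal_overlap(a, b) > ro_threshold
  }
}

#' Cross-cohort SV clustering
#'
#' Merges SV calls across population cohorts Jasmine-style: within each SV
#' type, two calls are linked when their reciprocal overlap is strictly
#' > `ro_threshold`; clusters are the connected components of that graph
#' (single linkage), so merging is independent of cohort input order.
#' Insertions, being zero-width anchors, use an anchor-distance and
#' inserted-length-ratio predicate instead of interval overlap.
#'
#' The cluster representative is the member with the largest carrier count
#' (ties: smallest start, then smallest end).
#'
#' @param cohorts named list of [sv_set()] objects; names are population
#'   labels.
#' @param ro_threshold reciprocal-overlap merge threshold (strict; default
#'   0.8).
#' @param ins_dist maximum insertion anchor distance in bp (default 100).
#' @param ins_len_ratio minimum inserted-length ratio (strict; default 0.8).
#' @return An object of class `sv_clusters`: list with `clusters`
#'   (data.frame `cluster_id`, `svtype`, `chrom`, `start`, `end`, `svlen`,
#'   `n_members`) and `members` (data.frame `cluster_id`, `population`,
#'   `sv_id`, `carriers`).
#' @export
cluster_svs <- function(cohorts, ro_threshold = 0.8, ins_dist = 100,
                        ins_len_ratio = 0.8) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  pool <- do.call(rbind, lapply(names(cohorts), function(p) {
    x <- cohorts[[p]]
    stopifnot(inherits(x, "sv_set"))
    v <- x$variants[, c("id", "chrom", "start", "end", "svtype", "svlen")]
    v$population <- p
    v$carriers <- if (ncol(x$genotypes))
      apply(x$genotypes, 1, function(g) sum(g %in% c("HET", "HOM"))) else 0L
    v
  }))
  # canonical input order so components and representatives are reproducible
  pool <- pool[order(pool$svtype, pool$chrom, pool$start, pool$end,
                     pool$population, pool$id), , drop = FALSE]
  rownames(pool) <- NULL
  n <- nrow(pool)
  parent <- .uf_new(n)
  for (grp in split(seq_len(n), paste(pool$svtype, pool$chrom))) {
    if (length(grp) < 2) next
    for (ii in seq_along(grp)[-length(grp)]) {
      i <- grp[ii]
      for (jj in seq((ii + 1), length(grp))) {
        j <- grp[jj]
        if (.merge_edge(pool[i, ], pool[j, ], ro_threshold, ins_dist,
                        ins_len_ratio)) {
          parent <- .uf_union(parent, i, j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  comp <- split(seq_len(n), root)
  reps <- vapply(comp, function(idx) {
    m <- pool[idx, , drop = FALSE]
    o <- order(-m$carriers, m$start, m$end)
    idx[o[1]]
  }, integer(1))
  o <- order(pool$svtype[reps], pool$chrom[reps], pool$start[reps],
             pool$end[reps])
  comp <- comp[o]; reps <- reps[o]
  cluster_id <- sprintf("cl%04d", seq_along(comp))
  clusters <- data.frame(
    cluster_id = cluster_id,
    svtype = pool$svtype[reps], chrom = pool$chrom[reps],
    start = pool$start[reps], end = pool$end[reps], svlen = pool$svlen[reps],
    n_members = lengths(comp), stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(seq_along(comp), function(k) {
    m <- pool[comp[[k]], , drop = FALSE]
    data.frame(cluster_id = cluster_id[k], population = m$population,
               sv_id = m$id, carriers = m$carriers, stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  structure(list(clusters = clusters, members = members),
            class = "sv_clusters")
}

#' @export
print.sv_clusters <- function(x, ...) {
  cat(sprintf("sv_clusters: %d clusters over %d member calls\n",
              nrow(x$clusters), nrow(x$members)))
  invisible(x)
}

#' Assign the combined background allele frequency
#'
#' The background AF of a merged SV is the maximum of its per-population
#' AFs; an SV is rare when this combined AF is strictly < `rare_threshold`.
#' Populations in which the SV was not observed contribute AF 0.
#'
#' @param db data.frame with per-population AF columns named `af_<pop>`.
#' @param rare_threshold rarity cutoff on the combined AF (strict `<`;
#'   default 0.01).
#' @return `db` with columns `background_af` and `rare` appended/updated.
#' @export
assign_background_af <- function(db, rare_threshold = 0.01) {
  af_cols <- grep("^af_", names(db), value = TRUE)
  if (!length(af_cols)) stop("no af_<pop> columns in db")
  af <- as.matrix(db[af_cols])
  af[is.na(af)] <- 0
  db$background_af <- apply(af, 1, max)
  db$rare <- db$background_af < rare_threshold
  db
}

#' Build the multi-ancestry background AF database
#'
#' Clusters QC-passed cohort call sets with [cluster_svs()], computes the
#' per-population AF of each cluster (the maximum member AF within that
#' cohort; 0 for cohorts without a member) and assigns the combined
#' background AF and rarity flag with [assign_background_af()].
#'
#' @inheritParams cluster_svs
#' @inheritParams assign_background_af
#' @return data.frame: one row per merged SV with representative interval,
#'   `af_<pop>` columns, `background_af` and `rare`.
#' @export
build_background_db <- function(cohorts, ro_threshold = 0.8,
                                rare_threshold = 0.01, ins_dist = 100,
                                ins_len_ratio = 0.8) {
  cl <- cluster_svs(cohorts, ro_threshold, ins_dist, ins_len_ratio)
  pops <- names(cohorts)
  afs <- lapply(pops, function(p) compute_pop_af(cohorts[[p]]))
  names(afs) <- pops
  db <- cl$clusters
  for (p in pops) {
    col <- vapply(db$cluster_id, function(cid) {
      ids <- cl$members$sv_id[cl$members$cluster_id == cid &
                              cl$members$population == p]
      if (!length(ids)) return(0)
      max(afs[[p]][ids], 0, na.rm = TRUE)
    }, numeric(1))
    db[[paste0("af_", p)]] <- unname(col)
  }
  assign_background_af(db, rare_threshold)
}

#' Annotate a patient call set with background AFs
#'
#' Matches each patient SV against the background database (same type,
#' reciprocal overlap strictly > `ro_threshold`; insertions by anchor
#' distance and length ratio) and fills `background_af` with the maximum AF
#' over matching database entries, or 0 when the SV is absent from every
#' background cohort.
#'
#' @param svs an [sv_set()].
#' @param db background database from [build_background_db()].
#' @inheritParams cluster_svs
#' @return The annotated [sv_set()].
#' @export
annotate_background_af <- function(svs, db, ro_threshold = 0.8,
                                   ins_dist = 100, ins_len_ratio = 0.8) {
  stopifnot(inherits(svs, "sv_set"))
  v <- svs$variants
  af <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    cand <- db[db$svtype == v$svtype[i] & db$chrom == v$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    hit <- if (v$svtype[i] == "INS") {
      abs(cand$start - v$start[i]) <= ins_dist &
        pmin(cand$svlen, v$svlen[i]) / pmax(cand$svlen, v$svlen[i]) > ins_len_ratio
    } else {
      reciprocal_overlap(v[i, ], cand) > ro_threshold
    }
    if (any(hit)) af[i] <- max(cand$background_af[hit])
  }
  svs$variants$background_af <- af
  svs
}
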