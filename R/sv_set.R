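#' Construct an SV call set
#'
#' The central container for structural-variant records. `variants` holds one
#' row per SV with 0-based half-open coordinates; `genotypes` is a character
#' matrix (one row per SV, one column per sample) with values `"HOMREF"`,
#' `"HET"`, `"HOM"` or `"MISSING"`. Insertions are stored as a zero-width
#' anchor (`end == start`) with `svlen` the inserted length; for DEL/DUP/INV,
#' `svlen` equals the interval length.
#'
#' @param variants data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (DEL/DUP/INV/INS), `svlen`; optional `source`, `qc_flags`
#'   (`;`-joined strings) and `background_af` are filled with defaults.
#' @param genotypes character matrix with `rownames` matching `variants$id`,
#'   or `NULL` for a call set without genotypes.
#' @return An object of class `sv_set`.
#' @export
sv_set <- function(variants, genotypes = NULL) {
  need <- c("id", "chrom", "start", "end", "svtype", "svlen")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "))
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$svtype <- as.character(variants$svtype)
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  bad_type <- setdiff(unique(variants$svtype), c("DEL", "DUP", "INV", "INS"))
  if (length(bad_type)) stop("unsupported svtype: ", paste(bad_type, collapse = ", "))
  if (any(variants$start < 0)) stop("negative start coordinate")
  if (any(variants$svlen <= 0)) stop("svlen must be positive")
  itv <- variants$svtype != "INS"
  if (any(variants$end[itv] - variants$start[itv] != variants$svlen[itv])) {
    stop("for DEL/DUP/INV, svlen must equal end - start")
  }
  if (any(variants$end[!itv] != variants$start[!itv])) {
    stop("INS records must be zero-width anchors (end == start)")
  }
  if (is.null(variants$source)) variants$source <- NA_character_
  if (is.null(variants$qc_flags)) variants$qc_flags <- ""
  if (is.null(variants$background_af)) variants$background_af <- NA_real_
  if (is.null(genotypes)) {
    genotypes <- matrix(character(0), nrow = nrow(variants), ncol = 0,
                        dimnames = list(variants$id, NULL))
  } else {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != nrow(variants) ||
        !identical(rownames(genotypes), variants$id)) {
      genotypes <- genotypes[variants$id, , drop = FALSE]
    }
    bad_gt <- setdiff(unique(as.vector(genotypes)),
                      c("HOMREF", "HET", "HOM", "MISSING"))
    if (length(bad_gt)) stop("invalid genotype codes: ", paste(bad_gt, collapse = ", "))
  }
  rownames(variants) <- NULL
  structure(list(variants = variants, genotypes = genotypes), class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  tab <- table(x$variants$svtype)
  cat(sprintf("sv_set: %d variants (%s), %d samples\n",
              nrow(x$variants),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$genotypes)))
  invisible(x)
}

#' @export
length.sv_set <- function(x) nrow(x$variants)

#' Subset an SV call set by variant id
#'
#' @param x an `sv_set`.
#' @param ids character vector of variant ids to keep (order preserved).
#' @return The subset `sv_set`.
#' @export
sv_subset <- function(x, ids) {
  stopifnot(inherits(x, "sv_set"))
  keep <- match(ids, x$variants$id)
  if (anyNA(keep)) stop("unknown variant ids: ",
                        paste(ids[is.na(keep)], collapse = ", "))
  sv_set(x$variants[keep, , drop = FALSE],
         x$genotypes[keep, , drop = FALSE])
}

# Append a qc flag to selected rows (internal).
.add_flag <- function(variants, rows, flag) {
  cur <- variants$qc_flags[rows]
  variants$qc_flags[rows] <- ifelse(cur == "" | is.na(cur), flag,
                                    paste(cur, flag, sep = ";"))
  variants
}

#' Carrier samples of a variant
#'
#' @param x an `sv_set`.
#' @param id a single variant id.
#' @return Character vector of sample names with a non-reference genotype
#'   (`HET` or `HOM`).
#' @export
sv_carriers <- function(x, id) {
  gt <- x$genotypes[id, ]
  colnames(x$genotypes)[gt %in% c("HET", "HOM")]
}
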