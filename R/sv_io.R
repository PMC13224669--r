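#' Read a structural-variant VCF into an `sv_set`
#'
#' Reads Manta-style SV VCFs (symbolic ALT alleles with `SVTYPE`, `END` and/or
#' `SVLEN` INFO fields plus `GT` genotypes). VCF 1-based inclusive coordinates
#' are converted to the package's 0-based half-open convention: a deletion
#' with `POS=1001`, `END=1100` becomes the interval `[1000, 1100)`. Insertions
#' become zero-width anchors with `svlen` taken from `SVLEN`. Multi-allelic
#' lines are split into one record per ALT allele. Records whose `SVTYPE` is
#' not DEL, DUP, INV, INS or BND are skipped with a message; BND records are
#' paired and converted to inversions (see [convert_bnd_to_inv()]) unless
#' `convert_bnd = FALSE`, in which case they are dropped.
#'
#' Genotypes are recoded to `HOMREF`/`HET`/`HOM`/`MISSING`; half-called
#' genotypes such as `./1` are treated as `MISSING`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param dialect caller label recorded in the `source` column.
#' @param convert_bnd convert mated same-chromosome BND pairs with
#'   inversion-compatible orientation to INV records (default `TRUE`).
#' @return An [sv_set()].
#' @export
read_sv_vcf <- function(path, dialect = "manta", convert_bnd = TRUE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body)) {
    nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
    if (any(nfield < 8)) {
      bad <- which(nfield < 8)[1] + sum(startsWith(lines, "#"))
      stop("malformed VCF record (fewer than 8 fields) at line ", bad)
    }
  } else {
    return(sv_set(.empty_variants()))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  gt_raw <- if (ncol(vcf@gt) > 1) vcf@gt[, -1, drop = FALSE] else NULL
  if (!is.null(gt_raw) && is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  }

  out <- list(); gts <- list(); bnd <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix[i, "POS"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    svtype <- .info_field(info[i], "SVTYPE")
    endv <- suppressWarnings(as.integer(.info_field(info[i], "END")))
    svlens <- suppressWarnings(as.numeric(strsplit(
      .info_field(info[i], "SVLEN") %||% NA_character_, ",", fixed = TRUE)[[1]]))
    mateid <- .info_field(info[i], "MATEID")
    bg_af <- suppressWarnings(as.numeric(
      .info_field(info[i], "BACKGROUND_AF") %||% NA_character_))
    id0 <- fix[i, "ID"]
    if (is.na(id0) || id0 == ".") id0 <- sprintf("sv_line%d", i)
    for (k in seq_along(alts)) {
      id <- if (length(alts) > 1) sprintf("%s_alt%d", id0, k) else id0
      st <- svtype %||% .alt_svtype(alts[k])
      if (is.null(st) || is.na(st)) { n_skipped <- n_skipped + 1L; next }
      gt_codes <- if (is.null(gt_raw)) NULL else .recode_gt(gt_raw[i, ], k)
      if (st == "BND") {
        bnd[[length(bnd) + 1L]] <- list(
          row = data.frame(id = id, chrom = fix[i, "CHROM"], pos = pos - 1L,
                           alt = alts[k], mateid = mateid %||% NA_character_,
                           stringsAsFactors = FALSE),
          gt = gt_codes)
        next
      }
      if (!st %in% c("DEL", "DUP", "INV", "INS")) { n_skipped <- n_skipped + 1L; next }
      svlen <- if (k <= length(svlens)) abs(svlens[k]) else NA_real_
      start0 <- pos - 1L
      if (st == "INS") {
        end0 <- start0
        if (is.na(svlen)) { n_skipped <- n_skipped + 1L; next }
      } else {
        end0 <- if (!is.na(endv)) endv else if (!is.na(svlen)) start0 + svlen else NA
        if (is.na(end0)) { n_skipped <- n_skipped + 1L; next }
        svlen <- end0 - start0
      }
      out[[length(out) + 1L]] <- data.frame(
        id = id, chrom = fix[i, "CHROM"], start = start0, end = end0,
        svtype = st, svlen = svlen, source = dialect, qc_flags = "",
        background_af = bg_af, stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- gt_codes
    }
  }
  if (n_skipped > 0) {
    message(n_skipped, " record(s) with unsupported or incomplete SVTYPE skipped")
  }
  variants <- if (length(out)) do.call(rbind, out) else .empty_variants()
  gmat <- .bind_gt(gts, variants$id, colnames(gt_raw))
  res <- sv_set(variants, gmat)

  if (length(bnd)) {
    bnd_df <- do.call(rbind, lapply(bnd, `[[`, "row"))
    bnd_gt <- .bind_gt(lapply(bnd, `[[`, "gt"), bnd_df$id, colnames(gt_raw))
    if (convert_bnd) {
      inv <- convert_bnd_to_inv(bnd_df, bnd_gt, dialect = dialect)
      if (length(inv)) {
        res <- sv_set(rbind(res$variants, inv$variants),
                      rbind(res$genotypes, inv$genotypes))
      }
    } else {
      message(nrow(bnd_df), " BND record(s) dropped (convert_bnd = FALSE)")
    }
  }
  res
}

.empty_variants <- function() {
  data.frame(id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), svtype = character(0), svlen = numeric(0),
             source = character(0), qc_flags = character(0),
             background_af = numeric(0), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (!length(m)) return(NULL)
  sub(paste0("^;?", key, "="), "", m)
}

# SVTYPE fallback from a symbolic ALT like <DEL> or a breakend ALT.
.alt_svtype <- function(alt) {
  if (grepl("^<(DEL|DUP|INV|INS)", alt)) sub("^<([A-Z]+).*", "\\1", alt)
  else if (grepl("\\[|\\]", alt)) "BND"
  else NULL
}

# GT string vector -> HOMREF/HET/HOM/MISSING for ALT allele k.
.recode_gt <- function(gt_strings, k = 1L) {
  gt <- sub(":.*", "", gt_strings)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".") || any(!a %in% c("0", as.character(k)))) {
      if (length(a) == 2 && !any(a == ".") && all(a %in% c("0", as.character(0:9)))) {
        # diploid call on another ALT allele: reference for this allele
        return(if (any(a == as.character(k))) "HET" else "HOMREF")
      }
      return("MISSING")
    }
    n_alt <- sum(a == as.character(k))
    c("HOMREF", "HET", "HOM")[n_alt + 1L]
  }, character(1))
}

.bind_gt <- function(gts, ids, samples) {
  gts <- gts[!vapply(gts, is.null, logical(1))]
  if (!length(gts) || is.null(samples)) {
    return(matrix(character(0), nrow = length(ids), ncol = 0,
                  dimnames = list(ids, NULL)))
  }
  m <- do.call(rbind, gts)
  dimnames(m) <- list(ids, samples)
  m
}

#' Convert mated breakend (BND) pairs to inversions
#'
#' Breakend records are paired by `MATEID` when present, otherwise by
#' reciprocal coordinate matching of the ALT bracket target. A pair is
#' converted to a single INV record when both mates lie on the same
#' chromosome and their ALT brackets have the same orientation (both `]` or
#' both `[`), the signature of an inversion junction. Inter-chromosomal
#' pairs (translocations), orientation-incompatible pairs and unmated records
#' are dropped with a warning.
#'
#' @param bnd data.frame with columns `id`, `chrom`, `pos` (0-based), `alt`
#'   and optionally `mateid`.
#' @param genotypes optional genotype matrix with rownames matching `bnd$id`;
#'   the converted INV inherits the genotypes of its leftmost mate.
#' @param dialect caller label for the `source` column.
#' @return An [sv_set()] of INV records (possibly empty).
#' @export
convert_bnd_to_inv <- function(bnd, genotypes = NULL, dialect = "manta") {
  if (is.null(bnd$mateid)) bnd$mateid <- NA_character_
  m <- regexpr("[\\[\\]][^\\[\\]]+[\\[\\]]", bnd$alt, perl = TRUE)
  tgt <- rep(NA_character_, nrow(bnd))
  tgt[m != -1] <- regmatches(bnd$alt, m)
  bnd$bracket <- ifelse(grepl("]", bnd$alt, fixed = TRUE), "]", "[")
  bnd$mate_chrom <- NA_character_; bnd$mate_pos <- NA_integer_
  ok <- !is.na(tgt)
  parts <- strsplit(gsub("[\\[\\]]", "", tgt[ok], perl = TRUE), ":", fixed = TRUE)
  bnd$mate_chrom[ok] <- vapply(parts, `[`, character(1), 1)
  bnd$mate_pos[ok] <- as.integer(vapply(parts, `[`, character(1), 2)) - 1L

  used <- rep(FALSE, nrow(bnd))
  out <- list(); gts <- list(); n_dropped <- 0L
  for (i in seq_len(nrow(bnd))) {
    if (used[i]) next
    j <- NA_integer_
    if (!is.na(bnd$mateid[i])) {
      j <- match(bnd$mateid[i], bnd$id)
    }
    if (is.na(j)) {
      cand <- which(!used & seq_len(nrow(bnd)) != i &
                    bnd$chrom == bnd$mate_chrom[i] &
                    bnd$pos == bnd$mate_pos[i] &
                    bnd$mate_chrom == bnd$chrom[i] &
                    bnd$mate_pos == bnd$pos[i])
      if (length(cand)) j <- cand[1]
    }
    if (is.na(j) || used[j] || j == i) { n_dropped <- n_dropped + 1L; used[i] <- TRUE; next }
    used[c(i, j)] <- TRUE
    if (bnd$chrom[i] != bnd$chrom[j] || bnd$bracket[i] != bnd$bracket[j]) {
      n_dropped <- n_dropped + 2L
      next
    }
    lo <- min(bnd$pos[i], bnd$pos[j]); hi <- max(bnd$pos[i], bnd$pos[j])
    if (hi <= lo) { n_dropped <- n_dropped + 2L; next }
    first <- if (bnd$pos[i] <= bnd$pos[j]) i else j
    out[[length(out) + 1L]] <- data.frame(
      id = paste0(bnd$id[first], "_inv"), chrom = bnd$chrom[i],
      start = lo, end = hi, svtype = "INV", svlen = hi - lo,
      source = dialect, qc_flags = "bnd2inv", background_af = NA_real_,
      stringsAsFactors = FALSE)
    gts[[length(gts) + 1L]] <-
      if (!is.null(genotypes) && ncol(genotypes)) genotypes[bnd$id[first], ] else NULL
  }
  if (n_dropped > 0) {
    warning(n_dropped, " BND record(s) dropped: unmated, inter-chromosomal, ",
            "or orientation-incompatible")
  }
  variants <- if (length(out)) do.call(rbind, out) else .empty_variants()
  sv_set(variants, .bind_gt(gts, variants$id,
                            if (is.null(genotypes)) NULL else colnames(genotypes)))
}

#' Read a BED interval file
#'
#' Reads BED3+ keeping BED's native 0-based half-open coordinates. Comment,
#' `track` and `browser` lines are skipped. Lines with non-numeric
#' coordinates raise an error naming the line; lines with `end <= start` are
#' rejected individually with a warning naming the line.
#'
#' @param path path to a BED file.
#' @param svtype_col optional 1-based column index holding an SV-type label
#'   (used for typed support-evidence BEDs); stored as column `svtype`.
#' @return data.frame with columns `chrom`, `start`, `end` (and `svtype` if
#'   requested).
#' @export
read_interval_bed <- function(path, svtype_col = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.null(svtype_col)) empty$svtype <- character(0)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3)) {
    stop("BED line ", lineno[which(lengths(fields) < 3)[1]], ": fewer than 3 columns")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinates")
  }
  bad <- end <= start
  if (any(bad)) {
    warning("rejected ", sum(bad), " BED record(s) with end <= start (line ",
            paste(lineno[bad], collapse = ", "), ")")
  }
  out <- data.frame(chrom = vapply(fields, `[`, character(1), 1),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  if (!is.null(svtype_col)) {
    out$svtype <- vapply(fields, function(f)
      if (length(f) >= svtype_col) f[svtype_col] else NA_character_,
      character(1))[!bad]
  }
  rownames(out) <- NULL
  out
}

#' Write an `sv_set` as a VCF file
#'
#' Emits VCF 4.2 with symbolic ALT alleles and `SVTYPE`/`END`/`SVLEN` INFO
#' fields plus `GT` genotypes, the inverse of [read_sv_vcf()]: internal
#' 0-based half-open coordinates go back to 1-based inclusive. `SVLEN` is
#' written negative for deletions, following caller convention.
#'
#' @param x an [sv_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path) {
  stopifnot(inherits(x, "sv_set"))
  v <- x$variants
  samples <- colnames(x$genotypes)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=BACKGROUND_AF,Number=1,Type=Float,Description=\"Maximum background allele frequency across populations\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  gt_back <- c(HOMREF = "0/0", HET = "0/1", HOM = "1/1", MISSING = "./.")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    svlen <- if (v$svtype[i] == "DEL") -v$svlen[i] else v$svlen[i]
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", v$svtype[i],
                    as.integer(v$end[i]), as.integer(svlen))
    if (!is.na(v$background_af[i])) {
      info <- sprintf("%s;BACKGROUND_AF=%.6g", info, v$background_af[i])
    }
    fields <- c(v$chrom[i], v$start[i] + 1L, v$id[i], "N",
                sprintf("<%s>", v$svtype[i]), ".", "PASS", info)
    if (length(samples)) {
      fields <- c(fields, "GT", unname(gt_back[x$genotypes[i, ]]))
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write / read an `sv_set` as a flat TSV
#'
#' One row per variant; genotype columns are prefixed `gt_`. The TSV round
#' trips through [read_sv_tsv()].
#'
#' @param x an [sv_set()].
#' @param path file path.
#' @return `path` (write) or an [sv_set()] (read).
#' @export
write_sv_tsv <- function(x, path) {
  stopifnot(inherits(x, "sv_set"))
  df <- x$variants
  if (ncol(x$genotypes)) {
    gt <- as.data.frame(x$genotypes, stringsAsFactors = FALSE)
    names(gt) <- paste0("gt_", colnames(x$genotypes))
    df <- cbind(df, gt)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  gt_cols <- grep("^gt_", names(df), value = TRUE)
  gmat <- NULL
  if (length(gt_cols)) {
    gmat <- as.matrix(df[gt_cols])
    dimnames(gmat) <- list(as.character(df$id), sub("^gt_", "", gt_cols))
  }
  df$qc_flags[is.na(df$qc_flags)] <- ""
  sv_set(df[setdiff(names(df), gt_cols)], gmat)
}
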