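#' Reciprocal overlap between genomic intervals
#'
#' The reciprocal overlap (RO) of two intervals is the smaller of the two
#' mutual overlap fractions, `min(ov / len(a), ov / len(b))`, where `ov` is
#' the length of their intersection. RO is the standard corroboration and
#' merging statistic for copy-number variants: medium/long CNVs are accepted
#' when an independent caller reports a same-type interval with RO > 0.8, and
#' cross-cohort merging joins same-type SVs with RO > 0.8.
#'
#' All coordinates in this package are 0-based half-open; intervals on
#' different chromosomes have RO 0. Inputs are recycled to a common length.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (0-based
#'   half-open). Single-row inputs are recycled against the other argument.
#' @return Numeric vector of reciprocal-overlap fractions in `[0, 1]`.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 100)
#' b <- data.frame(chrom = "chr1", start = 50, end = 150)
#' reciprocal_overlap(a, b)  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  len_a <- a$end - a$start
  len_b <- b$end - b$start
  if (any(len_a <= 0) || any(len_b <= 0)) {
    stop("reciprocal_overlap() requires positive-length intervals")
  }
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ro <- pmin(ov / len_a, ov / len_b)
  ro[as.character(a$chrom) != as.character(b$chrom)] <- 0
  ro
}

# Interval set -> GRanges (internal). Converts 0-based half-open to the
# 1-based closed convention GRanges uses. Zero-width records (INS anchors)
# become width-1 ranges covering the base the anchor points at, so that
# "anchor inside [s,e)" matches findOverlaps semantics.
.as_granges <- function(df) {
  start0 <- df$start
  end0 <- df$end
  zero <- end0 <= start0
  end0[zero] <- start0[zero] + 1L
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
}

# Any-overlap (>= 1 bp) test of query rows against a subject interval set.
.overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(.as_granges(query), .as_granges(subject))
}
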