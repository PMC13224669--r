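#' Residualize expression and compute per-gene Z-scores
#'
#' For each gene (column), supplied covariates are regressed out of the
#' log-scale expression values by ordinary least squares and the residuals
#' are standardized over samples to mean 0, sd 1. Hidden-factor estimation
#' is not performed here; covariates (sex, genotype principal components,
#' optionally top expression PCs) are supplied by the caller. Genes whose
#' residuals have (near-)zero variance get `NA` Z-scores and are recorded in
#' the `zero_variance` attribute.
#'
#' @param mat numeric matrix, samples in rows, genes in columns
#'   (log-transformed expression), or a named list of such matrices (one per
#'   tissue).
#' @param covariates data.frame or matrix of per-sample covariates
#'   (row-aligned to `mat`), or `NULL`.
#' @return For a matrix input: the Z-score matrix (attribute
#'   `zero_variance` lists flagged genes). For a list input: an object of
#'   class `zscore_table` with elements `z` (list of per-tissue Z matrices)
#'   and `median_z` (sample x gene cross-tissue median).
#' @export
residualize_and_zscore <- function(mat, covariates = NULL) {
  if (is.list(mat) && !is.data.frame(mat)) {
    z <- lapply(mat, residualize_and_zscore, covariates = covariates)
    genes <- colnames(z[[1]])
    med <- apply(simplify2array(lapply(z, function(m) m[, genes, drop = FALSE])),
                 c(1, 2), stats::median, na.rm = TRUE)
    return(structure(list(z = z, median_z = med), class = "zscore_table"))
  }
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("expression matrix must be finite")
  if (is.null(covariates) || NCOL(covariates) == 0) {
    resid <- scale(mat, scale = FALSE)
  } else {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (nrow(X) != nrow(mat)) stop("covariates not row-aligned to expression")
    if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank-deficient")
    resid <- qr.resid(qr(X), mat)
  }
  sds <- apply(resid, 2, stats::sd)
  zero <- sds < 1e-10 | is.na(sds)
  z <- sweep(sweep(resid, 2, colMeans(resid)), 2, ifelse(zero, NA, sds), "/")
  z[, zero] <- NA_real_
  dimnames(z) <- dimnames(mat)
  attr(z, "zero_variance") <- colnames(mat)[zero]
  z
}

#' Call expression outliers from Z-scores
#'
#' Single-tissue mode: an individual is an outlier for a gene when the
#' absolute Z-score strictly exceeds `threshold` (default 2). Multi-tissue
#' mode: when the absolute cross-tissue median Z-score strictly exceeds
#' `threshold`.
#'
#' @param z a Z-score matrix (single mode) or a `zscore_table` from
#'   [residualize_and_zscore()] (either mode).
#' @param mode `"single"` or `"multi"`.
#' @param threshold outlier cutoff (strict `>`; default 2).
#' @return Logical matrix (samples x genes); in single mode with a
#'   `zscore_table` input, a list of per-tissue logical matrices.
#' @export
call_outliers <- function(z, mode = c("single", "multi"), threshold = 2) {
  mode <- match.arg(mode)
  if (inherits(z, "zscore_table")) {
    if (mode == "multi") return(abs(z$median_z) > threshold)
    return(lapply(z$z, function(m) abs(m) > threshold))
  }
  if (mode == "multi") stop("multi-tissue mode needs a zscore_table")
  abs(z) > threshold
}

#' Odds ratio of being an expression outlier given SV carrier status
#'
#' Builds the 2x2 carrier-by-outlier contingency table and reports the odds
#' ratio `ad/bc`, a Woolf 95% confidence interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` (with a Haldane
#' +0.5 continuity correction applied to all cells when any cell is zero,
#' and the result flagged), and a two-sided Fisher exact p-value. A table
#' with an all-zero margin is degenerate and yields `NA` with flag
#' `degenerate`.
#'
#' @param carriers,outliers logical vectors or matrices of identical shape
#'   (`NA` pairs are dropped).
#' @return An object of class `enrichment_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `table` (2x2 counts), `flag`.
#' @export
carrier_outlier_enrichment <- function(carriers, outliers) {
  x <- as.vector(carriers); y <- as.vector(outliers)
  if (length(x) != length(y)) stop("carriers and outliers must align")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  a <- sum(x & y); b <- sum(x & !y); cc <- sum(!x & y); d <- sum(!x & !y)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(carrier = c("yes", "no"),
                                outlier = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(odds_ratio = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_, table = tab,
                          flag = "degenerate"), class = "enrichment_result"))
  }
  flag <- ""
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) {
    cells <- cells + 0.5
    flag <- "haldane_corrected"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  p <- stats::fisher.test(tab)$p.value
  structure(list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, table = tab, flag = flag),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("OR = %.3f [%.3f, %.3f], Fisher p = %.3g%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
              if (nzchar(x$flag)) paste0(" (", x$flag, ")") else ""))
  invisible(x)
}

#' Correlation between TDR and expression Z-score
#'
#' Deletions with larger TDR remove a larger share of a gene's tissue
#' expression, so their carriers show stronger under-expression (negative
#' correlation); duplications mirror this with over-expression. Pairs with
#' undefined TDR or Z are dropped (count reported via attribute
#' `n_dropped`). Spearman by default.
#'
#' @param tdr,z numeric vectors of per-carrier TDR and expression Z-score.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `r`, `p`, `n`; `NA` when fewer than 3 defined pairs or a
#'   constant vector.
#' @export
tdr_expression_correlation <- function(tdr, z, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(tdr) & !is.na(z)
  n_dropped <- sum(!keep)
  tdr <- tdr[keep]; z <- z[keep]
  out <- if (length(tdr) < 3 || stats::sd(tdr) == 0 || stats::sd(z) == 0) {
    list(r = NA_real_, p = NA_real_, n = length(tdr))
  } else {
    ct <- suppressWarnings(stats::cor.test(tdr, z, method = method,
                                           exact = FALSE))
    list(r = unname(ct$estimate), p = ct$p.value, n = length(tdr))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' TSS-distance-binned outlier enrichment for non-coding deletions
#'
#' Regulatory disruption leaves no TDR signal (TDR = 0 for non-coding
#' deletions) but can still cause expression outliers, most strongly when a
#' deletion removes promoter-proximal sequence. Carriers are binned by the
#' distance of the deletion to the gene's nearest TSS and each bin's outlier
#' status is contrasted against the non-carrier background with
#' [carrier_outlier_enrichment()].
#'
#' @param tss_dist numeric vector: per-carrier distance to the TSS (bp).
#' @param outlier logical vector: per-carrier outlier status.
#' @param background_outlier logical vector: outlier status among
#'   non-carriers.
#' @param bin_edges increasing numeric vector of bin edges (default
#'   `c(0, 2e3, 1e4, 1e5, 1e6)`; an extra `Inf` edge is appended).
#' @return data.frame: one row per bin with `bin`, `n_carriers`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value` (`NA` for empty bins).
#' @export
tss_bin_enrichment <- function(tss_dist, outlier, background_outlier,
                               bin_edges = c(0, 2e3, 1e4, 1e5, 1e6)) {
  stopifnot(length(tss_dist) == length(outlier))
  edges <- unique(c(bin_edges, Inf))
  bins <- cut(tss_dist, breaks = edges, right = FALSE,
              include.lowest = TRUE)
  out <- lapply(levels(bins), function(b) {
    idx <- which(bins == b)
    if (!length(idx)) {
      return(data.frame(bin = b, n_carriers = 0L, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    enr <- carrier_outlier_enrichment(
      c(rep(TRUE, length(idx)), rep(FALSE, length(background_outlier))),
      c(outlier[idx], background_outlier))
    data.frame(bin = b, n_carriers = length(idx),
               odds_ratio = enr$odds_ratio, ci_low = enr$ci_low,
               ci_high = enr$ci_high, p_value = enr$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
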