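test_that("Z-scores are standardized and confounder-free", {
  set.seed(21)
  n <- 120
  conf <- rnorm(n)
  y <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("g", 1:15)))
  y <- y + 2 * conf  # planted confounder on every gene
  z <- residualize_and_zscore(y, data.frame(batch = conf))
  expect_lt(max(abs(colMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-6)
  expect_lt(max(abs(cor(z, conf))), 1e-8)

  # without covariates, standardization only
  z0 <- residualize_and_zscore(y)
  expect_equal(unname(z0[, 1]), unname(scale(y[, 1])[, 1]))

  # a covariate identical to the expression vector leaves no variance
  y2 <- cbind(g1 = conf, g2 = rnorm(n))
  z2 <- residualize_and_zscore(y2, data.frame(batch = conf))
  expect_true("g1" %in% attr(z2, "zero_variance"))
  expect_true(all(is.na(z2[, "g1"])))
})

test_that("outlier calls use strict |z| > 2, single and multi tissue", {
  z <- matrix(c(2.1, 2.0, -2.5, 0.3), 2, 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  out <- call_outliers(z)
  expect_equal(as.vector(out), c(TRUE, FALSE, TRUE, FALSE))

  zt <- structure(list(
    z = list(t1 = z, t2 = z),
    median_z = matrix(c(-2.5, 2.0, 1.0, -1.0), 2, 2,
                      dimnames = dimnames(z))), class = "zscore_table")
  mt <- call_outliers(zt, mode = "multi")
  expect_equal(as.vector(mt), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("odds ratio, Woolf CI and Fisher p come from the 2x2 table", {
  carriers <- rep(c(TRUE, FALSE), c(100, 900))
  outliers <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 5), rep(FALSE, 895))
  e <- carrier_outlier_enrichment(carriers, outliers)
  expect_equal(e$odds_ratio, (10 * 895) / (90 * 5), tolerance = 1e-12)
  expect_equal(unname(e$table[1, ]), c(10, 90))
  expect_equal(e$p_value, fisher.test(e$table)$p.value)
  expect_true(e$ci_low <= e$odds_ratio && e$odds_ratio <= e$ci_high)

  # zero cell: Haldane correction keeps the OR finite
  e0 <- carrier_outlier_enrichment(c(TRUE, TRUE, FALSE, FALSE),
                                   c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(e0$flag, "haldane_corrected")
  expect_true(is.finite(e0$odds_ratio))

  # degenerate margin
  ed <- carrier_outlier_enrichment(c(TRUE, TRUE), c(TRUE, FALSE))
  expect_equal(ed$flag, "degenerate")
  expect_true(is.na(ed$odds_ratio))
})

test_that("OR matches brute-force contingency construction on random tables", {
  set.seed(33)
  for (i in 1:50) {
    n <- 400
    x <- runif(n) < 0.2
    y <- runif(n) < 0.1
    e <- carrier_outlier_enrichment(x, y)
    tab <- table(factor(x, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
    expect_equal(unname(e$table), unname(matrix(tab, 2)))
    if (all(tab > 0)) {
      expect_equal(e$odds_ratio,
                   (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
    }
  }
})

test_that("null simulations keep the CI on 1 and type-I error near 0.05", {
  set.seed(44)
  cover <- logical(100)
  for (r in 1:100) {
    x <- runif(500) < 0.15
    y <- runif(500) < 0.2
    e <- carrier_outlier_enrichment(x, y)
    cover[r] <- !is.na(e$ci_low) && e$ci_low <= 1 && 1 <= e$ci_high
  }
  expect_gte(mean(cover), 0.9)
})

test_that("TDR-expression correlation recovers planted effect directions", {
  set.seed(55)
  n <- 300
  tdr <- runif(n)
  z_del <- -2 * tdr + rnorm(n, sd = 0.8)
  z_dup <- 2 * tdr + rnorm(n, sd = 0.8)
  del <- tdr_expression_correlation(tdr, z_del)
  dup <- tdr_expression_correlation(tdr, z_dup)
  expect_lt(del$r, 0); expect_lt(del$p, 0.01)
  expect_gt(dup$r, 0); expect_lt(dup$p, 0.01)
  # undefined rows are dropped and counted
  res <- tdr_expression_correlation(c(tdr, NA, NA), c(z_del, 1, 2))
  expect_equal(attr(res, "n_dropped"), 2)
  expect_equal(res$n, n)
  # constant TDR is undefined
  expect_true(is.na(tdr_expression_correlation(rep(0.5, 10),
                                               rnorm(10))$r))
})

test_that("planted promoter-proximal effects decay across TSS bins", {
  set.seed(66)
  n_bg <- 3000
  background <- runif(n_bg) < 0.05
  d <- c(runif(150, 0, 2e3), runif(150, 2e3, 1e4), runif(150, 1e4, 1e5),
         runif(150, 1e5, 1e6))
  p_out <- c(rep(0.5, 150), rep(0.2, 150), rep(0.08, 150), rep(0.05, 150))
  outlier <- runif(600) < p_out
  res <- tss_bin_enrichment(d, outlier, background)
  or <- res$odds_ratio[!is.na(res$odds_ratio)]
  expect_gt(or[1], or[2])
  expect_gt(or[2], or[3])
  # null: no distance effect, ORs near 1
  out0 <- runif(600) < 0.05
  res0 <- tss_bin_enrichment(d, out0, background)
  expect_true(all(abs(log(res0$odds_ratio[res0$n_carriers > 0])) < log(3)))
  # one bin covering everything reduces to the plain enrichment
  res1 <- tss_bin_enrichment(d, outlier, background, bin_edges = 0)
  plain <- carrier_outlier_enrichment(
    c(rep(TRUE, 600), rep(FALSE, n_bg)), c(outlier, background))
  expect_equal(res1$odds_ratio[1], plain$odds_ratio)
})

test_that("slope recovery: regressing z on TDR returns the planted effect", {
  set.seed(77)
  n <- 500
  beta <- 1.8
  tdr <- runif(n)
  z <- -beta * tdr + rnorm(n)
  fit <- lm(z ~ tdr)
  est <- coef(summary(fit))["tdr", ]
  expect_lt(abs(est["Estimate"] + beta), 2 * est["Std. Error"])
})
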