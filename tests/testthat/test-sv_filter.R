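test_that("reciprocal overlap matches arithmetic and is symmetric", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(a, b), 0.5)
  expect_equal(reciprocal_overlap(b, a), 0.5)
  expect_equal(reciprocal_overlap(a, data.frame(chrom = "chr1", start = 200,
                                                end = 300)), 0)
  expect_equal(reciprocal_overlap(a, data.frame(chrom = "chr2", start = 0,
                                                end = 100)), 0)
  expect_error(reciprocal_overlap(a, data.frame(chrom = "chr1", start = 5,
                                                end = 5)), "positive-length")
})

test_that("reciprocal overlap agrees with base-by-base counting", {
  set.seed(11)
  for (i in 1:2000) {
    s1 <- sample(0:500, 1); s2 <- sample(0:500, 1)
    a <- data.frame(chrom = "chr1", start = s1, end = s1 + sample(1:200, 1))
    b <- data.frame(chrom = "chr1", start = s2, end = s2 + sample(1:200, 1))
    expect_equal(reciprocal_overlap(a, b), oracle_ro(a, b))
  }
})

test_that("size tiers follow the length and type table", {
  v <- rbind(sv_row("a", "chr1", 0, 150, "DEL"),
             sv_row("b", "chr1", 0, 200, "DEL"),
             sv_row("c", "chr1", 0, 99999, "DUP"),
             sv_row("d", "chr1", 0, 100000, "DEL"),
             sv_row("e", "chr1", 0, 5000, "INV"),
             sv_row("f", "chr1", 0, 150, "INV"),
             sv_row("g", "chr1", 10, 10, "INS", svlen = 300),
             sv_row("h", "chr1", 10, 10, "INS", svlen = 120))
  expect_equal(size_tier(v), c("SHORT", "MEDIUM", "MEDIUM", "LONG",
                               "OTHER", "OTHER", "OTHER", "SHORT"))
})

test_that("exclusion removes any-overlap hits but respects half-open ends", {
  y <- suppressMessages(
    exclude_regions(sv_set(rbind(sv_row("hit", "chr1", 100, 200, "DEL"),
                                 sv_row("adj", "chr1", 200, 300, "DEL"))),
                    data.frame(chrom = "chr1", start = 150, end = 160)))
  expect_equal(y$variants$id, "adj")
  # touching at the half-open boundary shares no base
  z <- exclude_regions(sv_set(sv_row("t", "chr1", 100, 200, "DEL")),
                       data.frame(chrom = "chr1", start = 200, end = 300))
  expect_equal(z$variants$id, "t")
  # empty exclusion set is the identity
  w <- sv_set(sv_row("u", "chr1", 5, 50, "DEL"))
  expect_equal(exclude_regions(w, data.frame(chrom = character(0),
                                             start = integer(0),
                                             end = integer(0))), w)
})

test_that("tiered QC applies the right rule per tier", {
  svs <- sv_set(rbind(
    sv_row("short_ok", "chr1", 100, 250, "DEL", svlen = 150),
    sv_row("short_bad", "chr1", 1000, 1150, "DEL", svlen = 150),
    sv_row("med_ok", "chr1", 10000, 12000, "DEL"),
    sv_row("med_edge", "chr1", 30000, 32000, "DUP"),
    sv_row("long_ok", "chr1", 100000, 220000, "DEL"),
    sv_row("long_lumpy_only", "chr1", 400000, 520000, "DEL"),
    sv_row("inv_any", "chr1", 50000, 54000, "INV"),
    sv_row("inv_tiny", "chr1", 60000, 60150, "INV")))
  para <- matrix("HOMREF", 2, 2,
                 dimnames = list(c("short_ok", "short_bad"), c("s1", "s2")))
  para["short_ok", "s1"] <- "HET"
  ev <- support_evidence(
    lumpy = data.frame(chrom = "chr1",
                       start = c(400000), end = c(520000), svtype = "DEL"),
    cnvnator = data.frame(chrom = "chr1",
                          start = c(10050, 30400, 100500),
                          end = c(12010, 32400, 220500),
                          svtype = c("DEL", "DUP", "DEL")),
    paragraph_genotypes = para)
  res <- apply_qc_workflow(svs, ev)
  a <- res$audit
  expect_true(a$pass[a$id == "short_ok"])
  expect_false(a$pass[a$id == "short_bad"])
  # CNVnator [10050,12010) vs [10000,12000): RO ~0.955 > 0.8
  expect_true(a$pass[a$id == "med_ok"])
  # shifted by exactly 20%: RO = 0.8, strict inequality fails
  expect_false(a$pass[a$id == "med_edge"])
  expect_true(a$pass[a$id == "long_ok"])
  # LONG requires CNVnator; Lumpy-only support does not count
  expect_false(a$pass[a$id == "long_lumpy_only"])
  expect_true(a$pass[a$id == "inv_any"])
  expect_true(a$pass[a$id == "inv_tiny"])
  flags <- res$passed$variants$qc_flags[res$passed$variants$id == "inv_tiny"]
  expect_match(flags, "untested_tier")
  # exactly one audit row per SV, and passed is a subset of the input
  expect_equal(sort(a$id), sort(svs$variants$id))
  expect_true(all(res$passed$variants$id %in% svs$variants$id))
})

test_that("evidence corroboration is type-matched", {
  svs <- sv_set(sv_row("m", "chr1", 10000, 12000, "DEL"))
  ev <- support_evidence(
    cnvnator = data.frame(chrom = "chr1", start = 10000, end = 12000,
                          svtype = "DUP"))
  res <- apply_qc_workflow(svs, ev)
  expect_false(res$audit$pass)
})

test_that("alignment QC gate enforces strict thresholds", {
  m <- data.frame(
    sample = c("good", "lowcov", "contam_edge", "chim", "na"),
    mean_coverage = c(30, 14, 30, 30, NA),
    chimeric_fraction = c(1e-4, 1e-4, 1e-4, 6e-4, 1e-4),
    contamination = c(0.01, 0.01, 0.05, 0.01, 0.01))
  res <- bam_qc_gate(m)
  expect_equal(res$status,
               c("PASS", "FAIL", "FAIL", "FAIL", "UNEVALUATED"))
})
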