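write_vcf_lines <- function(body, path, samples = character(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="m">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

test_that("VCF coordinates convert 1-based inclusive to 0-based half-open", {
  f <- write_vcf_lines(
    "chr1\t1001\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1100\tGT\t0/1",
    tempfile(fileext = ".vcf"), samples = "s1")
  x <- read_sv_vcf(f)
  expect_equal(x$variants$start, 1000)
  expect_equal(x$variants$end, 1100)
  expect_equal(x$variants$svlen, 100)
  expect_equal(unname(x$genotypes["del1", "s1"]), "HET")
})

test_that("unsupported SVTYPEs are skipped and BNDs routed to conversion", {
  body <- c(
    "chr1\t101\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200\tGT\t0/1",
    "chr1\t301\tb\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=400\tGT\t0/1",
    "chr1\t501\tc\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600\tGT\t1/1",
    "chr1\t5001\tbnd1\tN\tN]chr1:9001]\t.\tPASS\tSVTYPE=BND;MATEID=bnd2\tGT\t0/1",
    "chr1\t9001\tbnd2\tN\tN]chr1:5001]\t.\tPASS\tSVTYPE=BND;MATEID=bnd1\tGT\t0/1",
    "chr1\t701\tcnv\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=800\tGT\t0/1")
  f <- write_vcf_lines(body, tempfile(fileext = ".vcf"), samples = "s1")
  expect_message(x <- read_sv_vcf(f), "skipped")
  expect_equal(sum(x$variants$svtype == "DEL"), 3)
  # the mated BND pair became one inversion spanning the two breakends
  inv <- x$variants[x$variants$svtype == "INV", ]
  expect_equal(nrow(inv), 1)
  expect_equal(inv$start, 5000)
  expect_equal(inv$end, 9000)
})

test_that("header-only and malformed VCFs behave as specified", {
  f <- write_vcf_lines(character(0), tempfile(fileext = ".vcf"))
  expect_equal(length(read_sv_vcf(f)), 0)
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\tx"), bad)
  expect_error(read_sv_vcf(bad), "line 3")
})

test_that("multi-allelic SV lines split into one record per ALT", {
  f <- write_vcf_lines(
    "chr1\t1001\tma\tN\t<DEL>,<DUP>\t.\tPASS\tSVTYPE=DEL;END=1100\tGT\t1/2",
    tempfile(fileext = ".vcf"), samples = "s1")
  x <- read_sv_vcf(f)
  expect_equal(nrow(x$variants), 2)
  expect_setequal(x$variants$id, c("ma_alt1", "ma_alt2"))
  expect_equal(unname(x$genotypes[, "s1"]), c("HET", "HET"))
})

test_that("half-called genotypes are MISSING", {
  f <- write_vcf_lines(
    "chr1\t1001\td\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1100\tGT\t./1\t./.\t0|1",
    tempfile(fileext = ".vcf"), samples = c("s1", "s2", "s3"))
  x <- read_sv_vcf(f)
  expect_equal(unname(x$genotypes[1, ]), c("MISSING", "MISSING", "HET"))
})

test_that("BND conversion rejects translocations, bad orientation, unmated", {
  inter <- data.frame(id = c("a", "b"), chrom = c("chr1", "chr2"),
                      pos = c(100, 200), alt = c("N]chr2:201]", "N]chr1:101]"),
                      mateid = c("b", "a"), stringsAsFactors = FALSE)
  expect_warning(res <- convert_bnd_to_inv(inter), "dropped")
  expect_equal(length(res), 0)

  badori <- data.frame(id = c("a", "b"), chrom = "chr1",
                       pos = c(100, 200), alt = c("N]chr1:201]", "[chr1:101[N"),
                       mateid = c("b", "a"), stringsAsFactors = FALSE)
  expect_warning(res <- convert_bnd_to_inv(badori), "dropped")
  expect_equal(length(res), 0)

  lone <- data.frame(id = "a", chrom = "chr1", pos = 100,
                     alt = "N]chr1:900]", mateid = "zz",
                     stringsAsFactors = FALSE)
  expect_warning(res <- convert_bnd_to_inv(lone), "dropped")
  expect_equal(length(res), 0)
})

test_that("BND pairs are matched by coordinates when MATEID is absent", {
  bnd <- data.frame(id = c("a", "b"), chrom = "chr1", pos = c(5000, 9000),
                    alt = c("N]chr1:9001]", "N]chr1:5001]"),
                    stringsAsFactors = FALSE)
  res <- convert_bnd_to_inv(bnd)
  expect_equal(res$variants$svtype, "INV")
  expect_equal(res$variants$start, 5000)
  expect_equal(res$variants$end, 9000)
})

test_that("BED reading keeps native coordinates and rejects bad lines", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment", "chr1\t100\t200",
               "chr2\t500\t400", "chr2\t50\t60"), f)
  expect_warning(bed <- read_interval_bed(f), "line 4")
  expect_equal(nrow(bed), 2)
  expect_equal(bed$start, c(100, 50))
  expect_equal(bed$end, c(200, 60))

  g <- tempfile(fileext = ".bed")
  writeLines("chr1\tabc\t200", g)
  expect_error(read_interval_bed(g), "non-numeric")
})

test_that("VCF and TSV round trips preserve records for all four SV types", {
  v <- rbind(sv_row("d1", "chr1", 100, 400, "DEL"),
             sv_row("u1", "chr1", 1000, 1600, "DUP"),
             sv_row("i1", "chr2", 5000, 9000, "INV"),
             sv_row("n1", "chr2", 700, 700, "INS", svlen = 300))
  g <- matrix(c("HET", "HOM", "HOMREF", "MISSING",
                "HOMREF", "HET", "HET", "HOM"), ncol = 2,
              dimnames = list(v$id, c("sA", "sB")))
  x <- sv_set(v, g)
  x$variants$background_af <- c(0.05, 0.001, NA, 0.25)
  fv <- tempfile(fileext = ".vcf")
  write_sv_vcf(x, fv)
  y <- read_sv_vcf(fv)
  cols <- c("id", "chrom", "start", "end", "svtype", "svlen")
  expect_equal(y$variants[cols], x$variants[cols])
  expect_equal(y$genotypes, x$genotypes)
  expect_equal(y$variants$background_af, x$variants$background_af)

  ft <- tempfile(fileext = ".tsv")
  write_sv_tsv(x, ft)
  z <- read_sv_tsv(ft)
  expect_equal(z$variants[cols], x$variants[cols])
  expect_equal(z$genotypes, x$genotypes)
})
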