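test_that("disruption rules: DEL/DUP by CDS overlap, INS by anchor, INV by breakpoints", {
  gm <- toy_models()
  del <- sv_set(sv_row("d", "chr1", 2000, 2200, "DEL"))
  expect_setequal(disrupted_transcripts(del, gm, "d", "GX"), c("T1", "T3"))

  # UTR-only overlap does not disrupt a coding transcript
  utr <- sv_set(sv_row("u", "chr1", 1000, 1040, "DEL"))
  expect_equal(disrupted_transcripts(utr, gm, "u", "GX"), character(0))

  intronic <- sv_set(sv_row("i", "chr1", 2300, 2600, "DEL"))
  expect_equal(disrupted_transcripts(intronic, gm, "i", "GX"), character(0))

  # non-coding transcripts are disrupted through exon overlap
  nc <- sv_set(sv_row("n", "chr1", 22000, 22500, "DEL"))
  expect_equal(disrupted_transcripts(nc, gm, "n", "GN"), "N2")

  ins_in <- sv_set(sv_row("p", "chr1", 2100, 2100, "INS", svlen = 300))
  expect_setequal(disrupted_transcripts(ins_in, gm, "p", "GX"), c("T1", "T3"))
  ins_out <- sv_set(sv_row("q", "chr1", 2500, 2500, "INS", svlen = 300))
  expect_equal(disrupted_transcripts(ins_out, gm, "q", "GX"), character(0))

  # INV containing the whole gene relocates it intact
  inv_around <- sv_set(sv_row("v1", "chr1", 500, 5000, "INV"))
  expect_equal(disrupted_transcripts(inv_around, gm, "v1", "GX"), character(0))
  # INV with one breakpoint inside T3 crossing its CDS
  inv_bp <- sv_set(sv_row("v2", "chr1", 4100, 6000, "INV"))
  expect_equal(disrupted_transcripts(inv_bp, gm, "v2", "GX"), "T3")
})

test_that("TDR equals disrupted TPM over total TPM, with NA for silent genes", {
  gm <- toy_models()
  tpmx <- toy_tpm()
  svs <- sv_set(rbind(sv_row("d", "chr1", 2000, 2200, "DEL"),
                      sv_row("whole", "chr1", 0, 5000, "DEL"),
                      sv_row("i", "chr1", 2300, 2600, "DEL")))
  px <- data.frame(sv_id = svs$variants$id, gene_id = "GX")
  tab <- compute_tdr(svs, gm, tpmx, "tisA", px)
  # three transcripts at TPM 10/30/60, T1+T3 disrupted: 70/100
  expect_equal(tab$tdr[tab$variant_id == "d"], 0.7)
  expect_false(tab$disrupts_mane[tab$variant_id == "d"])
  expect_equal(tab$tdr[tab$variant_id == "whole"], 1.0)
  expect_true(tab$disrupts_mane[tab$variant_id == "whole"])
  expect_equal(tab$tdr[tab$variant_id == "i"], 0.0)

  # gene silent in the tissue: undefined, not zero
  tabz <- compute_tdr(sv_set(sv_row("z", "chr2", 5000, 5600, "DEL")),
                      gm, toy_tpm() * c(1, 1, 1, 1, 1, 0), "tisA",
                      data.frame(sv_id = "z", gene_id = "GZ"))
  expect_true(is.na(tabz$tdr))

  expect_error(compute_tdr(svs, gm, tpmx, "nosuch", px), "available")
})

test_that("TDR is scale-invariant and monotone in the disrupted set", {
  gm <- toy_models()
  tpmx <- toy_tpm()
  svs <- sv_set(sv_row("d", "chr1", 2000, 2200, "DEL"))
  px <- data.frame(sv_id = "d", gene_id = "GX")
  t1 <- compute_tdr(svs, gm, tpmx, "tisA", px)$tdr
  t2 <- compute_tdr(svs, gm, tpmx * 1000, "tisA", px)$tdr
  expect_equal(t1, t2)
  # growing the SV to also hit T2's CDS cannot lower the TDR
  bigger <- sv_set(sv_row("d", "chr1", 2000, 3300, "DEL"))
  t3 <- compute_tdr(bigger, gm, tpmx, "tisA", px)$tdr
  expect_gte(t3, t1)
})

test_that("TDR agrees with the per-base oracle on random SV-gene pairs", {
  spec <- fixture_spec(seed = 2)
  ann <- generate_annotation(spec)
  v <- random_svs(ann, 300, 55)
  svs <- sv_set(v)
  g <- ann$genes$genes
  pairs <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    data.frame(sv_id = v$id[i],
               gene_id = sample(g$gene_id[g$chrom == v$chrom[i]], 1))
  }))
  tab <- compute_tdr(svs, ann$genes, ann$tpm, spec$tissues[1], pairs)
  for (k in seq_len(nrow(pairs))) {
    want <- oracle_tdr(v[match(pairs$sv_id[k], v$id), ], ann$genes, ann$tpm,
                       spec$tissues[1], pairs$gene_id[k])
    expect_equal(tab$tdr[k], want, info = pairs$sv_id[k])
  }
})

test_that("stop-gain TDR uses CDS containment", {
  gm <- toy_models()
  tpmx <- toy_tpm()
  vars <- data.frame(id = c("sg1", "sg2", "sg3"), chrom = "chr1",
                     pos = c(3100, 1005, 2100), stringsAsFactors = FALSE)
  tab <- compute_tdr_stopgain(vars, gm, tpmx, "tisA",
                              pairs = data.frame(variant_id = vars$id,
                                                 gene_id = "GX"))
  # inside T2's CDS only: 30/100
  expect_equal(tab$tdr[tab$variant_id == "sg1"], 0.3)
  # in an exon that is UTR for every transcript
  expect_equal(tab$tdr[tab$variant_id == "sg2"], 0)
  # shared CDS base of T1 and T3: 70/100
  expect_equal(tab$tdr[tab$variant_id == "sg3"], 0.7)

  # position outside the gene span: flagged, TDR 0
  out <- compute_tdr_stopgain(
    data.frame(id = "sgx", chrom = "chr1", pos = 50000),
    gm, tpmx, "tisA",
    pairs = data.frame(variant_id = "sgx", gene_id = "GX"))
  expect_equal(out$tdr, 0)
  expect_equal(out$flag, "outside_gene")
})

test_that("MANE partition fractions respond to isoform structure", {
  gm <- toy_models()
  tpmx <- toy_tpm()
  # d1 spares MANE (T2) yet removes 70% of tisA expression; d2 hits MANE
  svs <- sv_set(rbind(sv_row("d1", "chr1", 2000, 2200, "DEL"),
                      sv_row("d2", "chr1", 3000, 3100, "DEL"),
                      sv_row("d3", "chr1", 1050, 1100, "DEL"),
                      sv_row("d4", "chr1", 4310, 4360, "DEL")))
  px <- data.frame(sv_id = svs$variants$id, gene_id = "GX")
  cmp <- mane_tdr_comparison(svs, gm, tpmx, "tisA", "tisB", pairs = px)
  non_mane <- cmp$summary[!cmp$summary$disrupts_mane, ]
  # non-MANE partition: d1 (0.7), d3 (0.1), d4 (0 in tisA: UTR-only)...
  expect_equal(non_mane$n, 3)
  expect_equal(non_mane$frac_high_tdr_a, 1 / 3)
  mane <- cmp$summary[cmp$summary$disrupts_mane, ]
  expect_equal(mane$n, 1)
  # empty partition reports NA, not 0
  only_mane <- sv_set(sv_row("d2", "chr1", 3000, 3100, "DEL"))
  cmp2 <- mane_tdr_comparison(only_mane, gm, tpmx, "tisA", "tisB",
                              pairs = data.frame(sv_id = "d2", gene_id = "GX"))
  expect_true(is.na(cmp2$summary$frac_high_tdr_a[!cmp2$summary$disrupts_mane]))
})

test_that("protein-coding expression share", {
  gm <- toy_models()
  tpmx <- toy_tpm()
  # GN in tisA: coding N1 = 40, non-coding N2 = 10
  r <- protein_coding_ratio(gm, tpmx, "tisA", "GN")
  expect_equal(unname(r), 0.8)
  expect_equal(unname(protein_coding_ratio(gm, tpmx, "tisA", "GX")), 1.0)
  expect_true(is.na(protein_coding_ratio(gm, tpmx, "tisB", "GN")))
})
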