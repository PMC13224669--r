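test_that("dosage-class stage keeps exonic/whole-gene CNVs and exonic INVs", {
  svs <- sv_set(rbind(
    sv_row("del_intron", "chr1", 0, 100, "DEL"),
    sv_row("dup_whole", "chr1", 0, 100, "DUP"),
    sv_row("inv_ex", "chr1", 0, 100, "INV"),
    sv_row("inv_whole", "chr1", 0, 100, "INV"),
    sv_row("ins_ex", "chr1", 10, 10, "INS", svlen = 50)))
  ctx <- data.frame(
    sv_id = c("del_intron", "dup_whole", "inv_ex", "inv_whole", "ins_ex"),
    gene_id = "G", context = c("INTRONIC", "WHOLE_GENE", "EXONIC",
                               "WHOLE_GENE", "EXONIC"))
  res <- dosage_class_filter(svs, ctx)
  expect_equal(res$pass[match(c("del_intron", "dup_whole", "inv_ex",
                                "inv_whole", "ins_ex"), res$sv_id)],
               c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("TDR gene-list stage: strict threshold, list membership, silent genes", {
  tab <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    gene_id = c("LISTED", "LISTED", "OTHER", "LISTED"),
    tissue = "tis",
    tdr = c(0.7, 0.25, 0.9, NA),
    stringsAsFactors = FALSE)
  res <- tdr_genelist_filter(tab, "LISTED", "tis")
  expect_true(res$pass[res$sv_id == "a"])
  expect_false(res$pass[res$sv_id == "b"])   # 0.25 exactly fails
  expect_false(res$pass[res$sv_id == "c"])   # high TDR in unlisted gene
  expect_false(res$pass[res$sv_id == "d"])
  expect_equal(res$reason[res$sv_id == "d"], "no expressed gene")
})

test_that("inheritance stage combines OMIM modes, MoDs and zygosity", {
  mods <- matrix(c(0.1, 0.6), 2, 1, dimnames = list(c("SENS", "TOL"), "tis"))
  omim <- data.frame(gene_id = c("ARG", "ADG"), modes = c("AR", "AD"),
                     stringsAsFactors = FALSE)
  ann <- gene_annotations(mods = mods, omim = omim)
  # AR-only gene, HET, no second hit
  v <- inheritance_consistency("ARG", "HET", ann, "tis")
  expect_false(v$pass)
  expect_match(v$rationale, "recessive")
  # AR gene, HOM
  expect_true(inheritance_consistency("ARG", "HOM", ann, "tis")$pass)
  # AR gene, HET plus supplied second hit
  expect_true(inheritance_consistency("ARG", "HET", ann, "tis",
                                      second_hits = "ARG")$pass)
  # dosage-sensitive by MoDs despite no OMIM entry
  expect_true(inheritance_consistency("SENS", "HET", ann, "tis")$pass)
  # MoDs 0.3 boundary is strict: tolerant gene with no AD mode fails
  mods2 <- matrix(0.3, 1, 1, dimnames = list("EDGE", "tis"))
  v2 <- inheritance_consistency("EDGE", "HET",
                                gene_annotations(mods = mods2), "tis")
  expect_false(v2$pass)
  # dominant gene passes on a HET
  expect_true(inheritance_consistency("ADG", "HET", ann, "tis")$pass)
  # unannotated gene passes, flagged
  v3 <- inheritance_consistency("NOVEL", "HET", ann, "tis")
  expect_true(v3$pass)
  expect_equal(v3$rationale, "unannotated")
})

test_that("the cascade reports exactly the planted pathogenic SV per patient", {
  spec <- fixture_spec(seed = 13)
  ann <- generate_annotation(spec)
  co <- generate_cohort(spec, ann)
  db <- build_background_db(co$cohorts)
  pc <- generate_patient_cohort(spec, ann, co, n_patients = 6)
  svs <- annotate_background_af(pc$patients, db)
  for (p in pc$truth$sample) {
    res <- run_cascade(svs, p, ann$genes, ann$tpm, pc$tissue, pc$gene_list,
                       pc$annotations, evidence = pc$evidence)
    expect_equal(res$report$sv_id,
                 pc$truth$pathogenic_sv_id[pc$truth$sample == p])
    # per-stage counts never increase, every carried SV traced exactly once
    expect_true(all(diff(res$stage_counts) <= 0))
    expect_equal(sort(res$trace$id),
                 sort(svs$variants$id[svs$genotypes[, p] %in%
                                        c("HET", "HOM")]))
    # common polymorphisms all die at the rarity stage or earlier
    common <- grep("^benign_common", res$trace$id, value = TRUE)
    expect_true(all(res$trace$stopped_at[res$trace$id %in% common] %in%
                      c("QC", "RARE")))
  }
})

test_that("an empty patient yields an empty report with zero counts", {
  v <- sv_row("a", "chr1", 0, 1000, "DEL")
  g <- matrix("HOMREF", 1, 1, dimnames = list("a", "p1"))
  x <- sv_set(v, g)
  x$variants$background_af <- 0
  gm <- toy_models()
  res <- run_cascade(x, "p1", gm, toy_tpm(), "tisA", "GX")
  expect_equal(nrow(res$report), 0)
  expect_true(all(res$stage_counts == 0))
})

test_that("known-pathogenic overlap is annotated but never gates", {
  spec <- fixture_spec(seed = 13)
  ann <- generate_annotation(spec)
  co <- generate_cohort(spec, ann)
  db <- build_background_db(co$cohorts)
  pc <- generate_patient_cohort(spec, ann, co, n_patients = 2)
  svs <- annotate_background_af(pc$patients, db)
  p <- pc$truth$sample[1]
  patho <- pc$truth$pathogenic_sv_id[1]
  vrow <- svs$variants[svs$variants$id == patho, ]
  clin <- data.frame(chrom = vrow$chrom, start = vrow$start + 10,
                     end = vrow$end + 10, svtype = vrow$svtype,
                     id = "known_sv_1", stringsAsFactors = FALSE)
  ann2 <- gene_annotations(mods = pc$annotations$mods,
                           omim = pc$annotations$omim, clinvar_svs = clin)
  res <- run_cascade(svs, p, ann$genes, ann$tpm, pc$tissue, pc$gene_list,
                     ann2, evidence = pc$evidence)
  expect_equal(res$report$known_pathogenic, "known_sv_1")
})
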