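# Hand-built three-transcript gene used across modules.
#
# GX (chr1, +, span [1000, 4400)):
#   T1 exons [1000,1200) [2000,2200); CDS [1050,1200) [2000,2150); TPM 10
#   T2 exons [1000,1150) [3000,3300); CDS [3000,3200) (exon 1 is UTR); TPM 30
#      -- MANE Select
#   T3 exons [2000,2200) [4000,4400); CDS [2020,2200) [4000,4300); TPM 60
# A deletion of [2000,2200) hits the CDS of T1 and T3 but not T2.
#
# GN (chr1, -, [20000, 26000)): one coding transcript plus one non-coding
# isoform (exon-overlap disruption rule, protein-coding ratio).
# GZ (chr2): cross-chromosome cases.
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("GX", "GN", "GZ"), symbol = c("GX", "GN", "GZ"),
    chrom = c("chr1", "chr1", "chr2"), strand = c("+", "-", "+"),
    start = c(1000, 20000, 5000), end = c(4400, 26000, 9000),
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    tx_id = c("T1", "T2", "T3", "N1", "N2", "Z1"),
    gene_id = c("GX", "GX", "GX", "GN", "GN", "GZ"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "+", "-", "-", "+"),
    start = c(1000, 1000, 2000, 20000, 21000, 5000),
    end = c(2200, 3300, 4400, 26000, 25000, 9000),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "protein_coding", "lncRNA", "protein_coding"),
    is_mane = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    tss = c(1000, 1000, 2000, 25999, 24999, 5000),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    tx_id = c("T1", "T1", "T2", "T2", "T3", "T3",
              "N1", "N1", "N2", "Z1", "Z1"),
    start = c(1000, 2000, 1000, 3000, 2000, 4000,
              20000, 25000, 21000, 5000, 8000),
    end = c(1200, 2200, 1150, 3300, 2200, 4400,
            20500, 26000, 25000, 5400, 9000),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    tx_id = c("T1", "T1", "T2", "T3", "T3", "N1", "N1", "Z1"),
    start = c(1050, 2000, 3000, 2020, 4000, 20100, 25000, 5100),
    end = c(1200, 2150, 3200, 2200, 4300, 20500, 25800, 5400),
    stringsAsFactors = FALSE)
  gene_models(genes, transcripts, exons, cds)
}

toy_tpm <- function() {
  m <- matrix(c(10, 30, 60, 40, 10, 5,
                 5, 80, 15,  0,  0, 2),
              ncol = 2, dimnames = list(c("T1", "T2", "T3", "N1", "N2", "Z1"),
                                        c("tisA", "tisB")))
  m
}

# One-row variants data.frame shortcut.
sv_row <- function(id, chrom, start, end, svtype, svlen = NULL) {
  data.frame(id = id, chrom = chrom, start = start,
             end = if (svtype == "INS") start else end, svtype = svtype,
             svlen = if (!is.null(svlen)) svlen else end - start,
             stringsAsFactors = FALSE)
}
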