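write_fasta <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  fa
}

test_that("genome loading and coordinate fetches behave as documented", {
  fa <- write_fasta(c(chr1 = "ACGT"))
  g <- load_genome(fa)
  expect_equal(fetch_subseq(g, "chr1", 2, 3), "CG")
  expect_equal(fetch_subseq(g, "chr1", 1, 4), "ACGT")
  expect_error(fetch_subseq(g, "chr1", 2, 5), "outside")
  expect_error(fetch_subseq(g, "chr1", 0, 2), "outside")
  expect_error(fetch_subseq(g, "chrX", 1, 2), "no such contig")

  fa2 <- write_fasta(Biostrings::DNAStringSet(
    stats::setNames(c("ACGT", "GGCC"), c("dup", "dup"))))
  expect_error(load_genome(fa2), "duplicate")
})

test_that("plus-strand extraction takes the bases left of the anchor", {
  set.seed(5)
  contig <- rand_seq(1300)
  g <- load_genome(Biostrings::DNAStringSet(c(chr = contig)))
  gm <- data.frame(gene_id = "gA", contig = "chr", strand = "+",
                   gene_start = 1001L, gene_end = 1300L,
                   cds_start = 1001L, cds_end = 1300L)
  reg <- extract_upstream(g, gm, anchor = "AUG", window_length = 1000)
  expect_equal(reg$sequence, substr(contig, 1, 1000))
  expect_equal(reg$source_start, 1L)
  expect_equal(reg$source_end, 1000L)
})

test_that("minus-strand extraction reverse-complements the right flank", {
  set.seed(6)
  contig <- rand_seq(700)
  g <- load_genome(Biostrings::DNAStringSet(c(chr = contig)))
  gm <- data.frame(gene_id = "gB", contig = "chr", strand = "-",
                   gene_start = 301L, gene_end = 500L,
                   cds_start = 301L, cds_end = 500L)
  reg <- extract_upstream(g, gm, anchor = "AUG", window_length = 100)
  expect_equal(reg$sequence, revcomp(substr(contig, 501, 600)))
  expect_equal(reg$source_start, 501L)
  expect_equal(reg$source_end, 600L)
  expect_equal(reg$source_strand, "-")
})

test_that("anchor choice distinguishes TSS from AUG", {
  set.seed(7)
  contig <- rand_seq(500)
  g <- load_genome(Biostrings::DNAStringSet(c(chr = contig)))
  gm <- data.frame(gene_id = "gC", contig = "chr", strand = "+",
                   gene_start = 301L, gene_end = 480L,
                   cds_start = 351L, cds_end = 480L)
  tss <- extract_upstream(g, gm, anchor = "TSS", window_length = 100)
  aug <- extract_upstream(g, gm, anchor = "AUG", window_length = 100)
  expect_equal(tss$sequence, substr(contig, 201, 300))
  expect_equal(aug$sequence, substr(contig, 251, 350))

  gm$cds_start <- NA_integer_
  gm$cds_end <- NA_integer_
  expect_error(extract_upstream(g, gm, anchor = "AUG"), "no CDS")
})

test_that("windows truncated at a contig edge warn and shorten", {
  set.seed(8)
  contig <- rand_seq(300)
  g <- load_genome(Biostrings::DNAStringSet(c(chr = contig)))
  gm <- data.frame(gene_id = "gD", contig = "chr", strand = "+",
                   gene_start = 101L, gene_end = 250L,
                   cds_start = 101L, cds_end = 250L)
  expect_warning(reg <- extract_upstream(g, gm, anchor = "TSS",
                                         window_length = 500),
                 "truncated")
  expect_equal(nchar(reg$sequence), 100L)
  expect_equal(reg$sequence, substr(contig, 1, 100))
})

test_that("extraction is symmetric under genome mirroring", {
  # reverse-complementing the contig and flipping the annotation must give
  # the identical upstream sequence
  set.seed(9)
  contig <- rand_seq(800)
  g1 <- load_genome(Biostrings::DNAStringSet(c(chr = contig)))
  gm1 <- data.frame(gene_id = "g", contig = "chr", strand = "+",
                    gene_start = 501L, gene_end = 700L,
                    cds_start = 501L, cds_end = 700L)
  g2 <- load_genome(Biostrings::DNAStringSet(c(chr = revcomp(contig))))
  gm2 <- data.frame(gene_id = "g", contig = "chr", strand = "-",
                    gene_start = 800L - 700L + 1L, gene_end = 800L - 501L + 1L,
                    cds_start = 800L - 700L + 1L, cds_end = 800L - 501L + 1L)
  r1 <- extract_upstream(g1, gm1, anchor = "AUG", window_length = 300)
  r2 <- extract_upstream(g2, gm2, anchor = "AUG", window_length = 300)
  expect_equal(r1$sequence, r2$sequence)
})

test_that("synthetic genome + GFF3 round trip recovers generated windows", {
  plans <- rbind(embed_plan("gene1", "GTCAAtgcTTGAC", 820, "TSS"),
                 embed_plan("gene2", "TTGACcttaTTGAC", 641),
                 embed_plan("gene3", "TGACaatacataagaaGTCAA", 667))
  sg <- build_synthetic_genome(plans, window_length = 1200, seed = 31)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_synthetic_genome(sg, fa, gff)
  genome <- load_genome(fa)
  gm <- read_gene_models(gff)
  expect_setequal(gm$gene_id, c("gene1", "gene2", "gene3"))
  expect_setequal(gm$strand, c("+", "-"))
  for (anch in c("TSS", "AUG")) {
    reg <- extract_upstream(genome, gm, anchor = anch, window_length = 1200)
    expect_equal(toupper(reg$sequence),
                 toupper(unname(sg$windows$sequences[reg$gene_id])))
  }
  # scanning the extracted windows reproduces the planned distances
  reg <- extract_upstream(genome, gm, anchor = "AUG", window_length = 1200)
  d <- scan_sequences(reg)
  m <- merge(d, sg$windows$truth, by = "gene_id")
  expect_equal(nrow(m), 3L)
  expect_equal(m$distance_upstream.x, m$distance_upstream.y)
})

test_that("dyads can be written back to genome coordinates as GFF3", {
  plans <- embed_plan("geneZ", "TGACTTGAC", 200)
  sg <- build_synthetic_genome(plans, window_length = 400, seed = 41,
                               strand = "-")
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_synthetic_genome(sg, fa, gff)
  genome <- load_genome(fa)
  reg <- extract_upstream(genome, read_gene_models(gff), anchor = "AUG",
                          window_length = 400)
  d <- scan_sequences(reg)
  out <- tempfile(fileext = ".gff3")
  write_dyads_gff3(d, reg, out)
  back <- rtracklayer::import(out, format = "GFF3")
  expect_equal(length(back), 1L)
  # the genomic span must contain the element verbatim on the gene strand
  span <- fetch_subseq(genome, as.character(GenomicRanges::seqnames(back)),
                       GenomicRanges::start(back), GenomicRanges::end(back))
  expect_equal(revcomp(span), "TGACTTGAC")
})
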