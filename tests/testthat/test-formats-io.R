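# External-format readers/writers: strict coordinate and dialect rules.

test_that("VCF reading keeps biallelic SNPs, drops the rest, preserves samples", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 150L, 200L, 250L),
                    ref = c("A", "C", "G", "T"),
                    alt = c("G", "G,T", "GA", "A"))
  gt <- matrix(c("0/0", "1/1",
                 "0/1", "0/0",
                 "0/0", "0/1",
                 "0/1", "./."), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  path <- write_tmp(vcf_text(rec, gt), ".vcf")
  vt <- read_variants(path)
  expect_s3_class(vt, "variant_table")
  expect_equal(nrow(vt$records), 2L)       # multiallelic + indel dropped
  expect_equal(vt$n_dropped, 2L)
  expect_equal(vt$sample_ids, c("s1", "s2"))
  expect_equal(vt$gt[1, ], c(s1 = "0/0", s2 = "1/1"))
  expect_equal(vt$gt[2, ], c(s1 = "0/1", s2 = NA))  # ./.  -> missing
})

test_that("half-calls and phased genotypes are normalized", {
  expect_equal(delscan:::normalize_gt(c("0|1", "1/0", "./1", "1")),
               c("0/1", "0/1", NA, NA))
})

test_that("unsorted VCF errors", {
  rec <- data.frame(chrom = "chr1", pos = c(200L, 100L), ref = "A", alt = "G")
  gt <- matrix("0/1", 2, 1, dimnames = list(NULL, "s1"))
  path <- write_tmp(vcf_text(rec, gt), ".vcf")
  expect_error(read_variants(path), "sorted")
})

test_that("variant table round-trips through VCF field-for-field", {
  rec <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    pos = c(5L, 10L, 3L), ref = c("A", "C", "G"),
                    alt = c("T", "T", "A"))
  gt <- matrix(c("0/0", "0/1", "1/1",
                 "0/1", NA, "0/0",
                 "1/1", "0/0", "0/1"), ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "c")))
  vt <- variant_table(rec, gt)
  path <- tempfile(fileext = ".vcf")
  write_variants(vt, path)
  back <- read_variants(path)
  expect_equal(back$records[, c("chrom", "pos", "ref", "alt")],
               vt$records[, c("chrom", "pos", "ref", "alt")])
  expect_equal(unname(back$gt), unname(vt$gt))
  expect_equal(back$sample_ids, vt$sample_ids)
})

test_that("gene models splice, reverse-complement and honour sharing", {
  fasta <- write_tmp(c(">chr1", "NNACCCATNNATGGGTNN"), ".fa")
  gff <- write_tmp(c(
    "##gff-version 3",
    "chr1\tt\tgene\t3\t16\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t11\t16\t.\t+\t.\tID=t.plus;Parent=g1",
    "chr1\tt\tmRNA\t3\t8\t.\t-\t.\tID=t.minus;Parent=g1",
    "chr1\tt\tCDS\t3\t8\t.\t-\t0\tParent=t.minus",
    "chr1\tt\tmRNA\t11\t16\t.\t+\t.\tID=t.share;Parent=g1",
    "chr1\tt\tCDS\t11\t16\t.\t+\t0\tParent=t.plus,t.share"), ".gff3")
  gm <- read_gene_models(gff, fasta)
  expect_equal(gm[["t.plus"]]$cds, "ATGGGT")
  # genomic ACCCAT on minus strand -> ATGGGT
  expect_equal(gm[["t.minus"]]$cds, "ATGGGT")
  # one CDS row shared by two transcripts yields two models
  expect_equal(gm[["t.share"]]$cds, "ATGGGT")
})

test_that("CDS not a codon multiple is flagged, not dropped silently", {
  fasta <- write_tmp(c(">chr1", "ATGGGTT"), ".fa")
  gff <- write_tmp(c("##gff-version 3",
                     "chr1\tt\tCDS\t1\t7\t.\t+\t0\tParent=tx1"), ".gff3")
  gm <- read_gene_models(gff, fasta)
  expect_true(gm[["tx1"]]$flagged)
  expect_equal(gm[["tx1"]]$flag_reason, "length_not_multiple_of_3")
})

test_that("phase trims the partial first exon", {
  fasta <- write_tmp(c(">chr1", "CCATGGGT"), ".fa")
  gff <- write_tmp(c("##gff-version 3",
                     "chr1\tt\tCDS\t1\t8\t.\t+\t2\tParent=tx1"), ".gff3")
  gm <- read_gene_models(gff, fasta)
  expect_equal(gm[["tx1"]]$cds, "ATGGGT")
  expect_false(gm[["tx1"]]$flagged)
})

test_that("alignment reading: codon columns, gap rule, error cases", {
  path <- write_tmp(c(">q", "ATGGGT", ">a", "ATGGGA", ">b", "AT-GGT"), ".fa")
  aln <- read_alignment(path, "q")
  expect_equal(aln$n_codons, 2L)
  expect_equal(length(aln$taxa), 3L)
  # codon with a gap is missing for that taxon only
  expect_true(is.na(aln$states["b", 1]))
  expect_false(is.na(aln$states["b", 2]))
  expect_false(anyNA(aln$states["a", ]))
  ragged <- write_tmp(c(">q", "ATGGGT", ">a", "ATG"), ".fa")
  expect_error(read_alignment(ragged, "q"), "ragged|length")
  len7 <- write_tmp(c(">q", "ATGGGTA", ">a", "ATGGGTA"), ".fa")
  expect_error(read_alignment(len7, "q"), "divisible")
  expect_error(read_alignment(path, "nope"), "absent")
})

test_that("stop codons are never observed states", {
  aln <- codon_alignment(c(q = "TAAATG", a = "ATGATG"), "q")
  expect_true(is.na(aln$states["q", 1]))
  expect_equal(unname(aln$states["q", 2]),
               unname(delscan:::encode_codons("ATG")))
})

test_that("Newick reading preserves tips and lengths, requires lengths", {
  p <- write_tmp("(A:0.1,B:0.2);", ".nwk")
  tr <- read_tree(p)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_setequal(tr$edge.length, c(0.1, 0.2))
  p2 <- write_tmp("((A:0.1,B:0.1):0.05,C:0.2);", ".nwk")
  tr2 <- read_tree(p2)
  expect_equal(length(tr2$tip.label), 3L)
  expect_equal(tr2$Nnode, 2L)  # one internal edge
  p3 <- write_tmp("(A:0.1,B);", ".nwk")
  expect_error(read_tree(p3), "branch length")
})

test_that("genetic map: sorting, duplicate collapse, numeric validation", {
  p <- write_tmp(c("marker\tchrom\tbp\tcM",
                   "m3\tchr1\t3000\t1.5",
                   "m1\tchr1\t1000\t0.0",
                   "m2\tchr1\t2000\t1.0"), ".tsv")
  gm <- read_genetic_map(p)
  expect_equal(gm$bp, c(1000, 2000, 3000))
  expect_equal(gm$marker, c("m1", "m2", "m3"))
  pdup <- write_tmp(c("marker\tchrom\tbp\tcM",
                      "m1\tchr1\t1000\t0.0",
                      "m1b\tchr1\t1000\t0.2",
                      "m2\tchr1\t2000\t1.0"), ".tsv")
  expect_warning(gm2 <- read_genetic_map(pdup), "duplicate")
  expect_equal(nrow(gm2), 2L)
  expect_equal(gm2$cM[1], 0.0)  # first occurrence retained
  pbad <- write_tmp(c("marker\tchrom\tbp\tcM",
                      "m1\tchr1\toops\t0.0"), ".tsv")
  expect_error(read_genetic_map(pbad), "line 2")
})

test_that("spliced CDS of unflagged transcripts has no internal stop", {
  toy <- simulate_toy_genome(tempfile("toy"), n_genes = 4, seed = 2)
  gm <- read_gene_models(toy$gff, toy$fasta)
  for (m in gm) {
    if (m$flagged) next
    aa <- delscan:::translate_codon(
      substring(m$cds, seq(1, nchar(m$cds), 3), seq(3, nchar(m$cds), 3)))
    expect_false(any(aa[-length(aa)] == "*", na.rm = TRUE))
  }
})
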