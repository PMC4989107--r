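# Effect classification, precedence, Grantham scores, Ts/Tv, codon positions.

test_that("classifier matches the genetic code on canonical examples", {
  genes <- make_model("ATGTGGGGT")  # Met | Trp | Gly at chr1:101..109
  # ATG pos3 G->A: Met -> Ile (missense)
  a <- classify_variant(list(chrom = "chr1", pos = 103, ref = "G", alt = "A"),
                        genes)
  expect_equal(a$class, "missense")
  expect_equal(a$aa_ref, "M"); expect_equal(a$aa_alt, "I")
  expect_equal(a$codon_index, 0L); expect_equal(a$codon_pos, 3L)
  # TGG pos2 G->A: Trp -> stop (nonsense)
  b <- classify_variant(list(chrom = "chr1", pos = 105, ref = "G", alt = "A"),
                        genes)
  expect_equal(b$class, "nonsense"); expect_equal(b$aa_alt, "*")
  # GGT pos3 T->C: Gly -> Gly (synonymous)
  c <- classify_variant(list(chrom = "chr1", pos = 109, ref = "T", alt = "C"),
                        genes)
  expect_equal(c$class, "synonymous")
  # outside every gene: single noncoding annotation
  d <- classify_variant(list(chrom = "chr1", pos = 5, ref = "A", alt = "C"),
                        genes)
  expect_equal(d$class, "noncoding"); expect_equal(nrow(d), 1L)
})

test_that("all 549 single-base codon changes match a table-driven oracle", {
  st <- delscan:::codon_states()
  n_cases <- 0L
  for (ci in seq_along(st$codons)) {
    codon <- st$codons[ci]
    genes <- make_model(codon, start = 101L)
    for (p in 1:3) {
      ref <- substr(codon, p, p)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        ann <- classify_variant(list(chrom = "chr1", pos = 100L + p,
                                     ref = ref, alt = alt), genes)
        alt_codon <- codon
        substr(alt_codon, p, p) <- alt
        expect_identical(ann$class, oracle_classify(codon, alt_codon),
                         label = paste(codon, "->", alt_codon))
        n_cases <- n_cases + 1L
      }
    }
  }
  expect_equal(n_cases, 549L)
})

test_that("minus-strand classification equals the reverse-complement construction", {
  st <- delscan:::codon_states()
  set.seed(11)
  for (rep in 1:25) {
    cds <- paste(st$codons[sample.int(61, 5)], collapse = "")
    p <- sample.int(15, 1)
    ref <- substr(cds, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    plus <- make_model(cds, start = 101L, strand = "+")
    ann_plus <- classify_variant(list(chrom = "chr1", pos = 100L + p,
                                      ref = ref, alt = alt), plus)
    # same CDS annotated on the minus strand of the complementary genome:
    # genomic interval 101..115 holds revcomp(cds); CDS base k sits at
    # genomic position 115 - k + 1 with complemented alleles
    minus <- make_model(cds, start = 101L, strand = "-")
    ann_minus <- classify_variant(
      list(chrom = "chr1", pos = 115L - p + 1L,
           ref = delscan:::comp_base(ref), alt = delscan:::comp_base(alt)),
      minus)
    expect_identical(ann_minus$class, ann_plus$class)
    expect_identical(ann_minus$alt_codon, ann_plus$alt_codon)
  }
})

test_that("a SNP exonic in one transcript and intronic in another gets both annotations", {
  toy <- simulate_toy_genome(tempfile("toy"), n_genes = 2, seed = 4)
  genes <- read_gene_models(toy$gff, toy$fasta)
  truth <- toy$truth_table
  # the planted stop_loss of gene1 lies in exon 2 of t1, skipped by t2
  sl <- truth[truth$class == "stop_loss" & truth$gene == "gene1.t1", ][1, ]
  ann <- classify_variant(as.list(sl[c("chrom", "pos", "ref", "alt")]), genes)
  expect_setequal(ann$transcript, c("gene1.t1", "gene1.t2"))
  expect_setequal(ann$class, c("stop_loss", "noncoding"))
  expect_equal(effect_precedence(ann$class), "stop_loss")
})

test_that("flagged transcripts yield class unknown", {
  genes <- make_model("ATGT")  # length 4: flagged
  expect_true(genes[[1]]$flagged)
  a <- classify_variant(list(chrom = "chr1", pos = 102, ref = "T", alt = "C"),
                        genes)
  expect_equal(a$class, "unknown")
})

test_that("effect precedence follows nonsense > stop_loss > missense > synonymous > noncoding", {
  expect_equal(effect_precedence(c("synonymous", "missense")), "missense")
  expect_equal(effect_precedence("noncoding"), "noncoding")
  expect_equal(effect_precedence(c("nonsense", "synonymous")), "nonsense")
  expect_equal(effect_precedence(c("stop_loss", "missense")), "stop_loss")
  expect_error(effect_precedence(character(0)), "empty")
})

test_that("Grantham scores reproduce the published matrix and its formula", {
  expect_equal(grantham_score("L", "L"), 0)
  expect_equal(grantham_score("L", "I"), 5)
  expect_equal(grantham_score("C", "W"), 215)  # matrix maximum
  m <- grantham_matrix()
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_equal(max(m), 215)
  expect_error(grantham_score("L", "*"), "amino acid")
  # independent recomputation from composition/polarity/volume: published
  # integers agree to rounding except the historical Asp-Trp entry
  for (i in rownames(m)) for (j in colnames(m)) {
    if (i == j) next
    if ((i == "D" && j == "W") || (i == "W" && j == "D")) next
    expect_lt(abs(grantham_formula(i, j) - m[i, j]), 1.5)
  }
})

test_that("Ts/Tv ratio counts A<->G and C<->T as transitions", {
  d <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(ts_tv_ratio(d), 2)
  expect_equal(ts_tv_ratio(data.frame(ref = "A", alt = "T")), 0)
  expect_equal(ts_tv_ratio(data.frame(ref = c("A", "G"), alt = c("G", "A"))),
               Inf)
  expect_error(ts_tv_ratio(data.frame(ref = character(0),
                                      alt = character(0))), "empty")
})

test_that("codon position distribution conserves counts and rejects NA", {
  ann <- data.frame(codon_pos = c(3L, 3L, 3L))
  expect_equal(codon_position_distribution(ann), c("1" = 0L, "2" = 0L, "3" = 3L))
  mixed <- data.frame(codon_pos = c(1L, 2L, 2L, 3L, 1L))
  expect_equal(sum(codon_position_distribution(mixed)), 5L)
  expect_error(codon_position_distribution(data.frame(codon_pos = c(1L, NA))),
               "non-coding")
})

test_that("neutral coding changes land on codon positions per the code's degeneracy", {
  # draw random codons and random single-base changes (the simulator's
  # neutral mutation scheme) and check synonymous changes concentrate on
  # third positions as the code dictates
  st <- delscan:::codon_states()
  syn3 <- with(st$pairs, sum(syn & pos == 3) / sum(syn))
  expect_gt(syn3, 0.9)  # degeneracy structure: almost all synonymy is pos 3
  set.seed(2)
  pos <- integer(0); syn <- logical(0)
  for (k in 1:500) {
    pr <- st$pairs[sample.int(nrow(st$pairs), 1), ]
    pos <- c(pos, pr$pos); syn <- c(syn, pr$syn)
  }
  emp <- mean(pos[syn] == 3)
  expect_gt(emp, syn3 - 3 * sqrt(syn3 * (1 - syn3) / sum(syn)))
})
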