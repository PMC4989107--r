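# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal VCF text from a record data.frame and genotype matrix.
vcf_text <- function(records, gt, samples = colnames(gt)) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  c(header, body)
}

# Single-transcript gene model object without touching GFF parsing.
make_model <- function(cds, chrom = "chr1", strand = "+", start = 101L,
                       id = "tx1", phase = 0L, intervals = NULL) {
  if (is.null(intervals))
    intervals <- data.frame(start = start, end = start + nchar(cds) - 1L)
  aa <- delscan:::translate_codon(
    substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3)))
  flagged <- nchar(cds) %% 3 != 0 ||
    any(aa[-length(aa)] == "*", na.rm = TRUE)
  structure(list(list(id = id, chrom = chrom, strand = strand,
                      intervals = intervals, phase = phase, cds = cds,
                      flagged = flagged,
                      flag_reason = NA_character_)),
            names = id, class = "gene_annotation_set")
}

# Independent table-driven genetic code (NCBI standard code, TCAG order),
# deliberately not built from the package's own tables.
oracle_code <- local({
  aas <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  bases <- c("T", "C", "A", "G")
  codons <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_classify <- function(ref_codon, alt_codon) {
  a1 <- oracle_code[[ref_codon]]; a2 <- oracle_code[[alt_codon]]
  if (a1 == a2) "synonymous"
  else if (a2 == "*") "nonsense"
  else if (a1 == "*") "stop_loss"
  else "missense"
}

# Deterministic tree with n tips and fixed total length (balanced when n is
# a power of two, ladder otherwise).
balanced_tree <- function(n, total_len = 2) {
  type <- if (log2(n) %% 1 == 0) "balanced" else "left"
  tr <- ape::stree(n, type = type)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * total_len
  tr
}

# Random alignment of sense codons (no evolution; for i/o and counting tests).
random_aln <- function(taxa, n_codons, seed = 1, query = taxa[1]) {
  st <- delscan:::codon_states()
  delscan:::with_seed(seed, {
    seqs <- vapply(taxa, function(t)
      paste(st$codons[sample.int(61, n_codons, TRUE)], collapse = ""),
      character(1))
    codon_alignment(seqs, query)
  })
}
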