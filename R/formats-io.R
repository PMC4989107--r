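# Readers and writers for the external formats the toolkit touches: VCF
# (variants + genotypes), GFF3 + genome FASTA (gene models), aligned FASTA
# (codon alignments), Newick (phylogeny), TSV (genetic map).
#
# Coordinate convention: every external format is 1-based inclusive
# (VCF/GFF3); internal codon/offset arithmetic is 0-based. Conversion happens
# only at these boundaries.

# ---- variant table -----------------------------------------------------

#' Construct a variant table
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases, ref != alt) and optionally `id`.
#' @param gt Character matrix of unphased diploid genotypes ("0/0", "0/1",
#'   "1/1", `NA` for missing), one row per record, one column per sample.
#' @param sample_ids Ordered accession labels (defaults to gt colnames).
#' @return Object of class `variant_table`.
#' @export
variant_table <- function(records, gt, sample_ids = colnames(gt)) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "ref", "alt") %in% names(records)),
            nrow(gt) == nrow(records))
  if (any(records$ref == records$alt)) stop("variant_table: ref == alt")
  if (any(records$pos < 1)) stop("variant_table: positions must be 1-based")
  if (is.null(records$id)) {
    records$id <- variant_key(records$chrom, records$pos,
                              records$ref, records$alt)
  }
  gt <- as.matrix(gt)
  colnames(gt) <- sample_ids
  structure(list(records = records, gt = gt, sample_ids = sample_ids),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d biallelic SNPs x %d samples\n",
              nrow(x$records), length(x$sample_ids)))
  invisible(x)
}

#' Canonical variant identifier
#' @param chrom,pos,ref,alt Variant fields.
#' @return `chrom:pos:ref:alt` key used to join external prediction tables.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

normalize_gt <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  g[g %in% c(".", "./.", ".|.")] <- NA_character_
  # half-calls count as missing
  g[grepl("\\.", g)] <- NA_character_
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p))))
      return(NA_character_)
    paste(sort(as.integer(p)), collapse = "/")
  }, character(1))
}

#' Read biallelic SNPs from a VCF file
#'
#' Multiallelic records, indels and other non-SNP records are dropped (with a
#' logged count); sample order is preserved. Genotypes are taken from the GT
#' field, unphased; half-calls and `./.` are treated as missing.
#'
#' @param path VCF v4.x file with GT in FORMAT.
#' @return A [variant_table()].
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("read_variants: empty VCF")
  if (!"FORMAT" %in% colnames(v@gt))
    stop("read_variants: VCF has no genotype columns")
  no_gt <- !grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])
  if (any(no_gt)) {
    stop(sprintf("read_variants: record %s:%s has no GT in FORMAT",
                 fix[which(no_gt)[1], "CHROM"], fix[which(no_gt)[1], "POS"]))
  }
  pos <- as.integer(fix[, "POS"])
  # per-chromosome sortedness check
  for (ch in unique(fix[, "CHROM"])) {
    p <- pos[fix[, "CHROM"] == ch]
    if (is.unsorted(p)) stop("read_variants: VCF not sorted on ", ch)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L &
    nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    ds_log("read_variants: dropped %d non-biallelic-SNP records", n_drop)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(v@gt)[-1]
  gt <- matrix(normalize_gt(gt_raw[keep, , drop = FALSE]),
               nrow = sum(keep), dimnames = list(NULL, samples))
  records <- data.frame(chrom = fix[keep, "CHROM"], pos = pos[keep],
                        ref = ref[keep], alt = alt[keep],
                        stringsAsFactors = FALSE)
  out <- variant_table(records, gt, samples)
  out$n_dropped <- n_drop
  out
}

#' Write a variant table to a VCF file
#'
#' @param vt A [variant_table()].
#' @param path Output path (plain-text VCF v4.2).
#' @return `path`, invisibly.
#' @export
write_variants <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$sample_ids),
                     collapse = "\t")), con)
  gt <- vt$gt
  gt[is.na(gt)] <- "./."
  body <- paste(vt$records$chrom, vt$records$pos, vt$records$id,
                vt$records$ref, vt$records$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

# ---- gene models -------------------------------------------------------

#' Read gene models from GFF3 + genome FASTA
#'
#' Builds one gene model per transcript from GFF3 CDS features (grouped by
#' their `Parent` attribute). Minus-strand CDS are spliced in translation
#' order and reverse-complemented; the phase of the first coding exon is
#' honoured for partial models. Transcripts whose phased CDS length is not a
#' multiple of 3, or that contain an internal stop codon, are flagged and
#' excluded from codon-level operations.
#'
#' @param gff3 Path to a GFF3 file whose CDS features carry Parent attributes.
#' @param fasta Path to the genome FASTA containing all referenced sequences.
#' @return Object of class `gene_annotation_set`: a named list of gene models,
#'   each a list with `id`, `chrom`, `strand`, `intervals` (data.frame start,
#'   end, 1-based inclusive, ascending), `phase`, `cds` (spliced CDS string),
#'   `flagged`, `flag_reason`.
#' @export
read_gene_models <- function(gff3, fasta) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3)
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("read_gene_models: no CDS features in ", gff3)
  parents <- cds$Parent
  if (is.null(parents)) stop("read_gene_models: CDS features lack Parent")
  # a CDS row may belong to several transcripts
  reps <- lengths(parents)
  cds <- cds[rep(seq_len(nrow(cds)), reps), , drop = FALSE]
  cds$tx <- unlist(parents)
  models <- lapply(split(cds, cds$tx), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    chrom <- as.character(d$seqnames[1])
    strand <- as.character(d$strand[1])
    if (!chrom %in% names(genome))
      stop("read_gene_models: chromosome ", chrom, " absent from FASTA")
    if (any(d$start[-1] <= d$end[-nrow(d)]))
      stop("read_gene_models: overlapping CDS intervals in ", d$tx[1])
    gseq <- genome[[chrom]]
    pieces <- vapply(seq_len(nrow(d)), function(k) {
      as.character(Biostrings::subseq(gseq, d$start[k], d$end[k]))
    }, character(1))
    spliced <- paste(pieces, collapse = "")
    # phase of the first exon in translation order
    ph <- d$phase
    ph[is.na(ph)] <- 0L
    if (strand == "-") {
      spliced <- revcomp(spliced)
      phase1 <- ph[nrow(d)]
    } else {
      phase1 <- ph[1]
    }
    cds_seq <- substr(spliced, phase1 + 1L, nchar(spliced))
    flagged <- FALSE; reason <- NA_character_
    if (nchar(cds_seq) %% 3L != 0L) {
      flagged <- TRUE; reason <- "length_not_multiple_of_3"
    } else {
      aa <- translate_codon(substring(cds_seq, seq(1, nchar(cds_seq), 3),
                                      seq(3, nchar(cds_seq), 3)))
      internal <- aa[-length(aa)]
      if (any(internal == "*", na.rm = TRUE)) {
        flagged <- TRUE; reason <- "internal_stop"
      }
    }
    list(id = as.character(d$tx[1]), chrom = chrom, strand = strand,
         intervals = data.frame(start = d$start, end = d$end),
         phase = phase1, cds = cds_seq, flagged = flagged,
         flag_reason = reason)
  })
  n_flag <- sum(vapply(models, `[[`, logical(1), "flagged"))
  if (n_flag > 0)
    ds_log("read_gene_models: flagged %d transcript(s) as partial/invalid",
           n_flag)
  structure(models, class = "gene_annotation_set")
}

#' @export
print.gene_annotation_set <- function(x, ...) {
  flagged <- sum(vapply(x, `[[`, logical(1), "flagged"))
  cat(sprintf("gene_annotation_set: %d transcripts (%d flagged)\n",
              length(x), flagged))
  invisible(x)
}

# ---- codon alignment ---------------------------------------------------

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned sequences, equal length,
#'   length divisible by 3.
#' @param query Label of the query taxon (the species whose variants are
#'   tested; masked from likelihoods and the novelty rule).
#' @return Object of class `codon_alignment` with taxa labels, a taxa x
#'   codon-column integer state matrix (`NA` = missing: any gap, N, IUPAC
#'   ambiguity or stop codon makes the whole codon missing for that taxon),
#'   the raw nucleotide matrix, and the query label.
#' @export
codon_alignment <- function(seqs, query) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("codon_alignment: sequences must have unique names")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("codon_alignment: ragged alignment")
  if (L %% 3L != 0L)
    stop("codon_alignment: alignment length ", L, " not divisible by 3")
  if (!query %in% names(seqs))
    stop("codon_alignment: query taxon '", query, "' absent")
  taxa <- names(seqs)
  nt_mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(nt_mat) <- taxa
  ncod <- L %/% 3L
  starts <- seq(1L, L, 3L)
  codons <- vapply(seq_along(taxa), function(i) {
    substring(toupper(seqs[[i]]), starts, starts + 2L)
  }, character(ncod))
  codons <- matrix(codons, nrow = ncod)  # guards ncod == 1
  states <- matrix(encode_codons(codons), nrow = ncod)
  colnames(states) <- taxa
  n_stop <- sum(translate_codon(codons) == "*", na.rm = TRUE)
  if (n_stop > 0)
    ds_log("codon_alignment: %d stop-containing codon(s) set to missing",
           n_stop)
  structure(list(taxa = taxa, query = query,
                 states = t(states), nt = nt_mat, n_codons = ncod),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d codon columns (query: %s)\n",
              length(x$taxa), x$n_codons, x$query))
  invisible(x)
}

#' Read a codon alignment from aligned FASTA
#'
#' @param path Aligned FASTA; all sequences equal length, divisible by 3.
#' @param query_taxon Label of the query taxon; must be present.
#' @return A [codon_alignment()].
#' @export
read_alignment <- function(path, query_taxon) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  codon_alignment(seqs, query_taxon)
}

#' Write a codon alignment to FASTA
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$nt, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$taxa, "\n", seqs), path)
  invisible(path)
}

# ---- phylogeny ---------------------------------------------------------

#' Read a phylogeny from a Newick file
#'
#' Branch lengths are in expected substitutions per codon site and are
#' required on every edge: there is no defaulting.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object, validated.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("read_tree: could not parse ", path)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree: every edge must carry a branch length")
  if (any(tr$edge.length < 0)) stop("tree: negative branch length")
  if (anyDuplicated(tr$tip.label)) stop("tree: duplicate tip labels")
  invisible(tr)
}

# ---- genetic map -------------------------------------------------------

#' Read a genetic map from TSV
#'
#' Plain TSV with header columns `marker`, `chrom`, `bp`, `cM`. Markers are
#' sorted by physical position within chromosome; duplicate bp positions are
#' collapsed to the first occurrence with a warning.
#'
#' @param path TSV file.
#' @return Object of class `genetic_map`: data.frame (marker, chrom, bp, cM)
#'   sorted by (chrom, bp).
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% names(d)))
    stop("read_genetic_map: need columns ", paste(need, collapse = ", "))
  for (col in c("bp", "cM")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v) && !all(is.na(d[[col]]) == is.na(v))) {
      bad <- which(is.na(v) & !is.na(d[[col]]))[1]
      stop(sprintf("read_genetic_map: non-numeric %s at line %d", col,
                   bad + 1L))  # +1 for header
    }
    d[[col]] <- v
  }
  d <- d[order(d$chrom, d$bp), , drop = FALSE]
  dup <- duplicated(d[, c("chrom", "bp")])
  if (any(dup)) {
    warning(sprintf("read_genetic_map: %d duplicate bp position(s) collapsed",
                    sum(dup)))
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  structure(d, class = c("genetic_map", "data.frame"))
}
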