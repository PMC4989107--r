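# SNP effect classification against gene models: noncoding / synonymous /
# missense / nonsense / stop_loss, with codon-position bookkeeping, Ts/Tv
# and codon-position summaries. Universal genetic code throughout (both
# target crops are nuclear-gene analyses).

EFFECT_LEVELS <- c("unknown", "noncoding", "synonymous", "missense",
                   "stop_loss", "nonsense")

# Map a genomic position to the 0-based offset within the spliced,
# phase-trimmed CDS of one gene model, or NA if the position falls in an
# intron (within the CDS span but outside every interval).
cds_offset <- function(model, pos) {
  iv <- model$intervals
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (length(hit) == 0) return(NA_integer_)
  if (model$strand == "+") {
    raw <- sum(iv$end[seq_len(hit - 1L)] - iv$start[seq_len(hit - 1L)] + 1L) +
      (pos - iv$start[hit])
  } else {
    later <- seq_len(nrow(iv)) > hit
    raw <- sum(iv$end[later] - iv$start[later] + 1L) + (iv$end[hit] - pos)
  }
  as.integer(raw - model$phase)
}

classify_one <- function(chrom, pos, ref, alt, model) {
  base <- data.frame(transcript = model$id, class = NA_character_,
                     codon_index = NA_integer_, codon_pos = NA_integer_,
                     ref_codon = NA_character_, alt_codon = NA_character_,
                     aa_ref = NA_character_, aa_alt = NA_character_,
                     stringsAsFactors = FALSE)
  if (model$flagged) { base$class <- "unknown"; return(base) }
  off <- cds_offset(model, pos)
  if (is.na(off) || off < 0L || off >= nchar(model$cds)) {
    base$class <- "noncoding"; return(base)
  }
  ci <- off %/% 3L
  cp <- off %% 3L + 1L
  ref_codon <- substr(model$cds, ci * 3L + 1L, ci * 3L + 3L)
  if (model$strand == "-") { ref <- comp_base(ref); alt <- comp_base(alt) }
  if (substr(ref_codon, cp, cp) != ref) {
    # reference allele disagrees with the annotated CDS sequence
    base$class <- "unknown"; return(base)
  }
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  cls <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_loss"
    else "missense"
  base$class <- cls; base$codon_index <- ci; base$codon_pos <- cp
  base$ref_codon <- ref_codon; base$alt_codon <- alt_codon
  base$aa_ref <- aa_ref; base$aa_alt <- aa_alt
  base
}

#' Classify one SNP against a set of gene models
#'
#' Produces one effect annotation per transcript whose CDS span overlaps the
#' variant (a SNP can be exonic in one transcript and intronic in another);
#' zero overlapping transcripts yield a single noncoding annotation.
#' Minus-strand variants are complemented before the codon substitution.
#' Variants inside flagged (partial/invalid) transcripts are classified
#' `"unknown"` and excluded from downstream counts.
#'
#' @param v List or one-row data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genes A `gene_annotation_set` from [read_gene_models()].
#' @return data.frame with columns `variant_id`, `transcript`, `class`,
#'   `codon_index` (0-based), `codon_pos` (1..3), `ref_codon`, `alt_codon`,
#'   `aa_ref`, `aa_alt`.
#' @export
classify_variant <- function(v, genes) {
  stopifnot(nchar(v$ref) == 1L, nchar(v$alt) == 1L, v$ref != v$alt)
  vid <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  overlapping <- Filter(function(m) {
    m$chrom == v$chrom && v$pos >= min(m$intervals$start) &&
      v$pos <= max(m$intervals$end)
  }, unclass(genes))
  if (length(overlapping) == 0) {
    return(data.frame(variant_id = vid, transcript = NA_character_,
                      class = "noncoding", codon_index = NA_integer_,
                      codon_pos = NA_integer_, ref_codon = NA_character_,
                      alt_codon = NA_character_, aa_ref = NA_character_,
                      aa_alt = NA_character_, stringsAsFactors = FALSE))
  }
  rows <- lapply(overlapping, function(m)
    classify_one(v$chrom, v$pos, v$ref, v$alt, m))
  out <- do.call(rbind, rows)
  out <- cbind(variant_id = vid, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify every SNP in a variant table
#'
#' @param vt A [variant_table()].
#' @param genes A `gene_annotation_set`.
#' @return data.frame of per-(variant, transcript) annotations, as
#'   [classify_variant()], stacked.
#' @export
classify_variants <- function(vt, genes) {
  rows <- lapply(seq_len(nrow(vt$records)), function(i)
    classify_variant(vt$records[i, ], genes))
  do.call(rbind, rows)
}

#' Single summary class for a SNP annotated in several transcripts
#'
#' Precedence: nonsense > stop_loss > missense > synonymous > noncoding >
#' unknown.
#'
#' @param classes Character vector of effect classes (>= 1).
#' @return The maximal class under the precedence order.
#' @export
effect_precedence <- function(classes) {
  if (length(classes) == 0) stop("effect_precedence: empty annotation list")
  bad <- setdiff(classes, EFFECT_LEVELS)
  if (length(bad) > 0)
    stop("effect_precedence: unknown class ", paste(bad, collapse = ", "))
  EFFECT_LEVELS[max(match(classes, EFFECT_LEVELS))]
}

#' Per-variant summary classes for a full annotation table
#'
#' @param annotations Output of [classify_variants()].
#' @return data.frame `variant_id`, `class` (one row per variant, precedence
#'   applied across transcripts).
#' @export
summarize_effects <- function(annotations) {
  cls <- tapply(annotations$class, annotations$variant_id, effect_precedence)
  out <- data.frame(variant_id = names(cls), class = unname(cls),
                    stringsAsFactors = FALSE)
  # keep input order
  out[match(unique(annotations$variant_id), out$variant_id), , drop = FALSE]
}

#' Transition/transversion ratio of a SNP set
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @param variants A [variant_table()] or data.frame with `ref`, `alt`.
#' @return Ratio of transition to transversion counts; `Inf` when there are
#'   no transversions.
#' @export
ts_tv_ratio <- function(variants) {
  d <- if (inherits(variants, "variant_table")) variants$records else variants
  if (nrow(d) == 0) stop("ts_tv_ratio: empty variant set")
  pair <- paste0(pmin(d$ref, d$alt), pmax(d$ref, d$alt))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(d) - ts
  if (tv == 0) return(Inf)
  ts / tv
}

#' Distribution of coding SNPs over codon positions
#'
#' @param annotations data.frame with a `codon_pos` column (coding
#'   annotations only; rows with `NA` codon position are rejected).
#' @return Named integer vector with counts for positions "1", "2", "3".
#' @export
codon_position_distribution <- function(annotations) {
  cp <- annotations$codon_pos
  if (anyNA(cp)) stop("codon_position_distribution: non-coding rows present")
  counts <- tabulate(cp, nbins = 3L)
  stats::setNames(as.integer(counts), c("1", "2", "3"))
}
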