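# Ancestral-state inference from a designated outgroup clade, polarization
# of variants to derived allele counts, and the class-stratified summaries
# built on top (unfolded SFS, heterozygosity, private fraction).
#
# Only coding variants are polarized in the pipeline: outgroup alignment
# outside CDS is not reliable for ancestral-state inference.

#' Infer the ancestral base at an aligned nucleotide column
#'
#' Strict-majority state (> 50% of informative taxa) among the non-missing
#' outgroup taxa; a tie or zero informative taxa yields `NA` (unknown).
#'
#' @param aln A [codon_alignment()].
#' @param outgroup_taxa Labels of the outgroup clade (must be alignment
#'   taxa).
#' @param nt_column 1-based nucleotide column.
#' @return Single base or `NA_character_`.
#' @export
infer_ancestral <- function(aln, outgroup_taxa, nt_column) {
  if (!all(outgroup_taxa %in% aln$taxa))
    stop("infer_ancestral: outgroup taxa absent from alignment: ",
         paste(setdiff(outgroup_taxa, aln$taxa), collapse = ", "))
  if (nt_column < 1L || nt_column > ncol(aln$nt))
    stop("infer_ancestral: column out of range")
  obs <- aln$nt[outgroup_taxa, nt_column]
  obs <- obs[obs %in% c("A", "C", "G", "T")]
  if (length(obs) == 0) return(NA_character_)
  tab <- table(obs)
  top <- tab[tab == max(tab)]
  if (length(top) > 1 || max(tab) * 2L <= length(obs)) return(NA_character_)
  names(top)
}

# genotype string -> number of '1' alleles (NA for missing)
gt_alt_count <- function(g) {
  out <- rep(NA_integer_, length(g))
  out[g == "0/0"] <- 0L
  out[g == "0/1"] <- 1L
  out[g == "1/1"] <- 2L
  out
}

#' Polarize one variant given its ancestral base
#'
#' The derived allele is whichever of ref/alt is not ancestral; the derived
#' allele count is taken over called genotypes (a heterozygote contributes
#' one derived allele).
#'
#' @param v List with `ref`, `alt` and `gt`, a named character vector of
#'   unphased genotypes ("0/0", "0/1", "1/1", `NA`).
#' @param ancestral The inferred ancestral base.
#' @return List with `ancestral`, `derived`, `derived_count`,
#'   `total_called` (called allele count), `carriers` (accessions carrying
#'   >= 1 derived allele); or, when the ancestral base matches neither
#'   allele, `list(excluded = TRUE, reason = "ancestral_mismatch")`.
#' @export
polarize <- function(v, ancestral) {
  if (is.na(ancestral) || !(ancestral %in% c(v$ref, v$alt)))
    return(list(excluded = TRUE, reason = "ancestral_mismatch"))
  alt_n <- gt_alt_count(v$gt)
  called <- !is.na(alt_n)
  if (ancestral == v$ref) {
    derived <- v$alt
    dcount <- alt_n
  } else {
    derived <- v$ref
    dcount <- 2L - alt_n
  }
  list(excluded = FALSE, ancestral = ancestral, derived = derived,
       derived_count = sum(dcount[called]),
       total_called = 2L * sum(called),
       carriers = names(v$gt)[called & dcount > 0L])
}

#' Polarize a variant table against per-variant ancestral bases
#'
#' @param vt A [variant_table()].
#' @param ancestral Named character vector (by variant id) of ancestral
#'   bases; variants absent or `NA` are excluded with reason
#'   `"no_ancestral"`.
#' @return List with `polarized` (data.frame: variant_id, ancestral,
#'   derived, derived_count, total_called, n_carriers), `carriers` (named
#'   list of carrier accessions), and `excluded` (data.frame variant_id,
#'   reason). The two parts always partition the input exactly.
#' @export
polarize_variants <- function(vt, ancestral) {
  ids <- vt$records$id
  pol <- list(); carr <- list(); exc <- list()
  for (i in seq_along(ids)) {
    anc <- if (ids[i] %in% names(ancestral)) ancestral[[ids[i]]]
      else NA_character_
    if (is.na(anc)) {
      exc[[length(exc) + 1L]] <- data.frame(variant_id = ids[i],
                                            reason = "no_ancestral")
      next
    }
    v <- list(ref = vt$records$ref[i], alt = vt$records$alt[i],
              gt = stats::setNames(vt$gt[i, ], vt$sample_ids))
    p <- polarize(v, anc)
    if (p$excluded) {
      exc[[length(exc) + 1L]] <- data.frame(variant_id = ids[i],
                                            reason = p$reason)
    } else {
      pol[[length(pol) + 1L]] <- data.frame(
        variant_id = ids[i], ancestral = p$ancestral, derived = p$derived,
        derived_count = p$derived_count, total_called = p$total_called,
        n_carriers = length(p$carriers), stringsAsFactors = FALSE)
      carr[[ids[i]]] <- p$carriers
    }
  }
  empty_pol <- data.frame(variant_id = character(0), ancestral = character(0),
                          derived = character(0), derived_count = integer(0),
                          total_called = integer(0), n_carriers = integer(0))
  list(polarized = if (length(pol)) do.call(rbind, pol) else empty_pol,
       carriers = carr,
       excluded = if (length(exc)) do.call(rbind, exc) else
         data.frame(variant_id = character(0), reason = character(0)))
}

#' Unfolded (derived) site frequency spectrum per class
#'
#' @param polarized data.frame from [polarize_variants()]`$polarized`.
#' @param class_of Named character vector mapping variant id to class label.
#' @param n_samples Number of diploid accessions (spectrum bins are
#'   1..2*n_samples - 1, segregating sites only).
#' @return Named list of integer spectra, one per class present; each sums
#'   to the number of polarized segregating variants of that class. Variants
#'   with derived count 0 or 2N (non-segregating in the sample) are not
#'   binned.
#' @export
derived_sfs <- function(polarized, class_of, n_samples) {
  nb <- 2L * n_samples - 1L
  if (nrow(polarized) > 0 &&
      any(polarized$total_called > 2L * n_samples))
    stop("derived_sfs: variants polarized against a larger sample set")
  cls <- unname(class_of[polarized$variant_id])
  cls[is.na(cls)] <- "unclassified"
  out <- list()
  for (cl in unique(cls)) {
    dc <- polarized$derived_count[cls == cl]
    dc <- dc[dc >= 1L & dc <= nb]
    out[[cl]] <- stats::setNames(tabulate(dc, nbins = nb), seq_len(nb))
  }
  out
}

#' Mean observed heterozygosity per SNP class
#'
#' Per SNP: the fraction of called genotypes that are heterozygous; per
#' class: the mean over its SNPs.
#'
#' @param vt A [variant_table()].
#' @param classes Named character vector mapping variant id to class.
#' @return Named numeric vector of class means.
#' @export
heterozygosity_by_class <- function(vt, classes) {
  het <- apply(vt$gt, 1L, function(g) {
    called <- !is.na(g)
    if (!any(called)) return(NA_real_)
    sum(g[called] == "0/1") / sum(called)
  })
  cls <- unname(classes[vt$records$id])
  keep <- !is.na(cls) & !is.na(het)
  tapply(het[keep], cls[keep], mean)
}

#' Fraction of variants private to a single accession
#'
#' @param polarized data.frame with an `n_carriers` column (from
#'   [polarize_variants()]).
#' @return Fraction of variants whose derived allele occurs in exactly one
#'   accession.
#' @export
private_fraction <- function(polarized) {
  if (nrow(polarized) == 0) stop("private_fraction: no polarized variants")
  mean(polarized$n_carriers == 1L)
}
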