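# Codon-state machinery shared by the substitution model, the effect
# classifier and the simulator. The state space is the 61 sense codons of the
# universal genetic code; stop codons are never valid observed states.

#' The universal genetic code over 64 codons
#'
#' Named character vector mapping codon (e.g. "ATG") to one-letter amino acid,
#' with "*" for stop. Taken from [Biostrings::GENETIC_CODE] so the table used
#' for classification is the community-standard one.
#'
#' @return Named character vector of length 64.
#' @keywords internal
genetic_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  # Biostrings uses T-containing codon names already (DNA alphabet)
  stats::setNames(as.character(gc), names(gc))
}

# Internal cache for codon-state tables (built once, on first use).
.codon_cache <- new.env(parent = emptyenv())

#' Sense-codon state tables
#'
#' Builds (and caches) the 61-state codon universe: codon strings, encoded
#' amino acids, per-position nucleotide indices, and the single-nucleotide
#' neighbour structure (which pairs differ at exactly one position, whether
#' the change is a transition, and whether it is synonymous). Everything
#' downstream -- rate matrix, pruning, simulator, classifier oracle -- indexes
#' into these tables.
#'
#' @return List with elements `codons` (character 61), `aa` (character 61),
#'   `nt` (61 x 3 integer matrix, 1=A 2=C 3=G 4=T), `pairs` (data.frame of
#'   ordered single-step neighbour pairs `i`, `j` with logicals `ts`, `syn`),
#'   and `codon_index` (named integer lookup codon -> state).
#' @keywords internal
codon_states <- function() {
  if (!is.null(.codon_cache$states)) return(.codon_cache$states)
  nts <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  # outer() order is position-3 fastest; rebuild in plain lexicographic order
  all64 <- sort(apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE),
                      1L, function(x) paste0(x[1], x[2], x[3])))
  code <- genetic_code_table()
  aa64 <- unname(code[all64])
  sense <- all64[aa64 != "*"]
  aa <- unname(code[sense])
  nt <- t(vapply(strsplit(sense, ""), function(x) match(x, nts), integer(3)))
  n <- length(sense)
  stopifnot(n == 61L)
  ii <- jj <- integer(0); ts <- syn <- logical(0); pos <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(nt[i, ] != nt[j, ])
      if (length(d) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j); pos <- c(pos, d)
      from <- nt[i, d]; to <- nt[j, d]
      # transitions: A<->G (1,3), C<->T (2,4)
      ts <- c(ts, (from + to) %in% c(4L, 6L) && abs(from - to) == 2L)
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  st <- list(codons = sense, aa = aa, nt = nt,
             pairs = data.frame(i = ii, j = jj, pos = pos, ts = ts, syn = syn),
             codon_index = stats::setNames(seq_len(n), sense))
  .codon_cache$states <- st
  st
}

#' Translate a codon string to a one-letter amino acid
#' @param codon Character vector of 3-letter codons (DNA alphabet).
#' @return Character vector of one-letter amino acids, `"*"` for stop, `NA`
#'   for codons containing gaps or ambiguity.
#' @keywords internal
translate_codon <- function(codon) {
  code <- genetic_code_table()
  out <- unname(code[toupper(codon)])
  out[is.na(out)] <- NA_character_
  out
}

# Encode a character vector of codons as 1..61 state indices; anything that
# is not a sense codon (gap, ambiguity, stop) becomes NA (= missing taxon).
encode_codons <- function(codons) {
  st <- codon_states()
  unname(st$codon_index[toupper(codons)])
}

# Reverse-complement a DNA string (base R wrapper over Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[toupper(b)]
}
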