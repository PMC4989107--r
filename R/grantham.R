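# Grantham (1974) physico-chemical distances between amino acids.
#
# grantham_score() returns the published integer matrix, which is what the
# field's annotation pipelines cite and compare against. The underlying
# composition/polarity/volume formula is also exposed so the matrix can be
# recomputed; the published integers differ from the formula by at most one
# unit of rounding, except the Asp-Trp entry (181 published vs 190.6
# recomputed), a long-known inconsistency of the original publication that we
# preserve because the published matrix is the de-facto standard.

.grantham_aa <- c("S","R","L","P","T","A","V","G","I","F",
                  "Y","C","H","Q","N","K","D","E","M","W")

# Side-chain properties: composition c, polarity p, volume v.
.grantham_props <- data.frame(
  aa = .grantham_aa,
  c = c(1.42,0.65,0,0.39,0.71,0,0,0.74,0,0,0.20,2.75,0.58,0.89,1.33,0.33,1.38,0.92,0,0.13),
  p = c(9.2,10.5,4.9,8.0,8.6,8.1,5.9,9.0,5.2,5.2,6.2,5.5,10.4,10.5,11.6,11.3,13.0,12.3,5.7,5.4),
  v = c(32,124,111,32.5,61,31,84,3,111,132,136,55,96,85,56,119,54,83,105,170)
)

# Published upper-triangle distances, row order as in .grantham_aa.
.grantham_upper <- list(
  S = c(R=110,L=145,P=74,T=58,A=99,V=124,G=56,I=142,F=155,Y=144,C=112,H=89,Q=68,N=46,K=121,D=65,E=80,M=135,W=177),
  R = c(L=102,P=103,T=71,A=112,V=96,G=125,I=97,F=97,Y=77,C=180,H=29,Q=43,N=86,K=26,D=96,E=54,M=91,W=101),
  L = c(P=98,T=92,A=96,V=32,G=138,I=5,F=22,Y=36,C=198,H=99,Q=113,N=153,K=107,D=172,E=138,M=15,W=61),
  P = c(T=38,A=27,V=68,G=42,I=95,F=114,Y=110,C=169,H=77,Q=76,N=91,K=103,D=108,E=93,M=87,W=147),
  T = c(A=58,V=69,G=59,I=89,F=103,Y=92,C=149,H=47,Q=42,N=65,K=78,D=85,E=65,M=81,W=128),
  A = c(V=64,G=60,I=94,F=113,Y=112,C=195,H=86,Q=91,N=111,K=106,D=126,E=107,M=84,W=148),
  V = c(G=109,I=29,F=50,Y=55,C=192,H=84,Q=96,N=133,K=97,D=152,E=121,M=21,W=88),
  G = c(I=135,F=153,Y=147,C=159,H=98,Q=87,N=80,K=127,D=94,E=98,M=127,W=184),
  I = c(F=21,Y=33,C=198,H=94,Q=109,N=149,K=102,D=168,E=134,M=10,W=61),
  F = c(Y=22,C=205,H=100,Q=116,N=158,K=102,D=177,E=140,M=28,W=40),
  Y = c(C=194,H=83,Q=99,N=143,K=85,D=160,E=122,M=36,W=37),
  C = c(H=174,Q=154,N=139,K=202,D=154,E=170,M=196,W=215),
  H = c(Q=24,N=68,K=32,D=81,E=40,M=87,W=115),
  Q = c(N=46,K=53,D=61,E=29,M=101,W=130),
  N = c(K=94,D=23,E=42,M=142,W=174),
  K = c(D=101,E=56,M=95,W=110),
  D = c(E=45,M=160,W=181),
  E = c(M=126,W=152),
  M = c(W=67)
)

.grantham_cache <- new.env(parent = emptyenv())

#' The Grantham distance matrix
#'
#' @return Symmetric 20 x 20 integer matrix of published Grantham distances,
#'   zero diagonal, dimnames in one-letter amino-acid codes.
#' @export
grantham_matrix <- function() {
  if (!is.null(.grantham_cache$mat)) return(.grantham_cache$mat)
  m <- matrix(0, 20, 20, dimnames = list(.grantham_aa, .grantham_aa))
  for (a1 in names(.grantham_upper)) {
    for (a2 in names(.grantham_upper[[a1]])) {
      m[a1, a2] <- m[a2, a1] <- .grantham_upper[[a1]][[a2]]
    }
  }
  .grantham_cache$mat <- m
  m
}

#' Grantham score of an amino-acid replacement
#'
#' Chemical dissimilarity of two amino acids combining side-chain composition,
#' polarity and molecular volume. Identity scores 0; the matrix maximum is
#' Cys-Trp at 215. Used to summarise the severity of missense changes called
#' deleterious by different prediction methods.
#'
#' @param aa_ref,aa_alt One-letter amino-acid codes (vectors recycle).
#' @return Numeric vector of published Grantham distances.
#' @examples
#' grantham_score("L", "I")
#' grantham_score(c("C", "G"), c("W", "G"))
#' @export
grantham_score <- function(aa_ref, aa_alt) {
  aa_ref <- toupper(aa_ref); aa_alt <- toupper(aa_alt)
  bad <- !(aa_ref %in% .grantham_aa) | !(aa_alt %in% .grantham_aa)
  if (any(bad)) {
    stop("grantham_score: not a standard amino acid: ",
         paste(unique(c(aa_ref[bad], aa_alt[bad])), collapse = ", "))
  }
  m <- grantham_matrix()
  m[cbind(aa_ref, aa_alt)]
}

#' Recompute Grantham distances from side-chain properties
#'
#' Evaluates rho * sqrt(alpha (c_i-c_j)^2 + beta (p_i-p_j)^2 + gamma
#' (v_i-v_j)^2) with the published constants alpha = 1.833, beta = 0.1018,
#' gamma = 0.000399, rho = 50.723. Provided as an independent check on the
#' published matrix; see the package vignette for the one historical
#' inconsistency (Asp-Trp).
#'
#' @param aa_ref,aa_alt One-letter amino-acid codes.
#' @return Unrounded formula distances.
#' @export
grantham_formula <- function(aa_ref, aa_alt) {
  p <- .grantham_props
  i <- match(toupper(aa_ref), p$aa); j <- match(toupper(aa_alt), p$aa)
  if (anyNA(i) || anyNA(j)) stop("grantham_formula: not a standard amino acid")
  50.723 * sqrt(1.833 * (p$c[i] - p$c[j])^2 +
                0.1018 * (p$p[i] - p$p[j])^2 +
                0.000399 * (p$v[i] - p$v[j])^2)
}
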