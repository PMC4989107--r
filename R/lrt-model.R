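# Goldman-Yang style codon substitution model and Felsenstein pruning
# likelihood. The generator Q acts on the 61 sense codons: rates are zero for
# multi-nucleotide changes and otherwise proportional to the target codon
# frequency pi_j, multiplied by kappa for transitions and by omega for
# nonsynonymous changes. Q is normalised so that at omega = 1 the mean rate
# is one expected substitution per codon site per unit branch length, which
# anchors branch lengths to the synonymous (neutral) clock regardless of the
# site's omega.

LOG_FLOOR <- -745  # log of the smallest subnormal double; floor for log(0)

#' Codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Gene-wide nonsynonymous/synonymous rate ratio (>= 0).
#' @param rho Tree scale multiplier applied to all branch lengths (>= 0).
#' @param pi Equilibrium frequencies over the 61 sense codons (sums to 1).
#' @return Object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega, rho, pi) {
  stopifnot(kappa > 0, omega >= 0, rho >= 0, length(pi) == 61L,
            all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  structure(list(kappa = kappa, omega = omega, rho = rho, pi = pi),
            class = "codon_model_params")
}

#' @export
print.codon_model_params <- function(x, ...) {
  cat(sprintf("codon model: kappa = %.4g, omega_g = %.4g, rho = %.4g\n",
              x$kappa, x$omega, x$rho))
  invisible(x)
}

# Precompute the kappa/pi-dependent parts of Q so that rebuilding Q for a new
# site omega is a cheap matrix add (used heavily by the per-site optimiser).
rate_matrix_parts <- function(pi, kappa) {
  st <- codon_states()
  p <- st$pairs
  A_syn <- A_non <- matrix(0, 61, 61)
  r <- pi[p$j] * ifelse(p$ts, kappa, 1)
  idx <- cbind(p$i, p$j)
  A_syn[idx[p$syn, , drop = FALSE]] <- r[p$syn]
  A_non[idx[!p$syn, , drop = FALSE]] <- r[!p$syn]
  # normaliser: mean rate at omega = 1 equals 1
  scale1 <- sum(pi * rowSums(A_syn + A_non))
  list(A_syn = A_syn, A_non = A_non, scale1 = scale1)
}

#' Build the codon substitution generator
#'
#' @param params A [codon_model_params()] (its `pi` and `kappa` are used).
#' @param omega Nonsynonymous/synonymous rate ratio for this matrix
#'   (defaults to the gene-wide value in `params`).
#' @return 61 x 61 generator matrix Q with zero row sums, normalised so the
#'   expected substitution rate at `omega = 1` is one per codon site per unit
#'   branch length.
#' @export
build_rate_matrix <- function(params, omega = params$omega) {
  pi <- params$pi
  if (any(pi == 0)) {
    stop("build_rate_matrix: degenerate pi (zero equilibrium frequency); ",
         "use a frequency floor when estimating F3x4")
  }
  parts <- rate_matrix_parts(pi, params$kappa)
  Q <- (parts$A_syn + omega * parts$A_non) / parts$scale1
  diag(Q) <- -rowSums(Q)
  Q
}

# Transition probabilities by uniformization (Jensen's method):
# P(t) = sum_k Pois(k; Lambda t) M^k with M = I + Q/Lambda, Lambda the
# largest exit rate. Every term is nonnegative, so small multi-step entries
# are computed with full relative accuracy — an eigendecomposition of the
# reversible-symmetrized generator reconstructs them only to absolute
# machine precision, which is orders of magnitude off in relative terms for
# the improbable transitions that dominate rare-configuration likelihoods.
# Powers of M are cached inside the object and shared across the branches
# of a tree (all branches use the same generator at a given omega).
decompose_generator <- function(Q, pi) {
  Lambda <- max(-diag(Q))
  M <- Q / max(Lambda, .Machine$double.xmin)
  diag(M) <- diag(M) + 1
  e <- new.env(parent = emptyenv())
  e$pow <- list(diag(61L), M)  # M^0, M^1
  list(Lambda = Lambda, M = M, cache = e)
}

# number of series terms for a Poisson tail below ~1e-16
unif_terms <- function(qt) {
  as.integer(ceiling(qt + 10 * sqrt(qt) + 10))
}

m_power <- function(dec, k) {
  pow <- dec$cache$pow
  while (length(pow) < k + 1L) {
    pow[[length(pow) + 1L]] <- pow[[length(pow)]] %*% dec$M
  }
  dec$cache$pow <- pow
  pow[[k + 1L]]
}

# Transition probability matrix P(t); P(0) is the exact identity.
prob_matrix <- function(dec, t) {
  if (t == 0 || dec$Lambda == 0) return(diag(61L))
  qt <- dec$Lambda * t
  K <- unif_terms(qt)
  w <- stats::dpois(0:K, qt)
  m_power(dec, K)  # ensure cache depth
  P <- matrix(0, 61L, 61L)
  for (k in 0:K) P <- P + w[k + 1L] * dec$cache$pow[[k + 1L]]
  P
}

# Apply P(t) to a partial-likelihood matrix V (61 x S) without forming P.
apply_prob <- function(dec, t, V) {
  if (t == 0 || dec$Lambda == 0) return(V)
  qt <- dec$Lambda * t
  K <- unif_terms(qt)
  w <- stats::dpois(0:K, qt)
  W <- w[1L] * V
  Mk <- V
  for (k in 1:K) {
    Mk <- dec$M %*% Mk
    W <- W + w[k + 1L] * Mk
  }
  W
}

# Edge table in postorder for pruning; cached per tree by the caller.
tree_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length,
       ntip = length(tr$tip.label), tips = tr$tip.label,
       root = length(tr$tip.label) + 1L)
}

# Felsenstein pruning over all sites at once.
# states: taxa x S integer matrix of codon states (NA = missing, marginalised
# with all-ones partials); taxa order must match po$tips.
# Returns the per-site log-likelihood vector (floored at LOG_FLOOR).
prune_loglik <- function(po, dec, rho, states, pi) {
  S <- ncol(states)
  nnode <- po$ntip + po$ntip  # upper bound on node ids (tips + internals)
  partial <- vector("list", 2L * po$ntip)
  scaler <- matrix(0, 2L * po$ntip, S)
  tip_state <- states  # rows follow po$tips
  edges <- po$edge
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1L]; child <- edges[k, 2L]
    t_e <- po$length[k] * rho
    if (child <= po$ntip) {
      s <- tip_state[child, ]
      V <- matrix(0, 61L, S)
      ok <- !is.na(s)
      V[cbind(s[ok], which(ok))] <- 1
      V[, !ok] <- 1  # missing taxon: marginalised
      child_scaler <- numeric(S)
    } else {
      V <- partial[[child]]
      child_scaler <- scaler[child, ]
    }
    # forming P explicitly wins once many sites share the edge
    W <- if (S >= 32L) prob_matrix(dec, t_e) %*% V else apply_prob(dec, t_e, V)
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- W
      scaler[parent, ] <- child_scaler
    } else {
      partial[[parent]] <- partial[[parent]] * W
      scaler[parent, ] <- scaler[parent, ] + child_scaler
      # rescale to avoid underflow
      m <- apply(partial[[parent]], 2L, max)
      pos <- m > 0 & m < 1e-100
      if (any(pos)) {
        partial[[parent]][, pos] <-
          partial[[parent]][, pos] / rep(m[pos], each = 61L)
        scaler[parent, pos] <- scaler[parent, pos] + log(m[pos])
      }
    }
  }
  lik <- as.vector(pi %*% partial[[po$root]])
  ll <- ifelse(lik > 0, log(lik) + scaler[po$root, ], -Inf)
  pmax(ll, LOG_FLOOR)
}

# Convenience: align a codon_alignment's state matrix to a tree's tip order,
# treating tree tips absent from the alignment (and excluded taxa) as
# missing. Errors if the alignment has taxa the tree lacks.
states_for_tree <- function(aln, po, exclude = character(0)) {
  extra <- setdiff(aln$taxa, po$tips)
  if (length(extra) > 0)
    stop("alignment taxa absent from tree: ", paste(extra, collapse = ", "))
  S <- aln$n_codons
  m <- matrix(NA_integer_, length(po$tips), S)
  keep <- setdiff(intersect(aln$taxa, po$tips), exclude)
  m[match(keep, po$tips), ] <- aln$states[keep, , drop = FALSE]
  m
}

#' Log-likelihood of one codon column under the site model
#'
#' Felsenstein-pruning likelihood of a single codon column on a fixed tree,
#' with missing taxa marginalised and an optional exclusion set (used to mask
#' the query taxon against reference bias).
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` tree whose tip set covers the alignment taxa.
#' @param params A [codon_model_params()].
#' @param omega Site omega at which to evaluate.
#' @param codon_index 0-based codon column index.
#' @param exclude Character vector of taxa to treat as missing.
#' @return Log-likelihood (floored at the configured log-floor).
#' @export
site_log_likelihood <- function(aln, tree, params, omega, codon_index,
                                exclude = character(0)) {
  validate_tree(tree)
  if (codon_index < 0 || codon_index >= aln$n_codons)
    stop("site_log_likelihood: codon index out of range")
  po <- tree_postorder(tree)
  states <- states_for_tree(aln, po, exclude)[, codon_index + 1L, drop = FALSE]
  if (all(is.na(states)))
    stop("site_log_likelihood: all taxa missing at codon ", codon_index)
  Q <- build_rate_matrix(params, omega)
  dec <- decompose_generator(Q, params$pi)
  prune_loglik(po, dec, params$rho, states, params$pi)
}

#' F3x4 codon equilibrium frequencies from an alignment
#'
#' Position-specific nucleotide frequencies over the non-missing codons of
#' the non-excluded taxa, multiplied across the three codon positions and
#' renormalised over the 61 sense codons. Position frequencies are floored at
#' `floor` (then renormalised) so no sense codon gets an exactly zero
#' equilibrium frequency, which would make the generator irreducible.
#'
#' @param aln A [codon_alignment()].
#' @param exclude Taxa to leave out (typically the query).
#' @param floor Minimum per-position nucleotide frequency.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln, exclude = character(0), floor = 1e-3) {
  st <- codon_states()
  keep <- setdiff(aln$taxa, exclude)
  states <- aln$states[keep, , drop = FALSE]
  obs <- states[!is.na(states)]
  if (length(obs) == 0) stop("f3x4_frequencies: no observed codons")
  f <- matrix(0, 3, 4)
  for (p in 1:3) {
    tab <- tabulate(st$nt[obs, p], nbins = 4L)
    fr <- tab / sum(tab)
    fr <- pmax(fr, floor)
    f[p, ] <- fr / sum(fr)
  }
  pi <- f[1, st$nt[, 1]] * f[2, st$nt[, 2]] * f[3, st$nt[, 3]]
  pi / sum(pi)
}
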