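# Shared oracles: random model parameterizations and the exhaustive
# internal-state enumeration likelihood (independent of the pruning path).

random_params <- function(seed) {
  delscan:::with_seed(seed, {
    # frequencies bounded away from zero: near-zero pi makes the reversible
    # symmetrization ill-conditioned and is excluded by the F3x4 floor anyway
    pi <- pmax(as.vector(stats::rexp(61)), 0.15); pi <- pi / sum(pi)
    codon_model_params(kappa = stats::runif(1, 0.5, 5),
                       omega = stats::runif(1, 0.05, 2),
                       rho = stats::runif(1, 0.5, 2), pi = pi)
  })
}

# Exhaustive-likelihood oracle: sum over all internal-node state
# assignments, transition probabilities from Matrix::expm (an algorithm
# independent of the package's eigendecomposition path).
brute_force_loglik <- function(tree, params, omega, states) {
  Q <- build_rate_matrix(params, omega)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    as.matrix(Matrix::expm(Q * tree$edge.length[k] * params$rho)))
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  colnames(grid) <- as.character(internal)
  lik <- params$pi[grid[, as.character(ntip + 1L)]]  # root prior
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
    ps <- grid[, as.character(par)]
    if (chd <= ntip) {
      s <- states[tree$tip.label[chd]]
      if (is.na(s)) next  # missing tip marginalises to 1
      lik <- lik * P[[k]][cbind(ps, s)]
    } else {
      lik <- lik * P[[k]][cbind(ps, grid[, as.character(chd)])]
    }
  }
  log(sum(lik))
}
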