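# Gene-level model fitting and the per-codon likelihood-ratio test of
# selective constraint.
#
# Anchoring strategy: (kappa, omega_g, rho) are estimated once per gene over
# all codon columns with the query taxon excluded; the per-site test then
# holds branch lengths, kappa and pi fixed and varies only the site's omega.
# The null fixes site omega = 1 (neutral evolution); the alternative
# maximises it over [omega_min, omega_max]. Because omega = 1 is interior to
# that interval, the LRT statistic is asymptotically chi-square with one
# degree of freedom; a boundary-mixture null (for a constrained alternative)
# is available behind `null = "mixture"`.

OMEGA_BOUNDS <- c(1e-4, 10)

#' Fit gene-wide codon model parameters
#'
#' Estimates kappa (transition/transversion ratio), omega_g (gene-wide
#' dN/dS) and rho (tree scale) by maximum likelihood over all codon columns,
#' with equilibrium frequencies fixed at their F3x4 empirical estimates. The
#' query taxon is excluded throughout (reference masking). Optimisation is
#' bounded quasi-Newton (L-BFGS-B) on log-parameters with three deterministic
#' restarts.
#'
#' @param aln A [codon_alignment()].
#' @param tree A `phylo` tree covering the alignment taxa; branch lengths in
#'   expected substitutions per codon site at neutrality.
#' @param min_taxa Minimum informative non-query taxa (default 3).
#' @param min_codons Minimum codon columns (default 10).
#' @param exclude_query Mask the query taxon from the fit (default TRUE).
#' @return A [codon_model_params()] with extra fields `logLik`, `converged`,
#'   `n_taxa`, `n_codons`.
#' @export
fit_gene_model <- function(aln, tree, min_taxa = 3L, min_codons = 10L,
                           exclude_query = TRUE) {
  validate_tree(tree)
  exclude <- if (exclude_query) aln$query else character(0)
  po <- tree_postorder(tree)
  states <- states_for_tree(aln, po, exclude)
  inf_taxa <- sum(rowSums(!is.na(states)) > 0)
  if (inf_taxa < min_taxa)
    stop("fit_gene_model: need >= ", min_taxa, " informative taxa, have ",
         inf_taxa)
  if (aln$n_codons < min_codons)
    stop("fit_gene_model: need >= ", min_codons, " codon columns, have ",
         aln$n_codons)
  pi <- f3x4_frequencies(aln, exclude = exclude)
  negll <- function(par) {
    kappa <- exp(par[1]); omega <- exp(par[2]); rho <- exp(par[3])
    parts <- rate_matrix_parts(pi, kappa)
    Q <- (parts$A_syn + omega * parts$A_non) / parts$scale1
    diag(Q) <- -rowSums(Q)
    dec <- decompose_generator(Q, pi)
    -sum(prune_loglik(po, dec, rho, states, pi))
  }
  lower <- log(c(0.05, OMEGA_BOUNDS[1], 1e-4))
  upper <- log(c(100, OMEGA_BOUNDS[2], 100))
  starts <- list(log(c(2, 0.5, 1)), log(c(1, 1, 0.5)), log(c(4, 0.2, 2)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$convergence == 0) break  # further restarts only on failure
  }
  if (is.null(best)) stop("fit_gene_model: optimisation failed from all starts")
  converged <- best$convergence == 0
  if (!converged) {
    cond <- simpleError("fit_gene_model: optimiser did not converge")
    cond$best <- best
    stop(cond)
  }
  out <- codon_model_params(kappa = exp(best$par[1]), omega = exp(best$par[2]),
                            rho = exp(best$par[3]), pi = pi)
  out$logLik <- -best$value
  out$converged <- converged
  out$n_taxa <- inf_taxa
  out$n_codons <- aln$n_codons
  out
}

# Cached per-gene context for repeated site tests: postorder edges, masked
# state matrix, kappa/pi rate-matrix parts, and the omega = 1 decomposition.
site_test_context <- function(aln, tree, params, exclude_query = TRUE) {
  po <- tree_postorder(tree)
  exclude <- if (exclude_query) aln$query else character(0)
  states <- states_for_tree(aln, po, exclude)
  parts <- rate_matrix_parts(params$pi, params$kappa)
  Q1 <- (parts$A_syn + parts$A_non) / parts$scale1
  diag(Q1) <- -rowSums(Q1)
  list(po = po, states = states, parts = parts,
       dec1 = decompose_generator(Q1, params$pi), pi = params$pi,
       rho = params$rho)
}

context_loglik <- function(ctx, omega, cols) {
  if (omega == 1) {
    dec <- ctx$dec1
  } else {
    Q <- (ctx$parts$A_syn + omega * ctx$parts$A_non) / ctx$parts$scale1
    diag(Q) <- -rowSums(Q)
    dec <- decompose_generator(Q, ctx$pi)
  }
  prune_loglik(ctx$po, dec, ctx$rho, ctx$states[, cols, drop = FALSE], ctx$pi)
}

#' Likelihood-ratio test of selective constraint at one codon
#'
#' Compares neutral evolution (site omega fixed at 1) against a free site
#' omega, with the query taxon masked from both likelihoods. Codons with
#' fewer informative non-query species than `min_species` are reported as
#' untested.
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` tree.
#' @param params Gene-level [codon_model_params()] from [fit_gene_model()].
#' @param codon_index 0-based codon column.
#' @param min_species Minimum informative non-query species (default 10,
#'   the standard calling rule for this test).
#' @param null `"chisq1"` (two-sided chi-square df = 1, default) or
#'   `"mixture"` (boundary mixture 0.5 chi0 + 0.5 chi1).
#' @param ctx Optional precomputed context (internal; built if missing).
#' @return One-row data.frame: `codon_index`, `n_species`, `lnL0`, `lnL1`,
#'   `omega_hat`, `D`, `p_value`, `verdict` ("tested"/"untested").
#' @export
test_site <- function(aln, tree, params, codon_index, min_species = 10L,
                      null = c("chisq1", "mixture"), ctx = NULL) {
  null <- match.arg(null)
  if (is.null(params$logLik) || is.null(params$converged))
    stop("test_site: params must come from fit_gene_model()")
  if (is.null(ctx)) ctx <- site_test_context(aln, tree, params)
  col <- codon_index + 1L
  if (col < 1L || col > ncol(ctx$states))
    stop("test_site: codon index out of range")
  n_inf <- sum(!is.na(ctx$states[, col]))
  res <- data.frame(codon_index = codon_index, n_species = n_inf,
                    lnL0 = NA_real_, lnL1 = NA_real_, omega_hat = NA_real_,
                    D = NA_real_, p_value = NA_real_, verdict = "untested",
                    stringsAsFactors = FALSE)
  if (n_inf < min_species) return(res)
  lnL0 <- context_loglik(ctx, 1, col)
  f <- function(lw) -context_loglik(ctx, exp(lw), col)
  opt <- stats::optimize(f, interval = log(OMEGA_BOUNDS), tol = 1e-4)
  lnL1 <- -opt$objective
  omega_hat <- exp(opt$minimum)
  if (lnL0 >= lnL1) {  # omega = 1 is in the alternative's search set
    lnL1 <- lnL0
    omega_hat <- 1
  }
  D <- max(0, 2 * (lnL1 - lnL0))
  p <- if (null == "chisq1") {
    stats::pchisq(D, df = 1, lower.tail = FALSE)
  } else {
    if (D <= 0) 1 else 0.5 * stats::pchisq(D, df = 1, lower.tail = FALSE)
  }
  res$lnL0 <- lnL0; res$lnL1 <- lnL1; res$omega_hat <- omega_hat
  res$D <- D; res$p_value <- p; res$verdict <- "tested"
  res
}

#' Allele novelty against the comparative species
#'
#' TRUE when either the reference or the alternate base is absent from every
#' non-query species at the aligned nucleotide column: the derived change is
#' then novel relative to the cross-species sample, one of the requirements
#' for a deleterious call.
#'
#' @param aln A [codon_alignment()].
#' @param nt_column 1-based nucleotide column within the alignment.
#' @param ref_base,alt_base The two alleles (single bases).
#' @return Logical flag; if no non-query taxon is informative at the column
#'   the result is TRUE with a low-information warning.
#' @export
allele_novelty <- function(aln, nt_column, ref_base, alt_base) {
  if (nt_column < 1L || nt_column > ncol(aln$nt))
    stop("allele_novelty: column outside alignment")
  others <- setdiff(aln$taxa, aln$query)
  obs <- aln$nt[others, nt_column]
  obs <- obs[obs %in% c("A", "C", "G", "T")]
  if (length(obs) == 0) {
    warning("allele_novelty: no informative comparative states; ",
            "novelty is vacuously TRUE")
    return(TRUE)
  }
  !(toupper(ref_base) %in% obs) || !(toupper(alt_base) %in% obs)
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of tested codons in the run (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 59277)  # 8.4e-7
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("bonferroni_threshold: alpha must be in (0, 1)")
  if (n_tests < 1) stop("bonferroni_threshold: n_tests must be >= 1")
  alpha / n_tests
}

#' Deleterious call from a site test result
#'
#' A site is called deleterious when the LRT p-value beats the Bonferroni
#' threshold, the allele is novel relative to the comparative species, and
#' the fitted site omega indicates constraint (< 1); otherwise tolerated.
#' Untested sites pass through unchanged.
#'
#' @param result One-row data.frame from [test_site()], with a logical
#'   `novel` column added by the caller.
#' @param threshold Per-test p-value threshold (see
#'   [bonferroni_threshold()]).
#' @return `"deleterious"`, `"tolerated"` or `"untested"`.
#' @export
call_deleterious <- function(result, threshold) {
  if (result$verdict == "untested") return("untested")
  if (is.null(result$novel) || is.na(result$novel))
    stop("call_deleterious: result lacks the novelty flag")
  if (result$p_value < threshold && result$novel && result$omega_hat < 1)
    "deleterious" else "tolerated"
}

# ---- the flagship scan -------------------------------------------------

#' Scan a codon alignment for selectively constrained codons
#'
#' The package's central fitting function: fits the gene-wide codon model,
#' then applies the per-codon likelihood-ratio test of constraint to every
#' codon column (or a subset), with the query taxon masked. Returns a classed
#' object with `print`, `summary`, `coef`, `logLik`, `plot`, `simulate` and
#' `as.data.frame` methods.
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` tree whose tips cover the alignment taxa.
#' @param codons 0-based codon indices to test (default: all).
#' @param min_species Minimum informative non-query species per codon
#'   (default 10).
#' @param alpha Family-wise error level for the Bonferroni threshold
#'   (default 0.05).
#' @param bonferroni_n Number of tests for the threshold; defaults to the
#'   number of codons actually tested in this scan. Pass the run-wide count
#'   when scanning many genes.
#' @param null Null distribution for the LRT, see [test_site()].
#' @param exclude_query Mask the query taxon (default TRUE).
#' @return Object of class `constraint_scan`.
#' @export
constraint_scan <- function(aln, tree, codons = NULL, min_species = 10L,
                            alpha = 0.05, bonferroni_n = NULL,
                            null = c("chisq1", "mixture"),
                            exclude_query = TRUE) {
  null <- match.arg(null)
  params <- fit_gene_model(aln, tree, exclude_query = exclude_query)
  ctx <- site_test_context(aln, tree, params, exclude_query = exclude_query)
  if (is.null(codons)) codons <- seq_len(aln$n_codons) - 1L
  rows <- lapply(codons, function(ci) {
    test_site(aln, tree, params, ci, min_species = min_species, null = null,
              ctx = ctx)
  })
  sites <- do.call(rbind, rows)
  n_tested <- sum(sites$verdict == "tested")
  thr <- if (n_tested > 0) {
    bonferroni_threshold(alpha, bonferroni_n %||% n_tested)
  } else NA_real_
  structure(list(params = params, sites = sites, alpha = alpha,
                 threshold = thr, n_tested = n_tested,
                 min_species = min_species, null = null,
                 query = aln$query, tree = tree, aln = aln),
            class = "constraint_scan")
}

#' @export
print.constraint_scan <- function(x, ...) {
  cat("Per-codon constraint scan (codon-model LRT)\n")
  cat(sprintf("  query taxon: %s (masked)\n", x$query))
  cat(sprintf("  gene model: kappa = %.3g, omega_g = %.3g, rho = %.3g, lnL = %.2f\n",
              x$params$kappa, x$params$omega, x$params$rho, x$params$logLik))
  cat(sprintf("  codons: %d scanned, %d tested (>= %d species), threshold %.3g\n",
              nrow(x$sites), x$n_tested, x$min_species, x$threshold))
  sig <- sum(x$sites$p_value < x$threshold, na.rm = TRUE)
  cat(sprintf("  constrained at Bonferroni level %.2g: %d codon(s)\n",
              x$alpha, sig))
  invisible(x)
}

#' @export
summary.constraint_scan <- function(object, ...) {
  s <- object$sites
  tested <- s[s$verdict == "tested", , drop = FALSE]
  out <- list(params = object$params, n_codons = nrow(s),
              n_tested = nrow(tested), threshold = object$threshold,
              n_significant = sum(tested$p_value < object$threshold),
              omega_quartiles = stats::quantile(tested$omega_hat,
                                                c(0.25, 0.5, 0.75),
                                                na.rm = TRUE),
              min_p = suppressWarnings(min(tested$p_value)))
  class(out) <- "summary.constraint_scan"
  out
}

#' @export
print.summary.constraint_scan <- function(x, ...) {
  print(x$params)
  cat(sprintf("codons tested: %d of %d; Bonferroni threshold %.3g\n",
              x$n_tested, x$n_codons, x$threshold))
  cat(sprintf("significant (constrained): %d; smallest p = %.3g\n",
              x$n_significant, x$min_p))
  cat("site omega quartiles:",
      paste(signif(x$omega_quartiles, 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.constraint_scan <- function(object, ...) {
  c(kappa = object$params$kappa, omega_g = object$params$omega,
    rho = object$params$rho)
}

#' @export
logLik.constraint_scan <- function(object, ...) {
  structure(object$params$logLik, df = 3L, class = "logLik")
}

#' @export
as.data.frame.constraint_scan <- function(x, ...) x$sites

#' @export
plot.constraint_scan <- function(x, ...) {
  s <- x$sites[x$sites$verdict == "tested", , drop = FALSE]
  graphics::plot(s$codon_index, -log10(s$p_value), pch = 16, cex = 0.6,
                 xlab = "codon index", ylab = expression(-log[10] ~ p),
                 main = "Per-codon constraint LRT", ...)
  if (is.finite(x$threshold))
    graphics::abline(h = -log10(x$threshold), lty = 2, col = "red3")
  invisible(x)
}

#' Parametric bootstrap from a fitted scan
#'
#' Simulates codon alignments on the scan's tree under the fitted gene-wide
#' parameters (every site at omega_g), mirroring the observed taxon set.
#'
#' @param object A `constraint_scan`.
#' @param nsim Number of alignments.
#' @param seed Seed fixing all randomness.
#' @param ... Unused.
#' @return List of [codon_alignment()] objects.
#' @export
simulate.constraint_scan <- function(object, nsim = 1, seed = NULL, ...) {
  spec <- simulation_spec(tree = object$tree, kappa = object$params$kappa,
                          pi = object$params$pi,
                          omega = rep(object$params$omega,
                                      object$aln$n_codons),
                          seed = seed %||% 1L)
  lapply(seq_len(nsim), function(k) {
    sp <- spec; sp$seed <- child_seed(spec$seed, k)
    simulate_alignment(sp, query = object$query)
  })
}
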