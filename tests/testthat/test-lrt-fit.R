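# Gene-model fitting, per-site LRT mechanics, masking, novelty, thresholds
# and the deleterious call rule.

test_that("identical sequences drive the tree scale to its lower bound", {
  tr <- balanced_tree(8, total_len = 1.6)
  seq <- strrep("ATGGGTACC", 5)  # 15 identical codons... enough columns
  seqs <- stats::setNames(rep(seq, 8), tr$tip.label)
  aln <- codon_alignment(seqs, tr$tip.label[1])
  fit <- fit_gene_model(aln, tr)
  expect_lt(fit$rho, 2e-4)  # at/near the lower bound: no substitutions
})

test_that("fit preconditions: too few taxa or codons error", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  aln <- random_aln(c("A", "B"), 20, seed = 1)
  expect_error(fit_gene_model(aln, tr), "informative taxa")
  tr8 <- balanced_tree(8)
  aln_short <- random_aln(tr8$tip.label, 5, seed = 2)
  expect_error(fit_gene_model(aln_short, tr8), "codon columns")
})

test_that("nesting: alternative likelihood never falls below the null", {
  tr <- balanced_tree(16, total_len = 4)
  spec <- simulation_spec(tr, kappa = 2,
                          omega = rep(c(0.1, 1, 5), each = 15), seed = 31)
  aln <- simulate_alignment(spec)
  fit <- fit_gene_model(aln, tr)
  ctx <- delscan:::site_test_context(aln, tr, fit)
  for (ci in seq_len(aln$n_codons) - 1L) {
    r <- test_site(aln, tr, fit, ci, min_species = 10, ctx = ctx)
    if (r$verdict != "tested") next
    expect_gte(r$lnL1, r$lnL0 - 1e-9)
    expect_gte(r$D, 0)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("tested/untested follows the minimum-species rule", {
  tr <- balanced_tree(16, total_len = 4)
  aln <- simulate_alignment(simulation_spec(tr, 2, rep(0.5, 12), seed = 7))
  fit <- fit_gene_model(aln, tr)
  # knock a column down to 9 informative non-query species
  nt <- apply(aln$nt, 1, paste, collapse = "")
  drop <- setdiff(aln$taxa, aln$query)[1:6]
  for (t in drop) substr(nt[t], 1, 3) <- "---"
  aln2 <- codon_alignment(nt, aln$query)
  r <- test_site(aln2, tr, fit, 0, min_species = 10,
                 ctx = delscan:::site_test_context(aln2, tr, fit))
  expect_equal(r$n_species, 9L)
  expect_equal(r$verdict, "untested")
  r2 <- test_site(aln2, tr, fit, 1, min_species = 10,
                  ctx = delscan:::site_test_context(aln2, tr, fit))
  expect_equal(r2$verdict, "tested")
})

test_that("a perfectly conserved codon on a long tree is called constrained", {
  tr <- balanced_tree(20, total_len = 5)
  spec <- simulation_spec(tr, kappa = 2, omega = rep(1, 60), seed = 13)
  aln <- simulate_alignment(spec)
  # overwrite column 0 with an invariant codon across all taxa
  nt <- apply(aln$nt, 1, paste, collapse = "")
  for (t in aln$taxa) substr(nt[t], 1, 3) <- "ATG"
  aln <- codon_alignment(nt, aln$query)
  fit <- fit_gene_model(aln, tr)
  r <- test_site(aln, tr, fit, 0, ctx = delscan:::site_test_context(aln, tr, fit))
  expect_lt(r$omega_hat, 0.1)
  expect_gt(r$D, 0)
  # grid-search oracle over omega confirms the optimum the solver found
  grid <- exp(seq(log(1e-4), log(10), length.out = 60))
  ctx <- delscan:::site_test_context(aln, tr, fit)
  ll_grid <- vapply(grid, function(w) delscan:::context_loglik(ctx, w, 1),
                    numeric(1))
  expect_gte(r$lnL1 + 1e-6, max(ll_grid))
})

test_that("zero-length tree collapses the test: D = 0, p = 1", {
  tr <- balanced_tree(12, total_len = 4)
  aln <- simulate_alignment(simulation_spec(tr, 2, rep(1, 12), seed = 3))
  fit <- delscan:::as_fitted_params(
    codon_model_params(2, 1, 0, rep(1 / 61, 61)))  # rho = 0
  r <- test_site(aln, tr, fit, 0, ctx = delscan:::site_test_context(aln, tr, fit))
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
})

test_that("masking: the query never influences other columns, but matters when divergent", {
  tr <- balanced_tree(16, total_len = 4)
  aln <- simulate_alignment(simulation_spec(tr, 2, rep(0.6, 20), seed = 17))
  fit <- fit_gene_model(aln, tr)
  ctx <- delscan:::site_test_context(aln, tr, fit, exclude_query = TRUE)
  base <- vapply(0:19, function(ci)
    test_site(aln, tr, fit, ci, ctx = ctx)$lnL1, numeric(1))
  # mutate the query sequence only; masked results must be identical
  nt <- apply(aln$nt, 1, paste, collapse = "")
  nt[aln$query] <- strrep("ATG", 20)
  aln2 <- codon_alignment(nt, aln$query)
  ctx2 <- delscan:::site_test_context(aln2, tr, fit, exclude_query = TRUE)
  masked <- vapply(0:19, function(ci)
    test_site(aln2, tr, fit, ci, ctx = ctx2)$lnL1, numeric(1))
  expect_equal(masked, base, tolerance = 1e-12)
  # with masking off, the divergent query changes the likelihoods
  ctx3 <- delscan:::site_test_context(aln2, tr, fit, exclude_query = FALSE)
  unmasked <- vapply(0:19, function(ci)
    test_site(aln2, tr, fit, ci, ctx = ctx3)$lnL1, numeric(1))
  expect_gt(max(abs(unmasked - base)), 1e-3)
})

test_that("allele novelty applies the unseen-allele rule", {
  aln <- codon_alignment(c(q = "ATG", a = "ATG", b = "ATG", c = "GTG"), "q")
  # column 1 states among non-query taxa: A, A, G
  expect_true(allele_novelty(aln, 1, ref_base = "A", alt_base = "C"))
  expect_false(allele_novelty(aln, 1, ref_base = "A", alt_base = "G"))
  expect_error(allele_novelty(aln, 99, "A", "C"), "outside")
  gappy <- codon_alignment(c(q = "ATG", a = "---", b = "---"), "q")
  expect_warning(nov <- allele_novelty(gappy, 1, "A", "C"), "vacuously")
  expect_true(nov)
})

test_that("Bonferroni thresholds reproduce the published two-figure values", {
  expect_equal(signif(bonferroni_threshold(0.05, 59277), 2), 8.4e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 64087), 2), 7.8e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("deleterious call requires significance, novelty and constraint", {
  thr <- 8.4e-7
  mk <- function(p, nov, w, verdict = "tested") {
    data.frame(verdict = verdict, p_value = p, novel = nov, omega_hat = w)
  }
  expect_equal(call_deleterious(mk(1e-8, TRUE, 0.01), thr), "deleterious")
  expect_equal(call_deleterious(mk(1e-8, FALSE, 0.01), thr), "tolerated")
  expect_equal(call_deleterious(mk(0.01, TRUE, 0.01), thr), "tolerated")
  expect_equal(call_deleterious(mk(1e-8, TRUE, 5), thr), "tolerated")
  expect_equal(call_deleterious(mk(NA, NA, NA, "untested"), thr), "untested")
})

test_that("constraint_scan returns a coherent classed fit with methods", {
  tr <- balanced_tree(16, total_len = 4)
  spec <- simulation_spec(tr, 2, omega = c(rep(0.05, 5), rep(1, 10)),
                          seed = 23)
  aln <- simulate_alignment(spec)
  scan <- constraint_scan(aln, tr, min_species = 10)
  expect_s3_class(scan, "constraint_scan")
  expect_equal(nrow(scan$sites), 15L)
  expect_equal(scan$threshold, 0.05 / scan$n_tested)
  co <- coef(scan)
  expect_named(co, c("kappa", "omega_g", "rho"))
  expect_output(print(scan), "constraint scan")
  expect_output(print(summary(scan)), "Bonferroni")
  df <- as.data.frame(scan)
  expect_equal(df, scan$sites)
  sims <- simulate(scan, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$n_codons, 15L)
  # determinism of the parametric bootstrap
  sims2 <- simulate(scan, nsim = 2, seed = 9)
  expect_identical(sims[[1]]$nt, sims2[[1]]$nt)
})
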