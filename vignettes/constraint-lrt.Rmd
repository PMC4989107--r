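---
title: "Calling deleterious variants with a per-codon constraint LRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling deleterious variants with a per-codon constraint LRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delscan)
```

## The problem

Resequencing panels of crop accessions segregate thousands of nonsynonymous
SNPs, a small fraction of which damage protein function and reduce fitness.
delscan operationalises "deleterious" the way comparative genomics does: a
nonsynonymous change at a codon that has been under purifying selection
across a deep species phylogeny is likely to be harmful. The package takes
variant calls (VCF), gene models (GFF3 + genome FASTA), precomputed
per-gene codon alignments across many species (FASTA) with a fixed
phylogeny (Newick), and external SIFT-like / PolyPhen2-like verdict tables,
and produces per-codon constraint tests, deleterious calls, and the
population summaries built on them (derived site frequency spectra,
per-accession burdens, recombination-rate overlays).

## The model

Codon evolution is modelled with a Goldman–Yang style substitution process
on the 61 sense codons. The generator Q has rate zero between codons
differing at more than one nucleotide; for single-nucleotide neighbours

$$ q_{ij} \propto \pi_j \cdot \kappa^{[\text{transition}]} \cdot
   \omega^{[\text{nonsynonymous}]} $$

with codon equilibrium frequencies $\pi$ (F3x4: position-specific
nucleotide frequencies multiplied and renormalised over sense codons),
transition/transversion ratio $\kappa$, and dN/dS ratio $\omega$. Q is
normalised so that at $\omega = 1$ the mean rate is one expected
substitution per codon site per unit branch length; branch lengths are
therefore anchored to the synonymous (neutral) clock and the same tree is
reused at every $\omega$.

Per gene, `fit_gene_model()` estimates $(\kappa, \omega_g, \rho)$ — $\rho$
a gene-level rescaling of the fixed tree — by maximum likelihood over all
codon columns, with the query species excluded. This is what ties each
site's test to the gene's local synonymous substitution rate: a slow gene
(small $\rho$) needs stronger conservation signal before a site looks
constrained.

Per codon, `test_site()` compares

* H0: site $\omega = 1$ (neutral evolution), against
* H1: site $\omega$ free in $[10^{-4}, 10]$,

holding $\kappa$, $\pi$, $\rho$ and the branch lengths at their gene-level
values. Likelihoods come from Felsenstein pruning with missing codons
marginalised. The statistic $D = 2(\ln L_1 - \ln L_0)$ is referred to
$\chi^2_1$ (two-sided: $\omega = 1$ is interior to the alternative's
interval, so the standard asymptotics apply; a boundary-mixture null
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ is available via `null = "mixture"`
for users who restrict the alternative a priori).

A variant is called deleterious (`call_deleterious()`) when all three hold:

1. the site's p-value beats the Bonferroni threshold $\alpha/n$, with $n$
   the number of codons actually tested in the run (at $\alpha = 0.05$ this
   reproduces the familiar thresholds 8.4e-7 for 59,277 tests and 7.8e-7
   for 64,087);
2. the reference or alternate allele is absent from every comparative
   species at the aligned column (`allele_novelty()`);
3. the fitted site $\omega < 1$ (constraint, not acceleration).

At the pipeline level the stricter consensus definition applies: a
nonsynonymous variant is consensus-deleterious only when SIFT-like,
PolyPhen2-like and the LRT all say deleterious (`consensus_call()`);
variants missing any method are reported as "untestable", never silently
counted as tolerated.

## Reference masking and polarization

The query species' sequence is excluded from both the gene fit and the site
likelihoods, and from the novelty rule. Reference bias otherwise depresses
deleterious calls in accessions resembling the reference genotype: a
derived allele fixed into the reference would look like a cross-species
state. The same concern motivates polarizing variants to ancestral/derived
rather than reference/alternate: `infer_ancestral()` takes the
strict-majority state among the informative taxa of a designated outgroup
clade (ties and uninformative columns yield unknown, and such variants
never enter a spectrum). We use an unweighted majority; a
phylogenetically weighted vote would be a reasonable alternative but adds a
dependency on branch-length trust that the simple rule avoids. Only coding
variants are polarized — outgroup alignment outside CDS is not reliable
enough for ancestral inference. Heterozygotes contribute one derived allele
to counts, matching allele-based (unfolded) frequency spectra.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `min_species` | 10 | minimum informative non-query species per codon; below this the codon is reported untested rather than weakly tested |
| `alpha` | 0.05 | family-wise level before Bonferroni division by codons tested |
| $\omega$ bounds | $[10^{-4}, 10]$ | keeps the generator non-degenerate and the alternative's optimum finite |
| F3x4 floor | $10^{-3}$ per position | no sense codon gets zero equilibrium frequency, which would make Q reducible and the reversible symmetrization singular |
| optimizer | L-BFGS-B on log-parameters | bounded quasi-Newton; up to three deterministic restarts, later restarts only fired when an earlier one fails to converge |
| site optimizer | golden-section/Brent on $\log\omega$, tol $10^{-4}$ | the lnL error is quadratic in the $\log\omega$ error, so D is resolved far below the calling thresholds |
| log floor | $-745$ | $\log$ of the smallest subnormal double; impossible configurations (e.g. conflicting states on a zero-length tree) floor here instead of $-\infty$ |

## Numerical choices

Transition probabilities are computed by uniformization (Jensen's method):
$P(t) = \sum_k \text{Pois}(k; \Lambda t)\, M^k$ with $M = I + Q/\Lambda$,
the series truncated when the Poisson tail falls below $10^{-16}$. Every
term is nonnegative, so even tiny multi-step transition probabilities are
obtained with full relative accuracy; an eigendecomposition of the
reversible-symmetrized generator — the obvious alternative — reconstructs
those entries only to absolute machine precision, which costs several
digits exactly where rare-configuration likelihoods need them. Powers of
$M$ are cached and shared across the branches of a tree; when a single
column is evaluated the series is applied directly to the partial vector
(matrix–vector products only), and $P(t)$ is formed explicitly only when
many columns share an edge. $P(0)$ is the exact identity.
Pruning rescales partials per node when column maxima fall below
$10^{-100}$. Per-site likelihoods are floored at the log of the smallest
subnormal double. The site alternative always includes $\omega = 1$ in its
comparison set, so $D \ge 0$ by construction.

## What the simulator does and does not emulate

`simulate_alignment()` evolves codon columns down a fixed tree under the
engine's own generator with known per-site $\omega$ — the standard
self-consistency harness for a likelihood method: parameter recovery, null
calibration and power are all measured against planted truth.
`simulate_toy_genome()` plants SNPs of every effect class (both strands,
dual transcripts, intronic and intergenic sites, a stop-loss in a terminal
stop codon) in a miniature genome and emits FASTA/GFF3/VCF plus a truth
table, closing the loop over the readers, the classifier and the
intersection logic.

Neither simulator emulates: alignment error (the pipeline consumes
alignments as given), gene conversion or CpG mutation-rate heterogeneity,
rate variation beyond the site-$\omega$ mechanism, linked selection, or the
demography of real breeding populations. Passing these tests therefore
demonstrates internal correctness of the method, not robustness of the
biology on real data.

## Calibration and its information requirement

`calibration_experiment()` simulates columns at chosen $\omega$ values and
reports rejection rates. Two regimes are built into the validation suite
(20 taxa, $\kappa = 2$, uniform $\pi$): total tree length 2 and total tree
length 5 expected substitutions per codon site. At length 5 the site LRT is
well calibrated at the 5% level. At length 2 — roughly two substitution
opportunities per column — the $\chi^2_1$ asymptotics have not set in and
the test is conservative (empirical size below nominal, the safe
direction); power at stringent Bonferroni thresholds is essentially nil
there because a length-2 tree bounds the achievable statistic. This is a
property of the likelihood-ratio test at low information, not of the
implementation: the same pruning likelihood is verified against exhaustive
internal-state enumeration to $10^{-9}$. Practically: deep, well-sampled
phylogenies (the 37-species scale the method is used at) are what make
per-codon constraint testing powerful.

Calibration experiments evaluate the bare statistic on all simulated taxa;
query masking is a pipeline policy against reference bias and is tested
separately (masked results are invariant to arbitrary query rewrites).

## Problem sizes used in the validation suite

The suite fits genes of 500 codons on 20-taxon trees (50 replicates for
recovery), tests 2,000 null columns for size and 4 x 500 columns for power,
and enumerates all 549 single-base codon changes against an independent
code table. These sizes give binomial standard errors a few times smaller
than the tolerances they are checked against while keeping a full run in
minutes on one CPU.

## Known limitations

* One $\omega$ per site, one $\rho$ per gene: no codon-site rate classes,
  no branch-specific $\omega$.
* The universal nuclear code only (configurable in principle; both target
  crops are nuclear analyses).
* Ancestral inference is majority-rule, not probabilistic reconstruction;
  ambiguous columns are dropped rather than down-weighted.
* The Bonferroni count is codons tested in the current run; combining runs
  requires passing `bonferroni_n` explicitly.
* Grantham scores return the published 1974 integer matrix; the
  composition/polarity/volume formula is exposed separately and agrees to
  rounding everywhere except the historical Asp–Trp entry, which the
  published matrix prints as 181 against a recomputed 190.6. We keep the
  published value because downstream tools and papers compare against it.
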