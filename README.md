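# delscan

Annotation of putatively **deleterious coding variants** in resequencing
panels (built for crop data: many accessions of one species, deep
multi-species alignments of each gene). A variant is treated as a candidate
deleterious mutation when it is nonsynonymous, novel relative to a panel of
diverged species, and hits a codon under measurable purifying selection.

## The method

For each gene, a Goldman–Yang style codon substitution model is fitted to a
multi-species codon alignment on a fixed phylogeny. The generator over the
61 sense codons has

    q_ij ∝ π_j · κ^[transition] · ω^[nonsynonymous]

(single-nucleotide neighbours only), with F3x4 equilibrium frequencies π,
normalised so branch lengths are expected substitutions per codon site at
neutrality. Gene-level parameters (κ, ω_g, tree scale ρ) are estimated by
maximum likelihood with the query species masked (reference-bias control).

Each codon is then tested with a likelihood-ratio test of **selective
constraint versus neutral evolution**: H0 fixes the site's dN/dS at ω = 1,
H1 frees it in [1e-4, 10]; D = 2(lnL1 − lnL0) is referred to χ²(1). Codons
with fewer than 10 informative species are reported untested. A site is
called deleterious when

1. p < α / (number of codons tested)  — Bonferroni; 0.05/59,277 ≈ 8.4e-7,
   0.05/64,087 ≈ 7.8e-7 at the scales this method is used at,
2. the ref or alt allele is absent from all other species at the column,
3. the fitted site ω < 1.

Around the test, the package implements the full pipeline: effect
classification from VCF + GFF3 + FASTA (synonymous / missense / nonsense /
stop-loss, Grantham scores, Ts/Tv), ancestral polarization from a
designated outgroup clade with unfolded site-frequency spectra and
per-accession burdens, consensus with external SIFT-like and
PolyPhen2-like verdict tables (deleterious = all three methods agree on a
nonsynonymous variant), recombination-rate overlays (cM/Mb per genetic-map
interval, Pearson correlation and logistic regression), and a seeded
simulator used for validation.

## Worked example

Simulate a 12-taxon gene alignment in which the first 10 codons are under
strong purifying selection (ω = 0.02) and the rest are neutral, then scan
it:

```r
library(delscan)
library(ape)
tree <- read.tree(text = paste0("(((((query:0.08,sp1:0.08):0.12,sp2:0.2):0.2,",
  "(sp3:0.2,sp4:0.2):0.2):0.3,(sp5:0.3,sp6:0.3):0.4):0.3,",
  "((sp7:0.25,sp8:0.25):0.35,(sp9:0.3,(sp10:0.2,sp11:0.2):0.1):0.3):0.4);"))
tree$edge.length <- tree$edge.length * 1.8
spec <- simulation_spec(tree, kappa = 2,
                        omega = c(rep(0.02, 10), rep(1, 40)), seed = 7)
aln <- simulate_alignment(spec, query = "query")
scan <- constraint_scan(aln, tree, min_species = 10)
print(scan)
#> Per-codon constraint scan (codon-model LRT)
#>   query taxon: query (masked)
#>   gene model: kappa = 1.62, omega_g = 0.605, rho = 1.08, lnL = -1350.07
#>   codons: 50 scanned, 50 tested (>= 10 species), threshold 0.001
#>   constrained at Bonferroni level 0.05: 9 codon(s)
head(as.data.frame(scan), 3)
#>   codon_index n_species      lnL0      lnL1    omega_hat        D      p_value
#> 1           0        11 -18.82195 -10.48924 0.0001000044 16.66542 4.458638e-05
#> 2           1        11 -21.73314 -15.07152 0.0001000044 13.32323 2.621381e-04
#> 3           2        11 -20.90547 -13.97310 0.0001000044 13.86473 1.964505e-04
```

The scan fits the gene model (κ̂ = 1.62 against a truth of 2, within noise
for a single 50-codon gene; ω_g is pulled toward 1 by the 40 neutral
codons), then tests each codon: the planted constrained codons show site
ω̂ at the lower bound and small p-values; nine beat the Bonferroni
threshold 0.05/50 = 0.001 on this modest 12-taxon tree.
`coef()`, `summary()`, `plot()` and `simulate()` (parametric bootstrap)
methods are available on the returned object.

A full toy pipeline — genome, GFF3, VCF with planted SNPs of every class —
comes from the simulator:

```r
toy <- simulate_toy_genome("toy_dir", n_genes = 4, n_samples = 8, seed = 1)
genes <- read_gene_models(toy$gff, toy$fasta)
vt <- read_variants(toy$vcf)
effects <- summarize_effects(classify_variants(vt, genes))
table(effects$class)
```

## Command line

A thin CLI wraps the same functions:

```sh
exec/delscan annotate --vcf variants.vcf --gff genes.gff3 --fasta genome.fa --out effects.tsv
exec/delscan lrt --alignments aln_dir --tree species.nwk --effects effects.tsv --out lrt.tsv
exec/delscan simulate --out toy_dir --n-genes 4 --seed 1
```

Genetic maps are plain TSV with header columns `marker`, `chrom`, `bp`,
`cM` (1-based bp, sorted or sortable per chromosome); prediction tables are
TSV with `variant_id` (`chrom:pos:ref:alt`) and `verdict`.

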