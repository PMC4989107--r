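Package: delscan
Title: Deleterious Variant Annotation by Phylogenetic Likelihood-Ratio Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates candidate deleterious coding variants in crop
    resequencing data. The core is a per-codon likelihood-ratio test of
    selective constraint against neutral evolution on a multi-species codon
    alignment over a fixed phylogeny, using a Goldman-Yang style codon
    substitution model with F3x4 equilibrium frequencies. Around the test the
    package provides variant effect classification from VCF/GFF3/FASTA input
    (synonymous, missense, nonsense), Grantham scores and Ts/Tv summaries,
    ancestral-state polarization from outgroup clades with derived site
    frequency spectra, intersection of constraint verdicts with external
    SIFT-like and PolyPhen2-like prediction tables, recombination-rate
    overlays from genetic maps, and a seeded simulator of codon alignments
    and toy genome/VCF/GFF bundles used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    vcfR,
    rtracklayer,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
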