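# Seeded simulator: codon alignments evolved under the engine's own model
# with known per-site omega (the validation harness for the LRT), plus toy
# genome/GFF/VCF bundles with planted SNPs of every effect class for
# end-to-end pipeline tests. All randomness flows from a single seed;
# per-gene streams are split deterministically so results do not depend on
# gene order.

#' Specification for a codon-alignment simulation
#'
#' @param tree `phylo` tree with branch lengths in expected substitutions
#'   per codon site at neutrality.
#' @param kappa Transition/transversion ratio.
#' @param omega Per-site omega vector (length = number of codons; >= 0).
#' @param pi Codon equilibrium frequencies (61; default uniform).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, kappa, omega, pi = rep(1 / 61, 61),
                            seed = 1L) {
  validate_tree(tree)
  stopifnot(kappa > 0, all(omega >= 0), length(pi) == 61L,
            abs(sum(pi) - 1) < 1e-8)
  structure(list(tree = tree, kappa = kappa, omega = omega, pi = pi,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a codon alignment under the substitution model
#'
#' The root codon of every column is drawn from pi; states then evolve along
#' each branch with transition probabilities exp(t Q(omega_site)), where Q
#' is the same normalised generator the likelihood engine uses. Deterministic
#' under a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @param query Taxon label to designate as query (default: first tip).
#' @param root_states Optional integer vector of fixed root codon states
#'   (1..61) instead of draws from pi.
#' @param query_is_root If TRUE the query taxon's row is replaced by the
#'   root sequence (useful for building fixtures where the query must equal
#'   a known reference CDS).
#' @return A [codon_alignment()].
#' @export
simulate_alignment <- function(spec, query = NULL, root_states = NULL,
                               query_is_root = FALSE) {
  tree <- spec$tree
  S <- length(spec$omega)
  if (!is.null(root_states) && length(root_states) != S)
    stop("simulate_alignment: root_states length must match omega vector")
  st <- codon_states()
  params <- codon_model_params(spec$kappa, 1, 1, spec$pi)
  with_seed(spec$seed, {
    root_s <- root_states %||% sample.int(61L, S, replace = TRUE,
                                          prob = spec$pi)
    po <- tree_postorder(tree)
    nmax <- po$ntip + tree$Nnode
    node_states <- matrix(NA_integer_, nmax, S)
    node_states[po$root, ] <- root_s
    # preorder = reverse postorder: parents are assigned before children
    groups <- split(seq_len(S), spec$omega)
    decs <- lapply(as.numeric(names(groups)), function(w) {
      decompose_generator(build_rate_matrix(params, w), spec$pi)
    })
    for (k in rev(seq_len(nrow(po$edge)))) {
      parent <- po$edge[k, 1L]; child <- po$edge[k, 2L]
      t_e <- po$length[k]
      for (g in seq_along(groups)) {
        cols <- groups[[g]]
        ps <- node_states[parent, cols]
        if (t_e == 0) { node_states[child, cols] <- ps; next }
        P <- prob_matrix(decs[[g]], t_e)
        for (c0 in unique(ps)) {
          sel <- cols[ps == c0]
          node_states[child, sel] <- sample.int(61L, length(sel),
                                                replace = TRUE,
                                                prob = P[c0, ])
        }
      }
    }
    seqs <- vapply(seq_len(po$ntip), function(i) {
      paste(st$codons[node_states[i, ]], collapse = "")
    }, character(1))
    names(seqs) <- po$tips
    query <- query %||% po$tips[1]
    if (query_is_root) {
      seqs[query] <- paste(st$codons[root_s], collapse = "")
    }
    codon_alignment(seqs, query)
  })
}

# Wrap raw generating parameters so test_site() accepts them (used when
# testing sites against known truth rather than a fitted gene model).
as_fitted_params <- function(params) {
  params$logLik <- NA_real_
  params$converged <- TRUE
  params
}

#' Null-calibration and power experiment for the site LRT
#'
#' Simulates codon columns at each omega in a grid (the grid must include
#' the neutral omega = 1 row), runs the site test with the true generating
#' kappa/pi, and tabulates rejection rates at `alpha` and at the Bonferroni
#' threshold for the total number of tests, with binomial standard errors.
#'
#' @param tree `phylo` tree.
#' @param kappa Generating (and testing) kappa.
#' @param omega_grid Omega values to simulate (must include 1).
#' @param n_sites Codon columns per grid value.
#' @param alpha Nominal level (default 0.05).
#' @param min_species Informative-species rule for the test (default 10).
#' @param pi Codon frequencies (default uniform).
#' @param seed Seed.
#' @param exclude_query Mask the (arbitrary) query tip from the test. The
#'   default FALSE calibrates the bare statistic on all simulated taxa;
#'   masking is a pipeline policy, orthogonal to null calibration.
#' @return data.frame: omega, n_tested, reject_alpha, reject_bonferroni,
#'   se (binomial SE of reject_alpha).
#' @export
calibration_experiment <- function(tree, kappa, omega_grid, n_sites,
                                   alpha = 0.05, min_species = 10L,
                                   pi = rep(1 / 61, 61), seed = 1L,
                                   exclude_query = FALSE) {
  if (n_sites < 1) stop("calibration_experiment: n_sites must be >= 1")
  if (!any(omega_grid == 1))
    stop("calibration_experiment: grid must include omega = 1")
  params <- as_fitted_params(codon_model_params(kappa, 1, 1, pi))
  bthr <- bonferroni_threshold(alpha, n_sites * length(omega_grid))
  rows <- lapply(seq_along(omega_grid), function(g) {
    w <- omega_grid[g]
    spec <- simulation_spec(tree, kappa, rep(w, n_sites), pi,
                            seed = child_seed(seed, g))
    aln <- simulate_alignment(spec)
    ctx <- site_test_context(aln, tree, params,
                             exclude_query = exclude_query)
    p <- vapply(seq_len(n_sites) - 1L, function(ci) {
      test_site(aln, tree, params, ci, min_species = min_species,
                ctx = ctx)$p_value
    }, numeric(1))
    p <- p[!is.na(p)]
    data.frame(omega = w, n_tested = length(p),
               reject_alpha = mean(p < alpha),
               reject_bonferroni = mean(p < bthr),
               se = sqrt(alpha * (1 - alpha) / length(p)))
  })
  do.call(rbind, rows)
}

# ---- toy genome --------------------------------------------------------

random_sense_cds <- function(n_codons) {
  st <- codon_states()
  paste(st$codons[sample.int(61L, n_codons, replace = TRUE)], collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome bundle with planted SNPs of every effect class
#'
#' Builds a small single-chromosome genome with two-exon genes (alternating
#' strands, one gene carrying a second transcript that skips exon 2), plants
#' one SNP of each class — synonymous, missense, nonsense, stop_loss (in the
#' terminal stop codon), intronic and intergenic — and writes genome FASTA,
#' GFF3, VCF and a truth table. Genotypes are random with the alternate
#' allele guaranteed present.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes (>= 2; default 4).
#' @param n_samples Number of diploid accessions (default 8).
#' @param seed Seed fixing all randomness.
#' @return List with paths `fasta`, `gff`, `vcf`, `truth`, the truth
#'   data.frame (`chrom`, `pos`, `ref`, `alt`, `class`, `gene`), and the
#'   per-gene layout.
#' @export
simulate_toy_genome <- function(dir, n_genes = 4L, n_samples = 8L,
                                seed = 1L) {
  if (n_genes < 2L) stop("simulate_toy_genome: need n_genes >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    exon1_codons <- 15L; exon2_codons <- 15L; intron_len <- 30L
    spacer <- 40L
    genome <- random_dna(spacer)
    gff <- c("##gff-version 3")
    truth <- list(); layout <- list()
    for (g in seq_len(n_genes)) {
      strand <- if (g %% 2L == 0L) "-" else "+"
      # CDS in translation order: exon1 | exon2 + terminal stop (TGA)
      cds <- paste0(random_sense_cds(exon1_codons),
                    random_sense_cds(exon2_codons - 1L), "TGA")
      # plant recognisable codons at fixed offsets (translation order)
      cds <- `substr<-`(cds, 4L, 6L, value = "GGT")   # codon 2: synonymous target
      cds <- `substr<-`(cds, 7L, 9L, value = "TGG")   # codon 3: nonsense target
      cds <- `substr<-`(cds, 10L, 12L, value = "ATG") # codon 4: missense target
      exon1 <- substr(cds, 1L, exon1_codons * 3L)
      exon2 <- substr(cds, exon1_codons * 3L + 1L, nchar(cds))
      gstart <- nchar(genome) + 1L
      exon3 <- NULL; e3 <- NULL
      if (strand == "+") {
        gene_seq <- paste0(exon1, random_dna(intron_len), exon2)
        e1 <- c(gstart, gstart + nchar(exon1) - 1L)
        e2 <- c(e1[2] + intron_len + 1L,
                e1[2] + intron_len + nchar(exon2))
        if (g == 1L) {
          # third exon for the second isoform (exon1 + exon3): in frame
          # after exon1, all sense codons, so the isoform stays valid
          exon3 <- random_sense_cds(3L)
          gene_seq <- paste0(gene_seq, random_dna(intron_len), exon3)
          e3 <- c(e2[2] + intron_len + 1L, e2[2] + intron_len + nchar(exon3))
        }
      } else {
        gene_seq <- revcomp(paste0(exon1, random_dna(intron_len), exon2))
        gend <- gstart + nchar(gene_seq) - 1L
        e1 <- c(gend - nchar(exon1) + 1L, gend)  # exon1 is 3'-most genomically
        e2 <- c(gstart, gstart + nchar(exon2) - 1L)
      }
      genome <- paste0(genome, gene_seq, random_dna(spacer))
      tx <- sprintf("gene%d.t1", g)
      gene_id <- sprintf("gene%d", g)
      ivs <- if (strand == "+") list(e1, e2) else list(e2, e1)
      gff <- c(gff,
               sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       min(e1[1], e2[1]), max(e1[2], e2[2]), strand, gene_id),
               sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       min(e1[1], e2[1]), max(e1[2], e2[2]), strand, tx,
                       gene_id))
      for (iv in ivs)
        gff <- c(gff, sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                              iv[1], iv[2], strand, tx))
      if (g == 1L && !is.null(e3)) {
        # second isoform skips exon 2: SNPs inside exon 2 are exonic in
        # gene1.t1 but intronic in gene1.t2
        tx2 <- sprintf("gene%d.t2", g)
        gff <- c(gff,
                 sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         e1[1], e3[2], strand, tx2, gene_id),
                 sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         e1[1], e1[2], strand, tx2),
                 sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         e3[1], e3[2], strand, tx2))
      }
      # genomic position of a CDS offset (0-based, translation order)
      gpos <- function(off) {
        if (strand == "+") {
          if (off < exon1_codons * 3L) e1[1] + off
          else e2[1] + (off - exon1_codons * 3L)
        } else {
          if (off < exon1_codons * 3L) e1[2] - off
          else e2[2] - (off - exon1_codons * 3L)
        }
      }
      cds_base <- function(off) substr(cds, off + 1L, off + 1L)
      plant <- function(off, alt_cds, class) {
        pos <- gpos(off)
        ref <- cds_base(off); alt <- alt_cds
        if (strand == "-") { ref <- comp_base(ref); alt <- comp_base(alt) }
        data.frame(chrom = "chr1", pos = pos, ref = unname(ref),
                   alt = unname(alt), class = class, gene = tx,
                   stringsAsFactors = FALSE)
      }
      stop_off <- nchar(cds) - 3L
      truth[[length(truth) + 1L]] <- rbind(
        plant(3L + 2L, "C", "synonymous"),    # GGT -> GGC
        plant(6L + 1L, "A", "nonsense"),      # TGG -> TAG
        plant(9L + 2L, "A", "missense"),      # ATG -> ATA
        plant(stop_off + 2L, "G", "stop_loss"))  # TGA -> TGG
      # intronic SNP (between the exons)
      ipos <- min(e1[2], e2[2]) + 5L
      iref <- substr(genome, ipos, ipos)
      ialt <- setdiff(c("A", "C", "G", "T"), iref)[1]
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = "chr1", pos = ipos, ref = iref, alt = ialt,
        class = "noncoding", gene = tx, stringsAsFactors = FALSE)
      layout[[tx]] <- list(strand = strand, e1 = e1, e2 = e2, e3 = e3,
                           cds = cds)
    }
    # one intergenic SNP in the leading spacer
    iref <- substr(genome, 10L, 10L)
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = "chr1", pos = 10L, ref = iref,
      alt = setdiff(c("A", "C", "G", "T"), iref)[1],
      class = "noncoding", gene = NA_character_, stringsAsFactors = FALSE)
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    # genotypes: at least one alternate allele per site
    gts <- t(vapply(seq_len(nrow(truth)), function(i) {
      f <- stats::runif(1, 0.1, 0.6)
      g <- stats::rbinom(n_samples, 2L, f)
      if (all(g == 0L)) g[sample.int(n_samples, 1L)] <- 1L
      c("0/0", "0/1", "1/1")[g + 1L]
    }, character(n_samples)))
    samples <- sprintf("acc%02d", seq_len(n_samples))
    colnames(gts) <- samples
    vt <- variant_table(truth[, c("chrom", "pos", "ref", "alt")], gts,
                        samples)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff = file.path(dir, "genes.gff3"),
                  vcf = file.path(dir, "variants.vcf"),
                  truth = file.path(dir, "truth.tsv"))
    writeLines(c(">chr1", genome), paths$fasta)
    writeLines(gff, paths$gff)
    write_variants(vt, paths$vcf)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(paths, list(truth_table = truth, layout = layout, variants = vt))
  })
}
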