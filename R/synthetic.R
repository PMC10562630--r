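#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' matching the statistical structure the analysis modules assume: 20
#' species on a unit-depth tree, critical birth--death family-count
#' evolution with discrete-gamma among-family variation, AMP-like motif
#' peptides against a uniform-composition background, exon-count and
#' TE-class mixes at the published AMP gene-structure proportions, and the
#' hierarchical-regression generative model with the reported coefficient
#' vector as truth.
#'
#' @param seed master integer seed.
#' @param n_species number of species.
#' @param tree_depth depth of the rescaled species tree (time units).
#' @param n_families number of gene families to evolve.
#' @param lambda_true birth = death rate (events/gene/time).
#' @param gamma_shape,n_categories among-family rate variation.
#' @param root_count_law list(name, ...) for root family sizes; the default
#'   `poisson_plus1` draws `1 + Poisson(lambda)`.
#' @param peptide_counts named counts: `defensin`, `cathelicidin`,
#'   `negative`.
#' @param te_class_weights probability per TE class (defaults: the
#'   beta-defensin intron TE class mix).
#' @param exon_count_weights per-family exon-count probabilities.
#' @param regression_truth list(beta, sigma2_species, sigma2_family,
#'   sigma2_resid); beta defaults to the reported posterior means
#'   (intercept, exon count, log TE length, TE count).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_species = 20L,
                             tree_depth = 1.0,
                             n_families = 40L,
                             lambda_true = 0.3,
                             gamma_shape = 2,
                             n_categories = 3L,
                             root_count_law = list(name = "poisson_plus1",
                                                   lambda = 1),
                             peptide_counts = c(defensin = 150L,
                                                cathelicidin = 150L,
                                                negative = 300L),
                             te_class_weights = c(DNA = 40, LINE = 156,
                                                  LTR = 21, RC = 12,
                                                  Retroposon = 1, SINE = 94,
                                                  Unknown = 11) / 335,
                             exon_count_weights = list(
                               DEFA = c("2" = 0.88, "3" = 0.12),
                               DEFB = c("1" = 0.13, "2" = 0.85, "3" = 0.02),
                               CTHL = c("2" = 0.04, "3" = 0.15, "4" = 0.81)),
                             regression_truth = list(
                               beta = c(intercept = 5.083, exon_count = 0.120,
                                        log_te_length = 0.436,
                                        te_count = -0.030),
                               sigma2_species = 0.2, sigma2_family = 0.05,
                               sigma2_resid = 0.1)) {
  norm1 <- function(w) w / sum(w)
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              tree_depth = tree_depth, n_families = as.integer(n_families),
              lambda_true = lambda_true, gamma_shape = gamma_shape,
              n_categories = as.integer(n_categories),
              root_count_law = root_count_law,
              peptide_counts = peptide_counts,
              te_class_weights = norm1(te_class_weights),
              exon_count_weights = lapply(exon_count_weights, norm1),
              regression_truth = regression_truth)
  stopifnot(abs(sum(cfg$te_class_weights) - 1) < 1e-12,
            all(abs(vapply(cfg$exon_count_weights, sum, numeric(1)) - 1) < 1e-12))
  structure(cfg, class = "synthetic_config")
}

draw_root_counts <- function(law, n) {
  switch(law$name,
         poisson_plus1 = 1L + rpois(n, law$lambda),
         fixed = rep(as.integer(law$count), n),
         geometric = 1L + rgeom(n, law$p),
         stop("unknown root count law: ", law$name, call. = FALSE))
}

#' Simulate gene-family counts along a species tree
#'
#' Forward simulation of the same critical linear birth--death process the
#' family-size likelihood fits: counts evolve branch by branch with
#' birth = death = lambda (times a per-family discrete-gamma category
#' factor of mean one when `gamma_shape` is set), and zero is absorbing.
#' True internal-node counts are retained for ancestral-state checks.
#'
#' @param tree species tree ([ape::phylo]).
#' @param lambda birth = death rate, or vector of per-edge rates.
#' @param n_families number of families.
#' @param root_count_law list(name, ...); see [synthetic_config()].
#' @param gamma_shape,n_categories optional among-family rate variation.
#' @param seed integer seed.
#' @return list with `counts` (families x tips), `node_counts` (families x
#'   all nodes), `category` (per-family rate multiplier) and `tree`.
#' @export
simulate_family_counts <- function(tree, lambda, n_families,
                                   root_count_law = list(name = "poisson_plus1",
                                                         lambda = 1),
                                   gamma_shape = NULL, n_categories = 3L,
                                   seed = 1L) {
  if (any(lambda < 0)) stop("rates must be non-negative", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  lam_edge <- if (length(lambda) == 1) rep(lambda, nrow(tree$edge)) else lambda
  mult <- if (is.null(gamma_shape)) 1
          else discrete_gamma_categories(gamma_shape, n_categories)
  with_seed(seed, {
    roots <- draw_root_counts(root_count_law, n_families)
    cat_mult <- sample(mult, n_families, replace = TRUE)
    node_counts <- t(vapply(seq_len(n_families), function(f)
      sim_family_on_tree(tree, roots[f], lam_edge * cat_mult[f]),
      integer(ntip + tree$Nnode)))
    colnames(node_counts) <- c(tree$tip.label,
                               paste0("node", (ntip + 1):(ntip + tree$Nnode)))
    rownames(node_counts) <- paste0("fam", seq_len(n_families))
    list(counts = node_counts[, seq_len(ntip), drop = FALSE],
         node_counts = node_counts, category = cat_mult, tree = tree)
  })
}

sample_aa <- function(n, exclude = "C") {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Six cysteines with inter-cysteine spacers of 2..12 residues plus short
# flanks: the defensin-like motif grammar.
r_defensin6 <- function() {
  spacers <- vapply(sample(2:12, 5, replace = TRUE), sample_aa, character(1))
  paste0(sample_aa(sample(0:6, 1)), "C",
         paste0(spacers, "C", collapse = ""),
         sample_aa(sample(0:6, 1)))
}

# Four cysteines in a propeptide-like core with longer flanks.
r_cathelicidin4 <- function() {
  spacers <- vapply(sample(3:15, 3, replace = TRUE), sample_aa, character(1))
  paste0(sample_aa(sample(5:20, 1)), "C",
         paste0(spacers, "C", collapse = ""),
         sample_aa(sample(5:20, 1)))
}

#' Generate labelled synthetic peptide sets
#'
#' Positives obey the cysteine-motif grammars by construction (six-cysteine
#' defensin-like, four-cysteine cathelicidin-like) with lengths inside
#' \[10, 200\]; negatives are uniform-composition background sequences with
#' a broader length law (uniform on \[10, 400\]), in which the motifs occur
#' only by chance.
#'
#' @param config a [synthetic_config()] (its `peptide_counts` and `seed`
#'   are used).
#' @return named character vector of sequences; names encode the true
#'   label, e.g. `def_003 label=defensin6`.
#' @export
generate_peptides <- function(config = synthetic_config()) {
  pc <- config$peptide_counts
  if (any(pc <= 0)) stop("peptide counts must be positive", call. = FALSE)
  with_seed(config$seed, {
    defs <- replicate(pc[["defensin"]], r_defensin6())
    caths <- replicate(pc[["cathelicidin"]], r_cathelicidin4())
    negs <- vapply(seq_len(pc[["negative"]]), function(i)
      paste(sample(AA20, sample(10:400, 1), replace = TRUE), collapse = ""),
      character(1))
    stopifnot(all(nchar(c(defs, caths)) >= 10),
              all(nchar(c(defs, caths)) <= 200))
    setNames(c(defs, caths, negs),
             c(sprintf("def_%03d label=defensin6", seq_along(defs)),
               sprintf("cath_%03d label=cathelicidin4", seq_along(caths)),
               sprintf("neg_%03d label=background", seq_along(negs))))
  })
}

#' Test sequences against the generative cysteine-motif grammars
#'
#' The spacing grammar the positive generators use: `defensin6` is six
#' cysteines with 2--12 residue spacers, `cathelicidin4` four cysteines
#' with 3--15 residue spacers. Looser than the count-based
#' [cysteine_motif_class()] (which implements the curation rule), this is
#' the pattern a background sequence only rarely contains.
#'
#' @param seqs character vector of amino-acid sequences.
#' @param class `"defensin6"` or `"cathelicidin4"`.
#' @return logical vector.
#' @export
matches_motif_grammar <- function(seqs, class = c("defensin6",
                                                  "cathelicidin4")) {
  class <- match.arg(class)
  pat <- switch(class,
                defensin6 = "C.{2,12}C.{2,12}C.{2,12}C.{2,12}C.{2,12}C",
                cathelicidin4 = "C.{3,15}C.{3,15}C.{3,15}C")
  grepl(pat, seqs)
}

CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              E = "GAA", Q = "CAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(peptide) {
  paste(CODON_OF[strsplit(peptide, "")[[1]]], collapse = "")
}

revcomp <- function(nt) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Generate a synthetic genome fixture
#'
#' Builds scaffold sequences, multi-exon AMP gene models and a TE
#' annotation table with the structure the downstream stages expect: exon
#' counts drawn per family from the configured weights, coding sequence
#' reverse-translated from motif-bearing peptides (so the models translate
#' back to defensin/cathelicidin-like proteins), TEs placed in introns and
#' intergenic space with classes from the configured mix and divergences
#' uniform on \[0, 40\] percent, a deliberate fraction of overlapping TE
#' pairs to exercise overlap resolution, plus simple-repeat records that
#' resolution must discard. Some genes are placed within 10 kb of each
#' other to form clusters.
#'
#' @param config a [synthetic_config()].
#' @param n_genes named per-family gene counts.
#' @param n_te_intergenic intergenic TE count per scaffold.
#' @param p_te_per_intron expected TEs per intron (Poisson mean).
#' @param overlap_fraction fraction of intronic TEs duplicated into a
#'   deliberately overlapping partner record.
#' @return list with `scaffolds` (named character of DNA), `genes`
#'   (data.frame with `exons` list-column, 0-based half-open), `tes`
#'   (TE data.frame), `peptides` (named character, the encoded proteins).
#' @export
generate_genome_fixture <- function(config = synthetic_config(),
                                    n_genes = c(DEFA = 8L, DEFB = 30L,
                                                CTHL = 8L),
                                    n_te_intergenic = 5L,
                                    p_te_per_intron = 1.5,
                                    overlap_fraction = 0.15) {
  with_seed(config$seed + 1L, {
    genes <- list(); peptides <- character(); tes <- list()
    scaffolds <- list()
    scaf_i <- 0L
    gid <- 0L
    for (fam in names(n_genes)) {
      remaining <- n_genes[[fam]]
      while (remaining > 0) {
        scaf_i <- scaf_i + 1L
        scaf <- sprintf("scaf%03d", scaf_i)
        in_this <- min(remaining, sample(1:3, 1))  # 2-3 genes => clusters
        remaining <- remaining - in_this
        pos <- 2000L
        seq_parts <- list()
        cursor <- 0L
        add_seq <- function(nt) {
          seq_parts[[length(seq_parts) + 1]] <<- nt
          cursor <<- cursor + nchar(nt)
        }
        for (k in seq_len(in_this)) {
          gid <- gid + 1L
          pep <- if (fam == "CTHL") r_cathelicidin4() else r_defensin6()
          cds <- reverse_translate(pep)
          nex <- as.integer(sample(names(config$exon_count_weights[[fam]]), 1,
                                   prob = config$exon_count_weights[[fam]]))
          # split CDS into nex chunks at codon boundaries
          ncod <- nchar(cds) / 3
          cuts <- if (nex == 1) integer(0) else
            sort(sample(seq_len(ncod - 1), nex - 1)) * 3
          bounds <- c(0, cuts, nchar(cds))
          chunks <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
          strand <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
          if (strand == "-") chunks <- rev(vapply(chunks, revcomp, character(1)))
          # intergenic gap before the gene
          gap <- sample(1500:8000, 1)
          add_seq(paste(sample(c("A", "C", "G", "T"), gap, TRUE), collapse = ""))
          gstart <- cursor
          exons <- matrix(0L, nex, 2)
          for (ei in seq_len(nex)) {
            exons[ei, 1] <- cursor
            add_seq(chunks[ei])
            exons[ei, 2] <- cursor
            if (ei < nex) {
              ilen <- sample(300:2500, 1)
              istart <- cursor
              add_seq(paste(sample(c("A", "C", "G", "T"), ilen, TRUE),
                            collapse = ""))
              # TEs inside this intron
              nte <- rpois(1, p_te_per_intron)
              for (ti in seq_len(nte)) {
                tlen <- sample(80:min(600, ilen - 20), 1)
                tstart <- istart + sample(0:(ilen - tlen), 1)
                cl <- sample(names(config$te_class_weights), 1,
                             prob = config$te_class_weights)
                tes[[length(tes) + 1]] <- data.frame(
                  scaffold = scaf, start = tstart, end = tstart + tlen,
                  strand = sample(c("+", "-"), 1),
                  te_family = paste0(cl, "-fam", sample(1:5, 1)),
                  te_class = cl, divergence = runif(1, 0, 40))
                if (runif(1) < overlap_fraction) {
                  sh <- sample(ceiling(tlen * 0.05):floor(tlen * 0.15), 1)
                  last <- tes[[length(tes)]]
                  tes[[length(tes) + 1]] <- transform(
                    last, start = start + sh, end = end + sh,
                    divergence = runif(1, 0, 40))
                }
              }
            }
          }
          gend <- cursor
          genes[[length(genes) + 1]] <- data.frame(
            gene_id = sprintf("%s_g%03d", fam, gid), scaffold = scaf,
            start = gstart, end = gend, strand = strand, family_label = fam)
          genes[[length(genes)]]$exons <- list(exons)
          peptides[sprintf("%s_g%03d", fam, gid)] <- pep
        }
        add_seq(paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
        # intergenic TEs + a simple repeat to exercise the discard rule
        slen <- cursor
        for (ti in seq_len(n_te_intergenic)) {
          tlen <- sample(80:600, 1)
          tstart <- sample(0:(slen - tlen), 1)
          cl <- sample(names(config$te_class_weights), 1,
                       prob = config$te_class_weights)
          tes[[length(tes) + 1]] <- data.frame(
            scaffold = scaf, start = tstart, end = tstart + tlen,
            strand = sample(c("+", "-"), 1),
            te_family = paste0(cl, "-fam", sample(1:5, 1)),
            te_class = cl, divergence = runif(1, 0, 40))
        }
        tes[[length(tes) + 1]] <- data.frame(
          scaffold = scaf, start = 10L, end = 60L, strand = "+",
          te_family = "(AT)n", te_class = "Simple_repeat",
          divergence = runif(1, 0, 40))
        scaffolds[[scaf]] <- paste(unlist(seq_parts), collapse = "")
      }
    }
    genes <- do.call(rbind, genes)
    tes <- do.call(rbind, tes)
    tes <- tes[order(tes$scaffold, tes$start), ]
    rownames(tes) <- NULL
    list(scaffolds = unlist(scaffolds), genes = genes, tes = tes,
         peptides = peptides)
  })
}

#' Generate a regression dataset with phylogenetically correlated species effects
#'
#' Emits the per-gene table the hierarchical regression consumes, generated
#' from its own model: `log(gene_length) = b0 + b1 exon_count +
#' b2 log(te_length + 1) + b3 te_count + u_species + v_family + e` with
#' `u ~ N(0, sigma2_s A)` (A from [tree_to_relatedness()]),
#' `v ~ N(0, sigma2_f I)`, `e ~ N(0, sigma2_e I)`.
#'
#' @param tree species tree covering all emitted species.
#' @param truth list(beta, sigma2_species, sigma2_family, sigma2_resid);
#'   see [synthetic_config()] for the default.
#' @param n_genes_per_species genes per species.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `species`, `amp_family`,
#'   `exon_count`, `te_count`, `te_length`, `gene_length`; attributes
#'   `truth`, `species_effects`, `family_effects`.
#' @export
generate_regression_data <- function(tree,
                                     truth = synthetic_config()$regression_truth,
                                     n_genes_per_species = 15L, seed = 1L) {
  if (any(unlist(truth[c("sigma2_species", "sigma2_family",
                         "sigma2_resid")]) < 0))
    stop("variance components must be >= 0", call. = FALSE)
  A <- tree_to_relatedness(tree)
  species <- rownames(A)
  fams <- c("DEFA", "DEFB", "CTHL")
  with_seed(seed, {
    u <- if (truth$sigma2_species == 0) setNames(rep(0, length(species)), species)
         else setNames(drop(crossprod(chol(A + diag(1e-10, nrow(A))),
                                      rnorm(length(species)))) *
                       sqrt(truth$sigma2_species), species)
    v <- if (truth$sigma2_family == 0) setNames(rep(0, 3), fams)
         else setNames(rnorm(3, 0, sqrt(truth$sigma2_family)), fams)
    rows <- lapply(species, function(sp) {
      fam <- sample(fams, n_genes_per_species, replace = TRUE,
                    prob = c(25, 234, 27) / 286)
      exon_count <- sample(1:4, n_genes_per_species, replace = TRUE,
                           prob = c(0.12, 0.62, 0.1, 0.16))
      te_count <- rpois(n_genes_per_species, 2)
      te_length <- ifelse(te_count == 0, 0,
                          round(exp(rnorm(n_genes_per_species,
                                          log(177), 0.8))) *
                            pmax(te_count, 1) / 2)
      te_length <- round(te_length)
      b <- truth$beta
      eta <- b[1] + b[2] * exon_count + b[3] * log(te_length + 1) +
        b[4] * te_count + u[sp] + v[fam]
      e <- if (truth$sigma2_resid == 0) 0 else
        rnorm(n_genes_per_species, 0, sqrt(truth$sigma2_resid))
      data.frame(gene_id = paste0(sp, "_g", seq_len(n_genes_per_species)),
                 species = sp, amp_family = fam, exon_count = exon_count,
                 te_count = te_count, te_length = te_length,
                 gene_length = exp(eta + e))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    attr(out, "species_effects") <- u
    attr(out, "family_effects") <- v
    out
  })
}
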