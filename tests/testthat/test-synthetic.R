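test_that("species tree simulator yields seeded, ultrametric, unit-depth trees", {
  expect_error(simulate_species_tree(1, seed = 1), "at least 2")
  tr <- simulate_species_tree(50, seed = 1)
  depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1.0)
  expect_identical(ape::write.tree(simulate_species_tree(20, seed = 1)),
                   ape::write.tree(simulate_species_tree(20, seed = 1)))
  expect_false(identical(ape::write.tree(simulate_species_tree(20, seed = 1)),
                         ape::write.tree(simulate_species_tree(20, seed = 2))))
})

test_that("family-count simulation matches the birth-death transition law", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  # lambda = 0: tips echo the root count
  sim0 <- simulate_family_counts(tr, 0, 200, root_count_law = list(name = "poisson_plus1", lambda = 2),
                                 seed = 3)
  expect_true(all(sim0$counts == sim0$node_counts[, "node3"]))
  # single-branch extinction probability, s = 1, lambda = 0.5, t = 1
  sim <- simulate_family_counts(tr, 0.5, 10000,
                                root_count_law = list(name = "fixed", count = 1),
                                seed = 11)
  p_hat <- mean(sim$counts == 0)
  p_true <- bdp_transition_prob(1, 0, 0.5, 1)
  se <- sqrt(p_true * (1 - p_true) / length(sim$counts))
  expect_lt(abs(p_hat - p_true), 3 * se)
  # martingale: equal-rate process preserves the mean
  sim5 <- simulate_family_counts(tr, 0.4, 10000,
                                 root_count_law = list(name = "fixed", count = 5),
                                 seed = 12)
  se5 <- sd(sim5$counts) / sqrt(length(sim5$counts))
  expect_lt(abs(mean(sim5$counts) - 5), 3 * se5)
})

test_that("peptide generator enforces the motif grammars and is seed-pure", {
  cfg <- synthetic_config(seed = 1L)
  peps <- generate_peptides(cfg)
  labs <- sub(".*label=", "", names(peps))
  defs <- peps[labs == "defensin6"]
  caths <- peps[labs == "cathelicidin4"]
  negs <- peps[labs == "background"]
  expect_true(all(vapply(defs, cysteine_motif_class, "") == "defensin6"))
  expect_true(all(matches_motif_grammar(defs, "defensin6")))
  expect_true(all(vapply(caths, cysteine_motif_class, "") == "cathelicidin4"))
  expect_true(all(nchar(c(defs, caths)) >= 10 & nchar(c(defs, caths)) <= 200))
  # uniform background only rarely contains the spacing grammar (pinned
  # empirically at the default seed; see the methods vignette)
  expect_lte(mean(matches_motif_grammar(negs, "defensin6")), 0.10)
  expect_identical(peps, generate_peptides(cfg))
  expect_false(identical(peps, generate_peptides(synthetic_config(seed = 2L))))
})

test_that("genome fixture has valid gene models and configured exon mix", {
  cfg <- synthetic_config(seed = 1L)
  fx <- generate_genome_fixture(cfg)
  # exons inside gene, same strand record, ordered
  for (i in seq_len(nrow(fx$genes))) {
    g <- fx$genes[i, ]
    ex <- fx$genes$exons[[i]]
    expect_true(all(ex[, 1] >= g$start & ex[, 2] <= g$end))
    expect_true(all(diff(as.vector(t(ex))) >= 0))
  }
  # genes translate back to their motif-bearing peptides
  g1 <- fx$genes[1, ]
  ex <- fx$genes$exons[[1]]
  nt <- paste(substring(fx$scaffolds[g1$scaffold], ex[, 1] + 1, ex[, 2]),
              collapse = "")
  if (g1$strand == "-") nt <- ampevo:::revcomp(nt)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(aa, unname(fx$peptides[g1$gene_id]))
  # no TEs requested -> intersect reports zero TEs everywhere
  fx0 <- generate_genome_fixture(cfg, n_genes = c(DEFB = 4L),
                                 n_te_intergenic = 0L, p_te_per_intron = 0)
  expect_equal(nrow(fx0$tes[fx0$tes$te_class != "Simple_repeat", ]), 0)
  ig0 <- intersect_genes_tes(fx0$genes, resolve_te_overlaps(fx0$tes))
  expect_true(all(ig0$summary$te_count == 0))
  # determinism
  expect_identical(fx$scaffolds, generate_genome_fixture(cfg)$scaffolds)
})

test_that("two-exon fraction of generated beta-defensin genes tracks the 85% weight", {
  fx <- generate_genome_fixture(synthetic_config(seed = 5L),
                                n_genes = c(DEFB = 2000L),
                                n_te_intergenic = 0L, p_te_per_intron = 0)
  nex <- vapply(fx$genes$exons, nrow, integer(1))
  expect_lt(abs(mean(nex == 2) - 0.85), 0.03)
})

test_that("regression generator follows its stated linear model", {
  tr <- simulate_species_tree(12, seed = 4)
  truth0 <- list(beta = c(intercept = 5.083, exon_count = 0.120,
                          log_te_length = 0.436, te_count = -0.030),
                 sigma2_species = 0, sigma2_family = 0, sigma2_resid = 0)
  d0 <- generate_regression_data(tr, truth0, n_genes_per_species = 10, seed = 2)
  b <- truth0$beta
  eta <- b[1] + b[2] * d0$exon_count + b[3] * log(d0$te_length + 1) +
    b[4] * d0$te_count
  expect_equal(log(d0$gene_length), unname(eta), tolerance = 1e-12)
  expect_identical(d0, generate_regression_data(tr, truth0,
                                                n_genes_per_species = 10,
                                                seed = 2))
})

test_that("species effects on a star tree are uncorrelated across species", {
  tr <- star_tree(6)
  truth <- list(beta = c(5, 0.1, 0.4, -0.03), sigma2_species = 1,
                sigma2_family = 0, sigma2_resid = 0)
  U <- t(vapply(1:500, function(r) {
    d <- generate_regression_data(tr, truth, n_genes_per_species = 1, seed = r)
    attr(d, "species_effects")
  }, numeric(6)))
  cors <- cor(U)[upper.tri(diag(6))]
  expect_lt(max(abs(cors)), 0.2)          # ~N(0, 1/sqrt(500)) under independence
  expect_lt(abs(mean(cors)), 0.05)
})
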