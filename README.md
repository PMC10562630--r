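# ampevo

Antimicrobial peptides (AMPs) — above all the defensins and cathelicidins —
are short, cysteine-rich host-defence peptides whose gene families expand,
contract and diverge unusually fast. Studying their evolution from genome
assemblies takes a chain of small, well-defined computations: curating
candidate peptides, scoring AMP probability, assigning subfamilies by local
alignment, cleaning transposable-element (TE) annotations and intersecting
them with gene models, regressing gene length on TE content while
controlling for phylogeny, and comparing birth–death models of gene-family
size. `ampevo` implements that chain as a tested, fully seeded R package,
together with a synthetic-data module that generates every input the
pipeline consumes with the statistical structure the analyses assume.

It is written for molecular evolution researchers who want the analysis
stages of an AMP repertoire study as reusable, verifiable functions rather
than one-off scripts.

## The models at the core

**Birth–death gene-family size.** Along each branch of an ultrametric
species tree, a family of size *s* evolves under the critical linear
birth–death process (birth = death = λ per gene copy), with

P(c | s) = Σ_{j=0}^{min(s,c)} C(s, j) · C(s+c−j−1, s−1) · α^{s+c−2j} · (1−2α)^j,  α = λt / (1 + λt),

zero absorbing. `family_loglik()` prunes this over the tree (uniform or
point root prior), optionally mixing over K equal-probability mean-one
discrete-gamma rate categories and an observation-error probability ε.
`fit_family_model()` maximises it with restarts; `lrt()` compares nested
fits against χ²; `branch_changes()` makes per-branch expansion/contraction
calls with Monte-Carlo p-values; `species_overlap_duplications()` applies
the Jaccard ≥ 0.5 species-overlap duplication criterion to gene trees.

**Phylogenetic hierarchical regression.** `fit_hierarchical_model()` is a
blocked Gibbs sampler for

log(gene length) = b₀ + b₁·exon count + b₂·log(TE length + 1) + b₃·TE count + u_species + v_family + e,

with u ~ N(0, σ²ₛ A) for the relatedness matrix A from
`tree_to_relatedness()` (shared root-to-MRCA path over tree depth),
v ~ N(0, σ²_f I), e ~ N(0, σ²_e I). Summaries report posterior means, 95%
highest-posterior-density intervals (`hpd_interval()`) and effective sample
sizes (`effective_sample_size()`).

**Classification and assignment.** `extract_features()` computes pinned
physicochemical features (composition, Henderson–Hasselbalch net charge and
pI, Kyte–Doolittle hydropathy, molecular weight); `train_amp_classifier()`
is a ridge-logistic model with length-matched negatives
(`match_length_distribution()`); `local_align()` is affine-gap
Smith–Waterman under BLOSUM62 with Karlin–Altschul e-values (`ka_evalue()`)
feeding `best_hit_assign()` and `relative_bitscore_filter()`.

## Worked example

```r
library(ampevo)

# model comparison of two reported birth-death fits
lrt(lnL_null = -648.749, lnL_alt = -627.106, df = 2)
#> $statistic
#> [1] 43.286
#> $p_value
#> [1] 3.98625e-10

# simulate a tree and gene-family counts, then recover the rate
tr  <- simulate_species_tree(10, seed = 3)
sim <- simulate_family_counts(tr, lambda = 0.3, n_families = 500, seed = 7)
fit <- fit_family_model(tr, sim$counts, bd_model_spec(0.5, max_count = 30),
                        n_starts = 3, seed = 1)
coef(fit)
#>   lambda1
#> 0.3154404

# phylogenetic regression on synthetic data planted at the reported means
A <- tree_to_relatedness(tr20 <- simulate_species_tree(20, seed = 4))
d <- generate_regression_data(tr20, n_genes_per_species = 30, seed = 5)
f <- fit_hierarchical_model(d, A, iterations = 20000, burn_in = 1000,
                            thin = 10, seed = 3)
round(f$summary["log_te_length", ], 3)
#>                mean lower_hpd95 upper_hpd95      ess
#> log_te_length 0.421       0.402        0.44 1405.809
```

The likelihood-ratio statistic is 2·ΔlnL = 43.286, far in the χ²₂ tail
(p ≈ 4e-10): the two-rate model fits decisively better. The recovered
birth–death rate (0.315) sits within sampling error of the simulated 0.3,
and the posterior for the TE-length coefficient brackets the planted 0.436.

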