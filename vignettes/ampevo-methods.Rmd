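---
title: "Models and methods behind ampevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampevo)
```

`ampevo` packages the analysis stages of an antimicrobial-peptide (AMP)
repertoire study — curation, classification, subfamily assignment,
transposable-element (TE) accounting, phylogenetic regression and
gene-family-size modelling — as seeded, testable functions. This vignette
explains each model, its assumptions and tunables, the synthetic data the
package tests itself against, and the numerical choices made where the
design was genuinely open.

## Peptide curation and the cysteine-motif grammar

`filter_peptides()` applies, in a fixed order, the predicates length in
[10, 200] residues, standard 20-letter alphabet, no internal stop, at
least two cysteines, and exact-sequence deduplication (first occurrence
kept). The order matters only for the reason code a rejected record
carries; the kept set is order-independent and filtering is idempotent.
"Premature stop" is interpreted at the protein level — a `*` anywhere
before the final position — and a single trailing `*` (a translated
terminal stop) is stripped silently, since inputs are translated products.

`cysteine_motif_class()` classifies by cysteine count in the annotated
mature region when one is present, otherwise the full sequence: six or
more cysteines is defensin-like, four to five cathelicidin-like. Only the
canonical counts (6 and 4) are conventional; the band edges are arguments
so the user can tighten them. `filter_genes_by_length()` keeps loci
spanning at least 200 bp (inclusive); shorter loci cannot encode a full
precursor (signal, propeptide, mature region).

## AMP probability classification

The feature sets of published AMP predictors are not uniquely specified,
so the package pins a fully deterministic one: length, the 20 composition
fractions, net charge at pH 7 via Henderson–Hasselbalch over the Lehninger
pKa set (termini included), isoelectric point by bisection of the same
charge function, mean Kyte–Doolittle hydropathy, cysteine fraction, and
average molecular weight from a pinned residue-mass table. All constants
ship in the source, so the features are reproducible to the last digit.

The classifier is L2-regularised logistic regression on standardised
features, fitted by IRLS. A ridge penalty (default 1e-2 on standardised
coefficients, intercept unpenalised) keeps coefficients finite on linearly
separable data — which synthetic positives versus background frequently
are — while perturbing well-posed fits negligibly (an unpenalised
`glm()` agrees to ~3 decimals on non-separable data, as the tests check).
Negative training sets are length-matched to the positives by
`match_length_distribution()`: 20 equal-width bins over the positives'
length range, bin-for-bin sampling without replacement, shortfalls filled
from the nearest bins (out-of-range pool sequences are used only as
filler). Probability calls are strictly greater-than the threshold;
retention thresholds of 0.7 (putative) and 0.8 (final positives) are the
pipeline's conventional operating points, while tests evaluate at 0.5.

`confusion_metrics()` reports the standard confusion-matrix rates as percentages.
Undefined ratios return `NaN` with a warning rather than an error, so a
degenerate confusion table cannot silently halt a report.

## Alignment and subfamily assignment

`local_align()` is the standard three-state affine-gap Smith–Waterman
(default BLOSUM62, gap open 11, extend 1; a length-L gap costs
open + L·extend). Raw scores convert to bit scores and e-values with the
published gapped-BLOSUM62 Karlin–Altschul constants λ = 0.267, K = 0.041;
composition-based adjustment is deliberately omitted. The database length
in the e-value is the total residue count of the reference set.

`best_hit_assign()` keeps the lowest-e-value hit if it is strictly below
1e-6, breaking ties by raw score then lexicographic target id — so
assignment is invariant to reference ordering. The fractional bit-score
filter keeps hits strictly above `fraction` × best (75% or 80% depending
on family conservation); the best hit itself is always kept, which is the
only sensible reading at fraction = 1. An HMM-based ortholog-screening
stage would use profile scores here; the package substitutes alignment bit
scores under the same fractional-threshold rule, which is an approximation
the documentation flags.

## TE overlap resolution and gene–TE intersection

RepeatMasker-style annotations double-count fragmented elements. The
resolution pass works on same-scaffold, same-strand records sorted by
start: simple/low-complexity records are discarded first; pairs that
overlap or lie within 10 bp are candidates; if the overlap covers at least
80% of the *longer* element the pair merges into its union, inheriting
family, class and divergence from the lower-divergence member; overlapping
candidates failing the coverage test keep only the lower-divergence
member; near-adjacent non-overlapping candidates keep both. The pass
iterates to a fixpoint, making it idempotent. Two ambiguities in the
verbal rule are exposed as flags: `both_fractions` applies the coverage
test to both members rather than the longer one, and
`keep_both_unresolved` retains both members of an unresolvable overlap
instead of dropping the worse one. Divergence is percent-to-consensus;
only its ordering matters to the tie-breaks.

Intersection uses 0-based half-open arithmetic throughout (GFF3 converts
on read/write). A TE counts for a gene at ≥ 1 bp overlap with the gene
span, contributes its span-clipped length, and is tagged exonic — and
excluded from the intronic summary — if it touches any exon, because
intron TE accumulation is what the summary tables describe. Cluster
detection is single-linkage chaining with a 10 kb gap, the upper end of
observed AMP cluster extents; chains of one are singletons, not clusters.

## Phylogenetic hierarchical regression

The model for gene length is

$$\log(\mathrm{len}) = b_0 + b_1\,\mathrm{exons} + b_2\log(\mathrm{TE\ len}+1)
 + b_3\,\mathrm{TE\ count} + u_{sp} + v_{fam} + e,$$

with $u \sim N(0, \sigma^2_s A)$, $v \sim N(0, \sigma^2_f I)$,
$e \sim N(0, \sigma^2_e I)$. $A$ is the relatedness matrix: shared
root-to-MRCA path length over tree depth, unit diagonal, positive
semidefinite by its Gram structure; it requires an ultrametric tree
(tolerance 1e-6 on tip-depth spread). The `log(x + 1)` transform keeps
genes without TEs in the model; it is recorded in the fitted object.

Every conditional is conjugate, so the sampler is blocked Gibbs with no
Metropolis steps: a 4-dimensional normal draw for the coefficients, one
multivariate normal per random-effect block (the species block uses the
precision $A^{-1}/\sigma^2_s + \mathrm{diag}(n_s)/\sigma^2_e$), and
scaled-inverse-gamma draws for the variances. Priors are weakly
informative: N(0, 1e8) on coefficients and inverse-gamma(0.001, 0.001)
(ν = 0.002, V = 1) on variances, the common default of animal-model MCMC
software; both are arguments. The production run configuration defaults to
1,000,000 iterations, burn-in 1,000, thinning 500; tests and the
acceptance script use 20,000/1,000/10, which the recovery checks show is
ample at their data sizes. HPD intervals are the shortest window holding
⌈0.95·n⌉ sorted draws (ties to the smaller lower bound); ESS uses Geyer's
initial-positive-sequence truncation of the autocorrelation sum. Variance
partitioning (a marginal R²) can be computed from the chains but no
reference value is asserted for it.

## Birth–death gene-family-size models

The transition probability of the critical linear birth–death process has
the closed form given in the README; it is validated against a
matrix-exponential of the truncated generator to 1e-8. The likelihood is
Felsenstein pruning with per-branch transition matrices, built vectorised
over the whole (parent, child) grid. Choices:

* **Root prior** — uniform over 1..max observed count (the convention of
  family-size software), or a point prior via `root_count`.
* **Truncation** — ancestral states are truncated at `max_count`
  (default 50, never below twice the observed maximum). Leakage is
  monitored on the lower half of the state space — the states the prior
  and tips can occupy — because the top rows of any truncated chain lose
  mass by construction; if it exceeds 1e-6 the bound doubles with a
  warning. During optimisation the bound is held fixed so a wild proposal
  cannot trigger runaway growth.
* **Among-family variation** — K equal-probability mean-one discrete-gamma
  categories (Yang-style category means; cross-checked against phangorn),
  averaged per family.
* **Observation error** — with probability ε a tip count is off by one,
  symmetric, clamped at zero; ε defaults to 0 and can be estimated.
* **Optimisation** — Nelder–Mead (or golden-section in 1-D) on
  log-parameters with 30 random restarts by default, all restart
  log-likelihoods kept so convergence across runs is inspectable. The
  headline two-model comparison uses df = 2.

`branch_changes()` computes MAP ancestral counts by max-product pruning
and per-family Monte-Carlo p-values: the fraction of null families
(simulated under the fitted model) whose log-likelihood is at most the
observed family's. These p-values are conservative at ties — the statistic
is discrete — which the calibration test accounts for by randomised
tie-breaking. The species-overlap duplication criterion labels a gene-tree
node a duplication when the Jaccard overlap of its child clades' species
sets is at least 0.5.

## What the synthetic data emulate — and what they do not

The generators produce every input with the structure the analyses assume:
a Yule tree rescaled to unit depth (ultrametricity is the only property
downstream stages need); family counts forward-simulated by the exact
geometric-offspring representation of the same birth–death process the
likelihood fits; motif-bearing peptides (six cysteines with 2–12 residue
spacers; four with 3–15) against a uniform-composition background with a
broader length law (uniform on [10, 400]); multi-exon gene models whose
CDS reverse-translates the generated peptides, with exon-count mixes at
the published per-family proportions (e.g. 85% two-exon β-defensins) and
deliberately overlapping TE pairs, intergenic TEs and simple repeats to
exercise resolution; and regression tables drawn from the hierarchical
model itself with the reported posterior means (5.083, 0.120, 0.436,
−0.030) as default truth. Default variance components (σ²ₛ = 0.2,
σ²_f = 0.05, σ²_e = 0.1) were chosen once as values a comparative analysis
of log gene lengths would find plausible — species signal a few times the
residual scale, family differences smaller. TE divergences are uniform on
[0, 40]%, spanning typical annotation divergences; only their ordering
matters to resolution.

Every generator is a pure function of its configuration including the
seed; the same seed yields byte-identical output.

Two honest limitations. First, a uniform amino-acid background is a weak
null: at lengths up to 400 it contains six-plus cysteines often (so a pure
count criterion cannot separate classes) and even the spacing grammar
appears in ~7–8% of background sequences at the default seed — the tests
pin that measured rate rather than a wished-for smaller one. Second, the
synthetic data contain none of the hard parts of real annotation — no
misassembly, no fragmented gene models, no compositional bias, no
alignment ambiguity — so passing tests demonstrate the correctness of the
computations, not the field performance of the pipeline on real genomes.

## Problem sizes used by the tests and acceptance script

The recovery and calibration checks run at deliberately desk-scale sizes,
chosen as the smallest at which the asymptotics they test are expected to
hold: rate recovery on 500 families × 10 species; LRT size under the null
on 200 replicates of 100 families × 5 species; HPD coverage on 50
datasets of 20 species × 30 genes at 20,000 iterations; alignment oracles
on strings up to length 6. The acceptance script's stochastic quantities
(classifier operating point, rate and coefficient recovery) rerun the full
synthetic pipeline at those sizes under the seed given on the command
line.
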