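---
title: "Methods: branch-site selection tests and convergence screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-site selection tests and convergence screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`subterra` implements a two-pronged screen for parallel molecular
adaptation across independent lineages on a species tree: branch-site
tests for positive selection on designated foreground branches, and
posterior probabilities of parallel/convergent amino-acid substitutions
between branch pairs. This vignette is the package's own account of the
models, the numerical choices, and what the simulation-based validation
does and does not establish.

## The substitution models

**Codon model.** The 61 sense codons of the universal code evolve by a
reversible Markov process in which only single-nucleotide changes have
positive rate: `q_ij ∝ π_j`, multiplied by `κ` for transitions and by `ω`
for nonsynonymous changes. Equilibrium codon frequencies default to F3×4
(position-specific nucleotide frequencies estimated from each alignment,
add-one smoothed), with F1×4 and F61 available; the choice follows common
branch-site practice. Rate matrices are diagonalised through the
symmetrised form `diag(√π) Q diag(1/√π)`, so one eigensystem serves all
branch lengths; this is numerically stable for reversible models and
makes `P(t) = exp(Qt)` a pair of 61×61 matrix products.

**Amino-acid model.** Ancestral reconstruction for the convergence stage
uses the published Dayhoff exchangeabilities and frequencies, scaled to
one expected substitution per site per unit time, with an optional
"+F"-style empirical-frequency mode (add-one smoothing with a warning
when a residue is unobserved).

**Missing data.** Gaps, `N` and `X` are treated as fully missing (partial
likelihood 1 over all states); other IUPAC codes expand to their
compatible state sets, and codons whose expansion contains only stop
codons are treated as missing. An all-gap column therefore contributes
exactly zero log-likelihood — one of the unit-test identities.

## Branch-site Model A and its null

Model A has four site classes with proportions

    p0                      omega0 everywhere (0 < omega0 < 1)
    p1                      omega1 = 1 everywhere
    p2a = (1-p0-p1) p0/(p0+p1)   background omega0, foreground omega2
    p2b = (1-p0-p1) p1/(p0+p1)   background 1,      foreground omega2

with `omega2 >= 1` free in the alternative and fixed to 1 in the null;
the test statistic is `2(lnL_alt - lnL_null)` (clamped at zero — the
models are nested, so negative values are numerical noise) against a
chi-square with 1 degree of freedom, significance at p < 0.05. Because
the null places `omega2` on the boundary of the alternative's parameter
space, the chi-square reference is conservative; the null-calibration
experiment below confirms rejection rates at or below the nominal level.

**Fitting strategy.** Writing `c = p0 + p1` and `r = p0/(p0+p1)`, the
four class weights factor as `(cr, c(1-r), (1-c)r, (1-c)(1-r))`. Class
site-likelihoods do not depend on the proportions, so for fixed
`(omega0, omega2)` the proportions are profiled out by a closed-form EM
(deterministic start `c = 0.85, r = 0.6`, tolerance 1e-8). The outer
optimisation is then only 2-dimensional (1-dimensional for the null,
solved by Brent search); it runs L-BFGS-B from three deterministic
starts, one of which is the null optimum with `omega2 = 1` — this
guarantees `lnL_alt >= lnL_null` by construction. `kappa` and a single
tree-scale factor are estimated once per gene under the one-ratio M0
model (itself fitted by L-BFGS-B from three deterministic starts on the
log scale) and held fixed in both Model A fits; this two-step scheme
trades a small amount of likelihood for a large, predictable saving and,
because both models share it, does not disturb the nesting that the LRT
relies on. Per-class rate matrices are used unscaled, with the time
units absorbed by the tree-scale factor.

Each outer evaluation needs one inside-outside pass at `omega_bg =
omega0` — the `omega_bg = 1` pass is cached across evaluations because
`kappa` and the scale are fixed — after which any foreground `omega2`
costs only a single extra transition matrix on the foreground branch:
the class likelihood is `sum_a sum_x Out[a] P^{fg}_{ax} In[x]` with the
outside and inside partials already in hand.

**Empirical-Bayes site identification.** NEB plugs the MLEs into the
per-site class posteriors. BEB averages them over a discrete uniform
prior grid: 10 midpoint categories for `omega0` on (0,1), 10 for
`omega2` on (1,11), and the 45 midpoint pairs `(p0, p1)` with
`p0 + p1 < 1`; each gridpoint is weighted by its posterior given the
whole gene. BEB is the default for reported sites (PP > 0.5), NEB the
cheaper option. A PSS is called only when the gene passes p < 0.05 and
`omega2 > 1`.

**Aggregation filter.** Genes whose called PSSs cluster tightly are
flagged as likely alignment errors: with sites sorted, the gene is
excluded when the median successive interval is ≤ 10 amino acids. Genes
with fewer than two PSSs have no interval and are retained — the rule
targets clustering, which is undefined below two sites. Downstream gene
sets are gated on raw p < 0.05 (the screen tests a priori hypotheses);
BH-FDR-adjusted values are reported alongside but not used as gates.

## Convergence between branch pairs

For each gene the codon alignment is translated and branch lengths are
re-fitted under Dayhoff on the protein alignment (coordinate-wise Brent
sweeps; the inside/outside partials are refreshed before every branch so
the sweep is Gauss-Seidel, and sweeps stop when the log-likelihood gain
drops below 1e-4). These fits are independent of the codon-stage fits —
the two stages answer different questions in different state spaces.

For a branch `e = (u, v)` the inside-outside pass yields the exact joint
posterior `J[a, x] = P(parent = a, child = x | data)` per site. For a
pair of branches the sitewise convergence probabilities combine the two
joints under an independence (product) approximation:

    pp_parallel   = sum_x sum_{a != x} J1[a,x] J2[a,x]
    pp_total      = sum_x (sum_{a != x} J1[a,x]) (sum_{b != x} J2[b,x])
    pp_convergent = pp_total - pp_parallel

The product form ignores the correlation induced by the path connecting
the two branches. The exact four-endpoint joint (computed by exhaustive
enumeration over internal-node states) is retained both as a validation
oracle and as `site_convergence_pp_exact()` for small trees; on trees
where the branches are separated by at least two edges the product form
agrees with it to ~1e-3, which is the regime of the intended use
(lineages in different clades). For adjacent branches the approximation
error is larger — that configuration is also excluded by the
non-overlap precondition on branch pairs.

Per gene and pair the screen reports summed total PP with the two-tier
thresholds (≥ 1.0, chosen as roughly one convergent site, and ≥ 2.0) and
the count of individual sites with PP > 0.5. "Most ancestral pairwise
comparison" is operationalised as the stem branch of the clade's MRCA in
each gene's pruned tree; a single present member yields its terminal
branch. Sites with missing data are still scored — missingness enters
through the likelihood, no masking.

## QC gates and coordinates

Sequence-level, in order: remove sequences with > 50% `N`; pad
incomplete final codons with `N`; remove sequences with an in-frame
internal stop; remove sequences < 150 nt. Alignment-level: remove codon
columns (whole triplets, preserving frame) in which more than half the
taxa are gapped; then remove sequences left with < 50 non-gap codons;
keep the alignment only if strictly longer than 100 codons. Gene-level
taxon gate: exclude when no outgroup taxon, no focal taxon, or fewer
than 4 taxa. All result coordinates are 1-based positions in the trimmed
alignment. External aligner confidence scores (e.g. GUIDANCE column
masks) are accepted as pre-applied input and not recomputed — only the
gap-fraction and length rules are re-applied here.

## Set statistics and GO enrichment

The m-way intersection of fixed-size random subsets of a background of
size N has an exact distribution obtained by iterated hypergeometric
conditioning (`|S1 ∩ S2|` is hypergeometric; condition on it for `S3`,
and so on); the test reports the expected size `N·Π(n_i/N)`, fold
enrichment, and the upper-tail p of the observed overlap. For m = 2 the
distribution is identically hypergeometric, and its mean matches the
product formula to 1e-9 — both tested.

GO enrichment runs on a user-supplied or simulated term DAG after
true-path propagation. `classic` is an independent one-sided Fisher test
per term. `elim` processes terms from the deepest level upward and
removes the genes of significant terms (internal cutoff 0.05,
configurable) from their ancestors before testing them. `weight` is
implemented as a ratio-weighting variant in the same family: when a
child is more significant than its parent, the child's genes are
down-weighted in the parent and its ancestors by the ratio of
log-significances; it is deterministic and demotes parents whose signal
is explained by a child, but it is a documented variant rather than a
reimplementation of any specific published weighting schedule. classic
p-values are deliberately not FDR-adjusted (the DAG makes terms
non-independent; the topology-aware algorithms are the multiplicity
control).

## The synthetic-data generator

`simulate_gene()` draws root codons from the equilibrium frequencies,
assigns each site a class, and evolves sites along branches by exact
CTMC transition probabilities, the foreground branch switching to the
class's foreground omega. Branch lengths are interpreted as expected
substitutions per codon averaged over the site classes (background
omegas). `inject_convergent_sites()` forces a common derived amino acid
at the child nodes of a branch pair and re-simulates the two subtrees
conditional on the forced states (rejection over eligible sites: equal
ancestral amino acids for parallel mode, different for convergent);
everything outside the two subtrees is untouched, so detection
experiments are fair. `make_study_fixture()` assembles the full study
design: a fixed 41-taxon topology with four focal clades (sizes 2, 8, 4,
1), four control branch sets, primate and non-placental outgroups;
branch lengths are drawn once from a seeded exponential with mean 0.06
substitutions/site (published per-branch lengths are not available, so
the lengths are a documented synthetic choice); defaults are 200 genes ×
300 codons, 10% of genes with foreground selection (omega2 = 4), 5%
with five injected parallel sites, 10% per-taxon dropout. All
generators are pure functions of (specification, seed).

What the generator does **not** emulate: alignment error and indels
(sites are always homologous), assembly artefacts and chimeras,
among-site rate variation beyond the four-class mixture,
non-stationarity, and selection regimes outside Model A. Passing the
validation experiments therefore shows that the estimators recover what
the models define on model-conforming data — not that real alignments
satisfy those models. The aggregation filter, for example, exists
precisely because real data violate the homology assumption.

## Validation experiments and the sizes used

The test suite validates the numerical core against independent oracles:
exhaustive enumeration over internal-node states (with transition
matrices from `Matrix::expm` where precision allows full independence),
closed-form two-taxon likelihoods, golden-section search for scalar ML,
`phangorn` for a Dayhoff likelihood cross-check, and full subset
enumeration plus Monte-Carlo for the intersection distribution.

The simulation experiments ship as package functions with reference
defaults reflecting the screen's calibration conditions
(`calibrate_null_lrt`: 200 genes × 500 codons; `power_experiment`: 50 ×
1000; `convergence_detection_experiment`: 20 × 300 with 5 injected sites
at branch length 0.1; `branchlength_trend_experiment`: 5 lengths × 50
genes). The automated tests and the acceptance script run the same
experiments at reduced sizes chosen once for turnaround — 60 × 250 for
null calibration, 30 × 400 for power, 20 × 300 for detection, 10
genes/point for the trend — with thresholds computed from the
corresponding binomial/rank formulas at the sizes actually used (e.g.
the null rejection rate must not exceed 0.05 + 3·SE with SE evaluated at
n = 60). Exhaustive-enumeration oracles run on 4–6-taxon instances
(codon enumeration on 4 taxa, where 61^3 internal assignments are
tractable); the pruning algorithm contains no size-dependent branches,
so small-tree equivalence validates the algorithm as such.

## Numerical choices and degenerate inputs

* Per-site scaling in all pruning passes (and log-scale bookkeeping in
  both inside and outside passes) prevents underflow on long trees.
* `P(t)` entries are clamped at 0 and rows renormalised to remove
  round-off negatives from the eigensystem reconstruction.
* Impossible site patterns (likelihood 0) are guarded so a single bad
  site yields `-Inf` log-likelihood rather than NaN propagation.
* Optimiser failures mark the gene `flagged`/quarantined rather than
  aborting a batch; reruns skip completed genes (the output TSV is the
  checkpoint).
* Trees with all-zero branch lengths trigger a warning in ancestral
  reconstruction (posteriors collapse to tip states, which is the
  correct limit and is tested).
* Ties and degenerate trend inputs: zero variance in branch lengths is
  flagged as undefined; zero variance in counts returns a zero
  correlation by convention.

## Known limitations

* Branch lengths for the codon stage are rescaled by a single factor
  from the M0 fit rather than refitted per model; per-branch refits
  under Model A would be slower and are not implemented.
* The BEB grid is the standard 10-category discretisation; posteriors
  for genes with very high omega2 can be sensitive to the (1, 11) grid
  range.
* The product-form convergence PP should not be trusted for adjacent
  branch pairs (see above).
* The `weight` GO algorithm is a faithful-variant, not a re-derivation;
  `classic` and `elim` are exact to their definitions and are the ones
  validated by constructed fixtures.
* No gamma rate variation, non-reversible models, or tree topology
  search; the species tree is an input, never estimated.
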