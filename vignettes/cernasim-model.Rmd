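---
title: "The cernasim model: expression-weighted miRNA redistribution in ceRNA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cernasim model: expression-weighted miRNA redistribution in ceRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernasim)
```

## The model

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNAs: because
a miRNA molecule bound to one target is not available to repress another, the
abundance of any single target modulates the repression felt by all of its
co-targets (the "sponge" effect). `cernasim` models this competition on a
bipartite network of miRNA nodes and gene nodes, each carrying an expression
value in one common, arbitrary abundance unit (normalized counts work well).

The central quantity is the **repression count** `RC[i,j]`, the share of
miRNA `j`'s expression sequestered by target `i`:

    RC[i,j] = Exp(miRNA_j) * (AF[i,j] * Exp(Target_i)) /
              sum over targets k of j ( AF[k,j] * Exp(Target_k) )

Each miRNA's expression is therefore divided completely among its targets —
conservation `sum_i RC[i,j] = Exp(miRNA_j)` holds exactly by construction —
in proportion to affinity-weighted target abundance. The per-edge **affinity
factor** `AF = E' * STE'` combines normalized binding free energy and
seed-type effect and acts *before* binding: it changes how much miRNA an edge
sequesters. The normalized **region effect** `RE'` acts *after* binding: the
total repression a gene experiences is

    R[i] = sum over miRNAs j targeting i ( RC[i,j] * RE'[i,j] )

so a site in a weakly-degrading region can sponge miRNA away from co-targets
without itself being strongly degraded. With all factors neutral (absent),
both formulas collapse to plain expression-proportional sharing.

### Factor normalization

Raw factors are mapped to `(0, 1]` so the most favourable value gets weight
1: binding energies (all `<= 0` kcal/mol) are divided by the most negative
energy in the edge table, and the seed/region multipliers are divided by
their column maximum. This choice preserves the ordering of the raw values,
collapses to the unweighted model when a column is uniform, and treats a
missing value on an individual edge as neutral (weight 1) — absence of
evidence about a binding site should not erase the interaction. A column
that is entirely constant carries no contrast and is normalized to all 1
with a warning. Other monotone rescalings are defensible; this one was
chosen for its simplicity and its exact reduction property, which the test
suite asserts.

## Perturbation propagation

The network is assumed to start at steady state, under three simplifying
assumptions: miRNA transcription and degradation are balanced, miRNAs are
recycled (targets are degraded, miRNAs are not consumed), and target
transcription/degradation rates are likewise balanced. No kinetic rates are
modelled; this is what makes genome-scale networks tractable, at the price
of not predicting absolute expression dynamics.

A **trigger** multiplies the expression of one or more nodes by a fold
change (`fold > 1` up, `0 < fold < 1` down; triggering a miRNA is allowed
and scales its distributable expression). Propagation then iterates:

1. recompute every `RC[i,j]` from current expressions;
2. update each gene synchronously by the repression it gained or lost:
   `expr_new = max(0, expr_current + (R_prev - R_new))`;
3. repeat.

The update rule is the discrete statement that repression released by a
competitor becomes available transcript, and it makes the untriggered steady
state an exact fixed point (asserted to 1e-12 in the tests). Synchronous
updates keep the result independent of node ordering. The `max(0, .)` clamp
prevents negative abundances under strong down-triggers. Iteration stops
when the largest per-gene change in a cycle drops below `tolerance`
(default 1e-6 expression units, absolute) or after `max_cycles` (default
30); hitting the cycle cap is reported as non-convergence, not an error, and
the per-cycle maximum-change series is exposed so non-monotone settling can
be inspected. On the fixtures used here convergence takes well under ten
cycles; the dual stop bounds runtime on pathological inputs.

### Perturbation metrics

After convergence every node's percent change relative to its *pre-trigger*
expression is computed. Nodes at or above the `limit` (default 0.1%) count
as **perturbed**; the **perturbation efficiency** is the mean absolute
percent change over those nodes. The trigger itself is always excluded —
its change is imposed, not propagated. The limit has no privileged value in
the model; it is a required, surfaced parameter because the perturbed count
is only meaningful relative to it.

## Screening and significance calibration

`screen_all_nodes()` runs one full simulation per node (default trigger:
three-fold increase) and tabulates perturbed counts and efficiencies;
`screen_cohort()` repeats this over per-sample expression overlays of one
shared interaction template, which is how patient cohorts are represented.

Across a cohort, the pooled perturbed-count distribution is typically a
mixture of a broad low-impact background and a high-impact tail. To turn
this into cutoffs, `fit_significance_threshold()` fits a finite Gaussian
mixture (2 components by default, EM via **mclust**, deterministic given the
data) and takes as the count cutoff the smallest value whose posterior
probability of belonging to the highest-mean component exceeds 0.5. The
sample cutoff is derived sequentially by the same rule from the per-node
distribution of "samples reaching the count cutoff". Gaussian components on
raw counts are the simplest family matching the screening output; the
component count is a parameter, and the statistic fitted can be switched to
efficiencies. When EM cannot separate components (identical counts,
component collapse, no posterior crossover) the cutoff falls back to the
95th percentile with a warning. `select_significant_nodes()` then keeps
nodes passing the count cutoff in at least the required number of samples
and, given sample group labels (e.g. tumour/normal), labels nodes
significant in exactly one group as group-specific.

## Fixtures and what the synthetic data does (not) show

`make_sample_network()` is the package's fully worked eight-node example:
M1 (expression 1,000) targets G1–G4 (10,000/10,000/5,000/10,000), M2 targets
G4–G6, so G4 bridges both neighbourhoods. M2's expression and the G5/G6
expressions are not constrained by the worked example's printed numbers and
are fixed here at 1,000 and 10,000; they do not affect the M1-neighbourhood
arithmetic. `make_sample_plus_network()` attaches synthetic interaction
factors (energies in [-25, -8] kcal/mol, multipliers in {0.5, 1}) chosen by
this package; they demonstrate factor weighting, not any published dataset.

`random_cerna_network()` draws seeded bipartite networks with log-normal
expressions (genes: meanlog `log(5000)`, sdlog 1; miRNAs: meanlog
`log(1000)`, sdlog 1 — right-skewed abundances spanning orders of magnitude,
as in RNA-seq), and `make_cohort()` overlays per-sample multiplicative
log-normal noise (default sdlog 0.25, roughly ±25% sample-to-sample
variation) with an optional planted fold-shift on designated nodes in half
the samples. The tests and the acceptance script use cohorts of 20 samples
on networks of 30 genes and 6 miRNAs, and mixture calibration benchmarks of
1,000 pooled counts — sizes at which every pipeline stage runs in seconds
while leaving the planted signal recoverable.

Synthetic cohorts share none of the structure that makes real expression
data hard: no correlated noise between co-regulated genes, no library-size
or batch effects, no uncertainty in the interaction edges themselves, and
log-normal rather than count-based noise. Passing tests therefore show that
the machinery is arithmetically correct and that the calibration recovers
signals *of the planted kind*; they do not certify performance on real
patient data, where edge quality and normalization dominate.

## Numerical choices and limitations

- All arithmetic is double precision; rounding to integers happens only in
  displays and serialized output (6 significant digits in TSV writers).
- A miRNA whose whole target pool is at zero expression distributes nothing
  (free miRNA) instead of dividing by zero; the affected miRNAs are flagged.
- Ties in screening tables are resolved by node id so all outputs are
  byte-deterministic; any parallel execution strategy must reproduce the
  sequential table exactly.
- The model is deterministic and steady-state: no molecule-count noise, no
  miRNA decay, no transcription-factor feedback, no prediction of
  miRNA:target pairs (interactions are inputs). Down-stream enrichment or
  disease-association analyses are out of scope; networks can be exported
  to GraphML/SIF for external tools.
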