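---
title: "Walk-based negative sample selection for drug side-effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walk-based negative sample selection for drug side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrneg)
```

## The problem

Treating drug side-effect prediction as binary classification requires
labeled pairs on both sides. Databases such as SIDER record only the
positives — pairs (drug *d*, side effect *s*) where *d* is known to cause
*s*. Everything else is unlabeled, not negative: many unrecorded pairs are
simply associations nobody has validated yet ("latent positives"). Sampling
negatives uniformly from the unlabeled pairs therefore contaminates the
training set, and the contaminated pairs are precisely the ones that look
most like positives — the worst possible label noise.

`rwrneg` implements a network-based selection that keeps only pairs a drug
interaction network argues *against*. The premise is that interacting
chemicals tend to share properties, side effects included. If a drug sits
far — in the random-walk sense — from every drug known to own a side
effect, the pair is a high-confidence negative.

## The selection procedure

The drug network has one node per drug; two drugs are adjacent when they
share a chemical–chemical interaction with a positive combined evidence
score (an integer in 1–999 in the STITCH convention), and the edge carries
that score as its weight. For each side effect *s*, the drugs owning *s*
form the seed set. The walk iterates

$$p_{t+1} = (1-\lambda)\, M \, p_t + \lambda\, p_0,$$

where $M$ is the column-stochastic transition matrix (each adjacency column
divided by its sum), $p_0$ is uniform over the seeds, and $\lambda$ is the
restart probability. Iteration stops when the $L_1$ change falls below
$\theta$. Defaults are $\lambda = 0.8$ and $\theta = 10^{-6}$, the values
standard in network-propagation work; $\lambda$ this large keeps mass near
the seeds, so probabilities decay quickly with network distance.

A note on the update operator: the propagation literature often writes the
update with a transposed normalized adjacency matrix. For a symmetric
weight matrix, transposing a column-normalized matrix yields a
row-stochastic operator that does not conserve probability mass. We use the
column-stochastic $M$ applied on the left, the mass-conserving form: when
every node reachable from the seeds has at least one edge, $\sum_i p_i = 1$
at every iteration. Columns of isolated nodes are left all-zero rather than
given self-loops; mass can only sit on an isolated node if it is seeded
there, in which case the total mass converges below one. Both behaviours
are tested.

Drugs with stationary probability at most $\varepsilon$ are paired with *s*
as candidate negatives; drugs owning *s* are excluded regardless. The union
over all side effects is the negative set NDS($\varepsilon$). Inclusion is
$p \le \varepsilon$, not strict: the meaningful base case
$\varepsilon = 0$ selects exactly the drugs with *no path* to any seed,
which a strict inequality would leave empty. Both solvers produce exact
structural zeros for unreachable nodes (the iterative one trivially, the
sparse direct solve because no fill-in connects separate components), so
the $\varepsilon = 0$ set equals the breadth-first-search unreachable set
— an equivalence the test suite checks against an independent graph
oracle.

Two solvers are provided: fixed-point iteration (capped at 10,000
iterations, with an explicit non-convergence flag — failure is observable,
never silent) and a direct sparse solve of
$(I - (1-\lambda)M)\,p = \lambda p_0$, which is exact, cannot be singular
for $\lambda > 0$, and doubles as the oracle for the iterative path.
Networks up to 2,000 nodes use the direct solver by default; per-side-effect
profiles are obtained from a single multi-right-hand-side solve.

## Threshold grids and parts

The canonical nine-threshold grid (0, 5e-7, 5e-6, 1e-5, 2e-5, 3e-5, 4e-5,
5e-5, 6e-5) is the package default. Negatives selected at the largest
threshold are graded into parts: part 1 is $[0, \varepsilon_1]$, part 2 the
open interval $(\varepsilon_1, \varepsilon_2)$, and part $i \ge 3$ the
half-open $[\varepsilon_{i-1}, \varepsilon_i)$. We reproduce these brackets
exactly as conventionally printed, which places the boundary
$\varepsilon_2$ in part 3; a probability equal to the final grid value goes
to the last part, since the selection at $\varepsilon_k$ includes it. The
grid's absolute values are calibrated to a real, sparse, ~800-drug CCI
network; on synthetic worlds whose probability scale is different,
`probability_grid()` instead takes 0 plus quartiles of the nonzero
non-positive-pair probabilities, ending at their maximum. That choice is
structural (it tracks the instance's own probability distribution) and is
made once, not tuned per experiment.

`score_distribution_diagnostic()` histograms the combined scores between
each selected drug and the owners of its paired side effect, per part, over
`n_bins = 10` equal-width bins spanning (0, 999]; the bin boundaries are
not dictated by any convention we know of, so equal width was chosen, with
zero scores (no direct edge) kept in their own bin or excluded on request.
Low parts showing all-zero score distributions is the structural signature
of high-quality negatives.

## The FIRE comparator

The FIRE-style strategy scores each non-positive pair by the strongest
*direct* edge between the drug and the side effect's owners and selects the
zero-score pairs. Only the zero/nonzero behaviour of the original score
matters for that selection, so the aggregation over owners (we use the
maximum) only needs to preserve "zero iff no direct edge", which it does
while staying order-independent. Zero walk probability implies no path,
hence no direct edge: NDS(0) is always contained in the FIRE selection,
while FIRE cannot grade its zero-score pairs any further — the walk can,
by distance. That containment and the graded refinement are both tested.

## Features and classifiers

Each pair (d, s) is encoded by five features, one per association channel:
the maximum similarity between *d* and the other drugs owning *s*
(`pair_feature()`), in fixed order fingerprint, structure, ATC, literature,
target. Fingerprint (Tanimoto over bit sets) and target-profile (cosine
over 0/1 vectors) similarities are computed natively; SIMCOMP structure
scores, ATC-code similarity and literature co-occurrence scores are
produced by external tools and are consumed as precomputed symmetric
matrices. Missing entries are zero ("no evidence"), under which the maximum
is well defined; when a side effect's owner set minus the drug is empty the
feature is 0 by convention (real data cleaning guarantees at least six
owners per side effect, so the case arises only in synthetic corners, but
it must be defined). Channels are used on their native scales — the
maximum is within-channel, so no cross-channel normalization is needed, and
any strictly monotone rescaling of a channel commutes with the feature map
(property-tested).

Classifier families sit behind `classifier_spec()`: tree ensembles
(`ranger`), max-margin (`e1071::svm`), and a single-hidden-layer
feed-forward network (`nnet`, hidden size 5 since the engine has no
default). Engine defaults are kept otherwise — hyperparameter tuning is
deliberately out of scope, since the claim under test is about negative
quality, not model tuning. Cross-validation is stratified with folds fixed
by seed and shared across families; the stratification is our choice (it is
not dictated by the tenfold convention) for variance control and
comparability. Point metrics use a 0.5 score cutoff; ROC and PR curves are
built at every distinct score threshold with trapezoidal areas, making
AUROC exactly the concordant-pair statistic (ties counted half); average
precision is available as an alternative PR integrator. A zero denominator
in any ratio metric yields 0 and is flagged rather than NaN.

## The synthetic world

`generate_world()` plants the structure the method presupposes, so that
every claim becomes auditable:

* drugs are split into communities; edges appear with probability `p_in`
  within and `p_out` between communities, with uniform integer weights in
  `weight_low:weight_high`;
* each side effect is carried by one or two communities; carrying-community
  drugs own it with probability `carriage_prob`. Carriers not emitted as
  positives are the planted latent positives; all other non-positive pairs
  are planted true negatives;
* similarity channels score `similarity_signal` plus noise within
  communities and at most `similarity_noise` between them.

Defaults: 300 drugs, 40 side effects, 6 communities, `p_in = 0.3`,
`p_out = 1e-4`, weights 150–999, `carriage_prob = 0.7`, signal 0.6, noise
0.1. `p_out = 1e-4` puts the expected between-community edge count (a few
edges) near the connectivity threshold, reproducing the fragmented regime
of real CCI coverage, where a fifth or more of drug/side-effect pairs have
no network path at all — without unreachable pairs the $\varepsilon = 0$
selection would be vacuous. Weights 150–999 mirror the typical reporting
range of combined scores; `carriage_prob = 0.7` leaves a realistic minority
of latent positives. Experiments in the tests and the acceptance script run
this default world (10 seeds for trend medians) plus smaller 90-drug worlds
for unit-level checks; at these sizes the full study completes in minutes
on one CPU.

What the generator does *not* emulate: heavy-tailed degree distributions,
overlapping communities, correlated channels, frequency-graded side
effects, and the biases of text-mining evidence. Passing tests on this
world show the machinery is correct and the qualitative claims
(purity ordering, threshold trend, FIRE containment) hold where the
planted premise holds; they do not certify performance numbers on SIDER- or
STITCH-scale data.

## What the study shows on synthetic worlds

With `p_out = 0`, purity of NDS(0) — the fraction of selected negatives
that are planted true negatives — is exactly 1, a graph-theoretic fact,
not a statistical one. With the default `p_out > 0` it stays above the
true-negative base rate. As $\varepsilon$ grows the selection admits pairs
ever closer to the seeds, latent positives pour in, purity falls, and the
median cross-validated MCC over the quantile grid declines; models trained
on NDS(0) beat models trained on equally many random negatives. These are
the package's qualitative analogues of the headline claims, recomputed from
scratch by `scripts/acceptance.R`.

## Degenerate inputs and numerical choices

Empty seed sets, side effects with no owner in the network, single-class
folds, probabilities beyond the grid, asymmetric similarity matrices
(beyond 1e-9), and non-integer scores all raise errors naming the culprit.
Duplicate interaction rows keep the maximum score (deterministic and
conservative; how ties were handled upstream in real files is unknowable).
Column sums of the transition matrix are exact to 1e-12; solver agreement
is verified to 1e-9 in the sup norm with the iterative tolerance tightened
to 1e-12 for that comparison. Identifiers are opaque strings throughout, so
synthetic and real data flow through identical code paths.
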