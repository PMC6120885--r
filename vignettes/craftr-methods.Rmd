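---
title: "craftr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{craftr: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craftr)
```

`craftr` turns a case/control expression study plus a signed regulome into
a ranked list of membrane-receptor drug targets. This vignette is the
package's account of the statistics it computes, the knobs that matter,
and the choices made where the design was genuinely open.

## Module discovery

The gene–gene dissimilarity is the Spearman distance d = 1 − ρ (average
ranks on ties), which is invariant under any strictly monotone per-gene
transform — the reason rank correlation is preferred for RNA-seq-scale
expression, whose per-gene distributions are heavy-tailed and
normalization-dependent. Constant genes have no rank variance and are
rejected by name; the expression filter (`filterExpressed`, strict
`> threshold` in at least `ceiling(minFraction · n)` samples, defaults 0
and 0.05 on log2-scale data) is expected to run first.

Ward clustering operates on these distances via `hclust`. Two Ward
variants exist for precomputed dissimilarities: the Lance–Williams
recurrence on d itself, and on d². We use the latter (`"ward.D2"`) so the
objective greedily minimized by the tree construction is the same
sum-of-squared-distances criterion the partition scan scores. That scan
evaluates, for each cut K,

* `WSS_c = (1/n_c) Σ_{i<j∈c} d²_ij`, a quantity well defined on any
  dissimilarity and equal to the centroid sum of squares whenever d is
  Euclidean-embeddable (the test suite checks this identity on embedded
  point clouds);
* `R² = BSS/(BSS + WSS)` with `BSS = TSS − WSS`;
* the Calinski–Harabasz pseudo F-index `(BSS/(K−1)) / (WSS/(n−K))` — the
  standard algebraic form of the pseudo-F cluster criterion.

For nested cuts of one tree, BSS + WSS = TSS holds exactly (asserted to a
relative 1e−9) and R² is non-decreasing in K.

**Choosing K.** The pseudo-F rule is the argmax. "Elbow" methods are
usually left informal, so ours is explicit and configurable: the selected
K is the smallest one after which the marginal gain ΔR² stays below
`elbowFraction` (default 0.01) of the total R² range for `elbowWindow`
(default 3) consecutive steps. `consensus` (the default) demands the two
criteria agree within ±2 and otherwise refuses with both candidates in the
error — on structureless data there is no stable K and the refusal is the
honest answer (the pipeline's `--select pseudoF` overrides it). Selections
on the scan boundary are flagged as unstable.

By default every gene is assigned to some module; a separate
"unclustered" bucket can be emulated post hoc by relabelling genes in
clusters below a minimum size, but since no principled size threshold
exists we do not enable one.

## Differential co-expression

The statistic is D = ‖r^case − r^control‖₂ over all within-module gene
pairs in a fixed (column-major upper-triangle) order. D is a pseudometric
on correlation profiles: zero on identical structure, symmetric, and
triangle-inequality-compliant.

The null redraws B gene sets of the module's size from the expressed-gene
pool and recomputes D — a *competitive* null asking "is this module's
co-expression change larger than that of a random same-size gene set?".
The empirical estimator p = (1 + #{D_null ≥ D_obs})/(B + 1) can never
return zero; B defaults to 1000 in the API (10,000 is the conventional
reference setting; tests use 200 for speed). An alternative null that
shuffles condition labels across samples is exposed via
`nullModel = "label"` for comparison; we default to redrawing because the
question is module-level and competitive.

**Calibration caveat.** When the tested module is exchangeable with the
pool (no shared factor, or one equally present in the pool), p is uniform
and the test holds its nominal level exactly — the acceptance suite
verifies a rejection rate within the exact binomial 99 % band around 0.05
at the exchangeable null. When the module carries a strong shared factor
that is *unchanged* between conditions, E[D] is essentially unchanged but
Var(D) is inflated by the correlation between pair estimates sharing
genes, and the test becomes mildly anti-conservative (we observed ≈
0.08–0.10 rejection at loading 0.4 on both conditions). Interpretation:
borderline q-values for highly coherent but unchanged modules deserve
caution; strong calls (q ≪ 0.05) are unaffected.

**Conservation across datasets.** Whether a module "replicates" in an
external (possibly cross-species, via a one-to-one ortholog map) dataset
is asked with a one-sided exceedance test: the statistic is the mean
absolute pairwise Spearman correlation of the mapped genes, against
equal-size random sets from the external data. A two-sample differential
test across species is a different question; both are available
(`conservationTest` vs `diffCoexprTest` after mapping) and reports should
name which was run.

**Sample-size grids.** `subsamplePower` draws stratified column subsets
per condition at each fraction, reruns the test, and repeats; seeds are
derived per (fraction, repetition) cell from one master seed so grids are
reproducible and embarrassingly parallel. Fractions leaving fewer than 4
samples per condition are skipped.

## Trait association

Module eigengenes are the first right singular vector of the
row-standardized module submatrix; values are unit-norm, zero-mean per
construction, and sign-oriented so the eigengene correlates non-negatively
with the module's mean standardized profile (with an all-positive loading
fallback when that mean is degenerate). Negating the data therefore flips
the eigengene; any trait association is unchanged in absolute value.

Gene- and module-level trait association uses Spearman's ρ with the
t-approximation for its two-sided p (the same approximation `cor.test`
applies with ties). Because squared rank correlation and linear-fit R² are
different summaries, `eigengeneTrait` reports both (`rho2`, `R2_trait` from
an ordinary least-squares fit of trait on eigengene). Trait association
uses case samples only by default — in the motivating disease setting the
controls have no phenotype variation (zero seizures) — and the QTT BH
family spans all tested genes genome-wide, not per module.

## Enrichment

All over-representation tests are upper-tail hypergeometric
(`phyper`, equivalently one-sided Fisher), exact and stable at
corpus-scale populations (millions of abstracts in the literature test).
Odds ratios get a 0.5 continuity correction only when a table margin is
zero and only for the reported ratio, never the p-value. Universes are
competitive and must be stated: expressed genes for cell-type markers,
expressed genes with at least one abstract for the literature module
ranking. BH families are per query for annotation scans and across
modules for module rankings, as labelled in each output.

## Causal reasoning

Signs compose along exactly two hops (receptor → TF → target); the
regulome's pathway layer is built from linear canonical pathways that
terminate at TFs, so deeper cascades are out of scope. The default
algebra is multiplicative — {+, −} with `unk` absorbing; associative with
`act` as identity. The published rule table contains one row
((inh, act) → activated) that contradicts sign multiplication and the
framework's own reversion logic; `signMode = "as_printed"` reproduces that
table literally so the original behaviour can be compared, and neither
mode silently "corrects" the other. A gene reachable through both an
activating and an inhibiting path legitimately sits in both target sets
and contributes to both effect tests.

The phrase "taking all genes under the control of the regulator as the
universe" does not parametrize a standard hypergeometric (the draw set
would equal the population), so the universe is configurable:
`regulome_targets` (default — expressed genes appearing as targets
anywhere in the filtered regulome), `expressed_genes`, or
`regulator_targets` (the literal reading: the sub-module's representation
inside the regulator's own target set is tested against the
regulome-wide rate). Every result names the universe used.

Classification at FDR α (default 0.05, BH across the full regulator ×
sub-module × direction family; receptors and TFs are separate families):
significant positive effect only → `act`; negative only → `inh`; both →
`uns`; neither → `ns`. Empty direction-specified target sets are recorded
as untested, never as p = 1. `activity` (k/n) and `weight` (k/K) come from
the classifying test; for `uns`, where both directions are significant, we
take the direction with the smaller q (tie → positive), a choice the
original rule leaves open.

Absolute ranking places defined effects (act/inh) above `uns`, excludes
`ns`, and orders within stratum by the ascending sum of activity and
weight ranks; remaining ties break by smaller classifying q, then
lexicographic id, making rankings fully deterministic. Relative ranking
greedily removes the covered sub-module genes of each picked regulator,
recomputes activity (residual overlap / target count) and weight
(residual overlap / residual size) and re-ranks, reporting cumulative
coverage — regulators adding nothing are appended with zero gain.
Intervention advice is pure signature reversion: `act` on an
over-expressed sub-module → blockade; `inh` on over → activation;
mirrored for under-expressed.

## Synthetic study conditions

The generator plants modules under a latent-factor model
x = λ_cond·f + δ·1[case, DE gene] + ε with f ~ N(0,1) per sample and
ε ~ N(0, σ). Within-module correlation follows the closed form
λ²/(λ² + σ²); with the default σ = 1 the loading is a signal-to-noise
ratio (λ = 0.8 → ρ ≈ 0.39; "strong" settings use σ = 0.5, λ = 0.9 → ρ ≈
0.76). Differential expression is an additive log-scale shift (default 1),
matching how the pipeline consumes DE as (direction, q) rather than any
count model. Traits are Poisson with log-rate `traitIntercept + β·f`
(default intercept log 3 ≈ three events per day), so the trait is a count
like a seizure frequency; the Spearman-based analyses make the link
function non-critical. The planted regulome wires one driver receptor
through dedicated activating TFs to a configured fraction of an
over-expressed sub-module, with uniformly random signed decoys and a
configurable fraction of signs degraded to `unk` (default 0.1). One RNG
stream per component (expression / regulome / citations) derives from the
master seed, so regenerating one component leaves the others untouched.

What the generator does **not** emulate: library-size and per-gene
overdispersion structure of real counts, correlated noise between
modules, hub-dominated regulome topology, batch effects, or annotation
error in edge signs. Passing tests on these conditions demonstrate the
statistics behave as designed — calibrated nulls, planted-effect
recovery, correct sign logic — not that any particular real dataset will
yield stable modules.

Test-suite problem sizes are the package's own choices to keep the suite
sharp: 60 + 60 samples (modules of 50–120 genes, pools of a few hundred),
B = 200 permutations and 10–40 replicates for simulation checks; the
subsampling check averages over 10 dataset realizations × 5 subsample
repetitions because a single realization makes the half-sample verdict a
property of one factor draw rather than of the effect size (the strongly
differential module is also planted in its own dataset there, since a
strong module elsewhere in the pool inflates the competitive null for a
weak one — a property users should keep in mind when interpreting
borderline modules in real data).

## Numerical notes

* Spearman correlations are computed as Pearson on average ranks; rank
  matrices are precomputed once per permutation test, and null redraws
  index into a precomputed pool correlation matrix when the pool has ≤
  4000 genes.
* Distances are clipped at 0 from below to absorb floating-point noise at
  ρ = 1; merge heights from Ward trees are monotone.
* Hypergeometric tails use `phyper` directly; at N ≈ 3.8 × 10⁶ this is
  exact in double precision (cross-checked against a log-space
  enumeration oracle in the tests).
* The BH step-up is implemented once (`adjustBH`) and verified against an
  independent reference implementation to 1e−12; NA p-values propagate
  without shrinking the family.
* Derived seeds use double arithmetic below 2³¹ to avoid 32-bit overflow.

## Known limitations

* The causal layer is two-hop and sign-only: no edge weights, no pathway
  context, no ligand/drug affinity modelling; `unk` edges are uninformative
  rather than marginalized over.
* The competitive permutation null is mildly anti-conservative for
  strongly coherent unchanged modules (see above) and its power depends
  on what else is in the pool.
* Eigengene summaries capture only the first principal component; modules
  with two comparable factors are under-summarized
  (`varianceExplained` is reported so this is visible).
* The elbow criterion is a declared parameterization, not an inference;
  on smooth R² curves consensus selection will (correctly) refuse.
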