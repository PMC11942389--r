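---
title: "Methods: network contribution index and metabolomics screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network contribution index and metabolomics screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## Scope

`herbnet` packages the computational core of a network-pharmacology plus
cell-metabolomics study of a two-herb formula: a differential-expression
screen over tumor/normal count data, an ADME filter and bipartite
component–target (C-T) network over herbal compounds, a degree-based
contribution index (CI) that ranks compounds, and a from-scratch
PLS-DA/OPLS-DA metabolomics screen with VIP scores, cross-validated Q²,
permutation validation and hypergeometric pathway over-representation.
Everything external — compound databases, target predictors, expression
repositories, raw spectra — is out of scope; seeded generators supply
inputs with the statistical structure each stage assumes.

## Differential-expression screen

Each gene is tested with a two-sided Wilcoxon rank-sum test between the
two groups, and its effect size summarised as
`log2((mean_case + c) / (mean_control + c))` on CPM-normalised counts
with pseudocount `c = 1`. A gene is flagged when `p < 0.05` **and**
`|log2FC| > 2`, both strict inequalities. No multiple-testing correction
is applied by default — the screen reproduces a fixed published
criterion — but `adjust = "BH"` switches flagging to
Benjamini–Hochberg-adjusted p-values for reuse.

The Wilcoxon p-value has two paths. The exact path enumerates all
`choose(n, n_x)` assignments of the pooled midranks, so it remains exact
under ties, and reports `2 * min(P(W <= w), P(W >= w))` capped at 1; it
is used automatically up to 16 pooled samples. The normal path uses the
midrank tie correction and a continuity correction of 1/2. On tie-free
data the exact path agrees with `stats::wilcox.test(exact = TRUE)` to
machine precision, and the normal path matches
`wilcox.test(exact = FALSE, correct = TRUE)`; both facts are asserted in
the test suite, keeping base R as an independent oracle rather than the
implementation.

The count simulation is gamma-Poisson: gene-level means drawn
log-uniformly over `base_mean_range` (default 10–1000), dispersion 0.1
(variance `mu + 0.1 mu²`), and a planted subset of genes whose
case-group mean is multiplied by `2^planted_log2fc`. The default planted
effect is `log2FC = 3`, comfortably above the screening threshold of 2,
with 50 + 50 samples — the scale of a tumor/normal expression cohort
reduced to desk size. What the generator does **not** emulate:
library-size variation between samples, gene–gene correlation, and
count–mean trends in dispersion. Passing recovery tests therefore show
the screen's arithmetic and calibration are right, not that it is robust
to every artefact of real sequencing data.

## Compound filter and C-T network

Compounds are kept when oral bioavailability ≥ 30 % and drug-likeness
≥ 0.18 (inclusive bounds, matching the conventional "≥" phrasing of
ADME screens). The C-T network is bipartite; its degree statistics are
the per-compound degree `Ci`, per-target degree `Pj` and total edge
count `Tedge`, with the identity `sum(Ci) = sum(Pj) = Tedge` asserted on
every build. Duplicate edges — one compound–target pair reported by
several prediction sources — count once. Compounds left without edges
are dropped before scoring, because the contribution index is undefined
on isolated nodes.

Herb attribution: `CAi` and `CBi` are the compound's degree attributed
to herb A and herb B. A compound claimed by both herbs carries its full
degree on both sides. This is a documented package choice: the
herb-contrast term below only makes sense with herb-attributed degrees,
and published descriptions do not fix the convention for shared
compounds.

## Contribution index

For compound *i* with degree `Ci`:

* edge share `omega_i = Ci / Tedge` (shares sum to 1);
* affinity `A_i = omega_i + |(CAi + CBi) / (CAi - CBi)|`, which is
  `omega_i + 1` for single-herb compounds;
* network effect `NE_i = Ci * A_i * sum(Pj over targets of i)`;
* contribution index
  `CI_i = 100 * (NE_i / sum(NE) + Ci / sum(Ci)) / 2`.

Three numerical choices deserve justification:

1. **The combining formula.** Printed linearly,
   "`NE_i/sum(NE) + Ci/sum(Ci) × 100`" admits readings that total 101
   or 200 across compounds. We average the two shares and scale by 100,
   so CI is a percentage summing to exactly 100 and a top-k cumulative
   CI reads directly as "k compounds carry x % of the network". The two
   literal readings stay available via
   `compute_ci(normalization = "literal")` and `"sum"` for comparison;
   their totals (101 and 200) are asserted in tests.
2. **Equal herb degrees.** When `CAi = CBi` the affinity denominator
   vanishes. The denominator is clamped to 1, making the term
   `CAi + CBi`: finite, monotone in the shared degree, and logged with a
   message whenever it fires. Single-herb networks never hit this rule.
3. **Summation range.** `NE_i` sums target degrees over the targets
   adjacent to *i* only — a compound's network effect must depend on its
   own targets.

Ties in the ranking are broken lexicographically by compound id for
determinism. `compute_ci` is checked against an independently coded
brute-force evaluation (no shared helpers) on hundreds of random
networks to 1e-9, and on a 3-edge toy network worked by hand:
compounds X (herb A, targets t1 and t2) and Y (herb B, target t2) score
CI = 72.81 and 27.19.

The network generator plants one herb-A "core" compound with degree 15
against Poisson(3) background degrees (zeros lifted to 1 so no compound
is isolated). The planted degree gap is what a dominant active compound
looks like in a small formula network; recovery tests ask that CI rank
the core first.

## PLS-DA, VIP and validation

Group membership is dummy-coded as a centered ±1 response and the model
fitted by NIPALS PLS1, deterministically (no random initialisation).
Default preprocessing is mean-centering plus unit-variance scaling per
metabolite — the convention of SIMCA-style software — with
log-transformation left to the caller; a constant variable under UV
scaling is an error naming the variable. Weight vectors are unit-norm
and score vectors orthogonal (checked to 1e-8); `R²X`/`R²Y` are
cumulative explained sums of squares and non-decreasing in the number
of components.

VIP uses Wold's formulation,
`VIP_j = sqrt(p * sum_a SSY_a w_aj² / sum_a SSY_a)`, whose mean square
is exactly 1 — the algebraic identity `sum(VIP²) = p` is asserted to
1e-8 on every fitted model, and the implementation is compared against
both a literal re-implementation of the formula and `mixOmics::vip`.

`Q²` comes from k-fold cross-validation with deterministic venetian
blinds (samples ordered by group then id, dealt round-robin; 7 folds by
default, never random): `Q² = 1 − PRESS/SSY`. Each training fold
recomputes its own centering and scaling; a variable constant within a
training fold keeps scale 1 rather than aborting the fold. A fold that
would empty a group is an error.

Permutation validation refits the model under label permutations. The
default verdict is `valid` when the original Q² exceeds the 95th
percentile of the permuted Q² values — a convention calibrated by
construction: on signal-free data the original statistic is exchangeable
with the permuted ones, so the verdict is `valid` about 5 % of the time.
The SIMCA-style intercept rule (regression of permuted Q² on label
correlation, intercept below 0.05) is available as an alternative
because published reports rarely state which rule produced "valid".

OPLS-DA removes one Y-orthogonal component (Trygg–Wold orthogonal
signal correction) before a one-component PLS-DA; if the orthogonal
weight norm is numerically zero the function falls back to plain PLS-DA
with a warning. S-plot coordinates are, per metabolite, the covariance
and the correlation of its (scaled) intensity with the predictive
score.

## Univariate screen and enrichment

Per metabolite, a Welch (unequal-variance) two-sided t-test and the raw
group-mean ratio `FC = mean(treated)/mean(control)`. The joint screen
keeps metabolites with `VIP > 1`, `p < 0.05`, and a fold-change
criterion that is **two-sided by default** (`FC > θ` or `FC < 1/θ`,
θ = 1): published panels report both increased and decreased
metabolites, so a literal one-sided `FC > 1` rule would discard every
down-regulated hit; it remains available via `fc_mode = "greater"`.
Whether published fold changes used means or medians, and whether data
were log-transformed before modelling, is generally unstated — the
defaults here (arithmetic means, no log) are documented so results are
reproducible either way.

The packaged 47-metabolite panel (formononetin-treated vs control HepG2
cells) runs through this screen unchanged: all 47 pass, 31 up and 16
down, which the acceptance suite asserts.

Heatmap ordering z-scores each metabolite and clusters rows and columns
by average-linkage on Euclidean distances — deterministic leaf orders,
zero-variance metabolites excluded with a warning. Pathway
over-representation is the one-sided hypergeometric tail
`P(X ≥ k)` via `stats::phyper`, checked against exact combinatorial
enumeration on small universes; it deliberately omits pathway-topology
impact scores.

The metabolite generator draws control means log-uniformly over
10³–10⁶ (LC-MS peak-area scale) and multiplies by log-normal noise with
a stated coefficient of variation (mean-one, so the planted group-mean
ratio is exactly `planted_fc`). Defaults — 200 metabolites, 10 + 10
samples, 10 planted at FC 4, CV 0.1 — describe a clean two-group cell
extract experiment. Real data add missing values, batch drift,
retention-time artefacts and correlated metabolite families, none of
which are simulated; null-calibration and recovery results should be
read with that in mind. One consequence worth knowing: because PLS
weights are proportional to the covariance between a metabolite and the
group code, VIP and the t-test p-value are strongly dependent under the
null, so the joint screen's null pass rate is close to the t-test's
alone (~5 %), not the product of marginal rates.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → deg → network → ci → metabo →
report from a validated YAML/list config (unknown keys rejected, all
violations reported together); every table is delimited text with a
header, every random draw flows from the config seed, and a rerun with
the same config is byte-identical. The test suite and the acceptance
script run the full stack at reduced but representative sizes — 500 to
10,000 genes, 36 compounds, 200 metabolites, 20–100 permutations —
chosen so the whole suite completes in well under a minute while leaving
the Monte-Carlo checks enough replicates to be meaningful.

## Known limitations

* CI is a topology score on a bipartite graph; it knows nothing of
  binding affinity, expression direction or dosage.
* The degenerate-affinity rule (`CAi = CBi`) and the "mean"
  normalization are package conventions for formulas whose printed
  forms are ambiguous; alternative readings are provided but produce
  different absolute numbers.
* PLS-DA here is two-class PLS1 only; multi-class designs and missing
  values are unsupported by design.
* The permutation verdict is a calibration convention, not a formal
  test of model truth.
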