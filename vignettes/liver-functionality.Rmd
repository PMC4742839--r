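---
title: "Scoring liver metabolic functionality from expression and flux data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring liver metabolic functionality from expression and flux data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

## The problem

Non-alcoholic fatty liver disease (NAFLD) alters what the liver *can do*
metabolically — gluconeogenesis, ureagenesis, ketogenesis, lipogenesis,
bile-acid and glycogen handling — but neither a transcriptome nor a handful
of measured splanchnic fluxes reports these capabilities directly. hepaflux
integrates both data types with a genome-scale metabolic model (GSMM): a
stoichiometric matrix $S$, flux bounds, and gene–protein–reaction (GPR)
rules. All analyses work on the steady-state flux polytope
$\{v : S v = 0,\ lb \le v \le ub\}$.

A *metabolic function* $i$ is a pair $(r_i, C_i)$: a target reaction $r_i$
(usually the one producing the function's end-product, e.g. glucose export
for gluconeogenesis) and a constraint set $C_i$ restricting the nutrient
environment (e.g. lactate as the only carbon source). The shipped catalogue
covers 22 key liver functions and is editable YAML.

## Expression integration and the two scores

Expression profiles enter through iMAT-style discretization: within each
sample, genes are ranked and the lowest `q_low` fraction is called *low*,
the highest `1 - q_high` fraction *high*, the rest *moderate* (defaults
0.25/0.75; ties broken by gene id). GPR rules map gene states to reaction
states with *and* = min, *or* = max over the ordered tri-states. The iMAT
MILP then finds a steady-state flux vector maximizing the number of
satisfied states, where a *high* reaction is satisfied iff it carries
$|v| \ge \varepsilon$ (either direction; $\varepsilon = 1$ model unit by
default) and a *low* reaction iff $v = 0$. The optimum $F_{ji}$ is the
consistency of sample $j$ with constraint set $C_i$.

Two complementary scores follow for every (sample, function) pair:

* **Activity** $A_{ij}/A_i$, where $A_i = \max v_{r_i}$ under $C_i$ and
  $A_{ij}$ is the same maximum with the expression fit pinned at its
  optimum $F_{ji}$. It asks: *how much of the function's capacity survives
  the observed expression state?*
* **Adaptability** $Fa_{ji}/F_{ji}$ (the MPA score), where $Fa_{ji}$ is the
  optimal expression fit when $r_i$ is *forced* active, by bounding its
  flux at half the maximal rate it can carry in the original,
  expression-unconstrained model. It asks: *how much of the expression fit
  must be sacrificed to run the function?* Low adaptability means the
  function requires substantial (post-)transcriptional rerouting.

Both are ratios in $[0, 1]$: the constrained optimum can never exceed the
unconstrained one.

### Design choices in the scores

* *Enforcement bound.* The enforcement level is $0.5 \times$ the target's
  maximal flux in the model **without** $C_i$ and without expression
  constraints. Under $C_i$ that demand can be unattainable; this is exactly
  the "cannot adapt at all" signal and is reported as adaptability 0 (with
  a warning). Calibrating on the $C_i$-constrained maximum instead would
  make enforcement tautologically feasible and erase that signal. For
  reversible targets the direction with the larger absolute capacity is
  enforced (ties broken forward).
* *Consistency pinning.* $A_{ij}$ is computed with consistency constrained
  to $\ge F_{ji}$, which at the MILP optimum is equivalent to pinning it
  exactly; an `alpha < 1` option relaxes this for sensitivity analysis.
* *Undefined scores.* A function whose unconstrained capacity is
  numerically zero ($A_i \le 10^{-3}\varepsilon$) is *blocked*; a sample
  with $F_{ji} = 0$ has no expression signal to trade. Both yield `NA`,
  excluded pairwise from group tests.
* *Discretization defaults* (`q_low = 0.25`, `q_high = 0.75`,
  $\varepsilon = 1$) follow common iMAT practice; they are parameters of
  `imat_settings()`, not constants.

## The flux arm

Measured splanchnic exchange fluxes (uptake negative, secretion positive,
in model units) are fitted by quadratic programming: the steady-state flux
vector minimizing the Euclidean distance to the measurements over the
measured reactions. The minimum distance is the *consistency score* — zero
exactly when the measurements are jointly feasible. The QP is unweighted by
default (an optional $1/\mathrm{sd}^2$ weighting exists); a Tikhonov ridge
of $10^{-8}$ (scale-aware) on all fluxes makes the quadratic form positive
definite and selects the minimum-norm solution among alternate optima — its
effect on the measured coordinates is orders of magnitude below every
reported tolerance.

Downstream of the fit:

* **Constrained FVA** fixes measured reactions at their fitted values and
  computes every reaction's flux interval; a reaction is **active** when
  its interval allows $|v| > 0.001$.
* **Pathway enrichment**: upper-tail hypergeometric tests of each pathway
  against the active and the inactive set.
* **Fat correlations**: per reaction, Spearman correlation of per-sample
  maximal flux ($v_{max}$; $v_{min}$ available by option) with liver-fat
  %, an empirical p-value from label shuffles
  ($p = (r + 1)/(n_{perm} + 1)$), and Benjamini–Hochberg FDR across
  reactions (rate 0.1). A row is significant when both p-values are below
  0.05 and $q \le 0.1$. Per-sample QP fits are used (the alternative,
  shared constraints across patients, is not what per-patient FVA ranges
  require).
* **Consistency p-value**: 1000 random measurement sets, each value drawn
  uniformly on the global [min, max] envelope of the observed values ("the
  scale of the data"); $p$ is the fraction of random sets fitting at least
  as well, with the usual +1 correction.
* **LOOCV**: each measured reaction is held out, the rest refit, and the
  held-out flux predicted as the midpoint of its FVA interval under the
  refit — the midpoint rule resolves the indeterminacy a single held-out
  reaction can have.

## Statistics and classification

Group comparisons default to the Wilcoxon rank-sum test for unpaired
patient groups (exact p for combined $n \le 20$, normal approximation
above) with the paired signed-rank variant for function-paired vectors;
the choice is recorded in every output. Classification uses a linear-kernel
SVM (interpretable weights over functionality scores; RBF by option) on
100 stratified 2/3–1/3 splits, features standardized on the training fold,
rank-based AUC on the test fold, and an empirical p-value from 1000
label-permutation re-runs of the whole procedure. Splits are stratified
because with 8 + 8 samples unstratified test folds regularly lose a class.

Tracer arithmetic: from deuterium enrichment ratios,
$\mathrm{GNG}_{tot} = 100\,(C5/C2)$, $\mathrm{GNG}_{pyr} = 100\,(C6/C2)$,
and $\mathrm{GNG}_{gly} = \mathrm{GNG}_{tot} - \mathrm{GNG}_{pyr}$ exactly;
negative glycerol contributions are returned as-is with a flag, since they
indicate measurement error rather than a computable quantity.

## What the synthetic generator emulates — and what it does not

`make_toy_model()` builds parallel linear pathways from one uptake to
secretion (one gene per internal reaction, pathway labels); the canonical
5-reaction fixture TM1 is the (2, 2) case. `simulate_expression_cohort()`
draws per-gene baselines $\mu_g \sim N(8, 1)$ once per cohort and per-sample
values $\mu_g + N(0, \sigma)$ with $\sigma = 1$ log-intensity unit by
default — the within-group variability of normalized microarray data — plus
decoy genes (60 by default) so that within-sample ranking behaves like a
genome-wide profile. Planted effects shift the pathway genes of a chosen
function additively on the log scale (multiplicatively on intensity) in one
group; the liver-fat covariate is drawn uniformly on 20–80% (high group)
and 0–10% (low group), the ranges that define the study contrast.
`simulate_flux_cohort()` constructs per-patient feasible flux states in
which one pathway's flux rises monotonically with liver fat, then measures
exchanges with Gaussian noise.

The generator does **not** simulate probe-level microarray effects,
realistic hepatic flux magnitudes, metabolomics peak data, or correlated
gene modules. Passing tests therefore demonstrate that the pipeline
recovers what it models — planted capability differences under rank-based
discretization — not that any particular clinical effect size is
detectable in real cohorts.

### Calibration properties, measured not assumed

With a planted 2-noise-sd adaptability deficit at $n = 8 + 8$, the
per-function rank-sum comparison recovers the effect in $\ge 90\%$ of 20
seeds. Under the null the flag rate at $p < 0.05$ sits near the *lower*
edge of its binomial band: adaptability scores on small networks take few
distinct values, and the exact rank-sum test is conservative under heavy
ties. This conservatism is a property of the score's discreteness, not a
bug; on genome-scale models the scores are far less tied. Similarly, with
16 samples and 44 features a linear SVM on label-shuffled data shows the
well-known small-sample below-chance dip in single shuffles; chance level
is therefore estimated as the mean over 20 shuffles.

Problem sizes used in the packaged checks (toy networks of 2–4 pathways,
200–1000 randomized score triples, 20 detection and 100 null seeds, 100
splits and 1000 permutations) were chosen so the whole validation runs
comfortably on a laptop while keeping every Monte-Carlo estimate's
sampling error well inside the asserted bands.

## Numerical choices

Steady state is enforced to $10^{-6}$, bound slack $10^{-6}$, LP
optimality $10^{-9}$ (all configurable via `hepaflux_tolerances()`). The
LP/MILP backend is the deterministic HiGHS solver; the QP is solved by a
dual active-set method with linearly dependent steady-state rows removed
by QR factorization. MILP objectives are integral, so optima are rounded
to the nearest count. Degenerate alternate optima are accepted: every
contract in the package is written against optimal *values*, never against
witness uniqueness.

## Known limitations

* The default liver catalogue ships Recon 1-style identifiers and
  deliberately small constraint sets; real analyses should review and
  extend the uptake closures per function.
* The biomass reaction added by `add_liver_modifications()` is a
  configurable placeholder (one unit of each designated precursor), since
  a literature-grade hepatocyte biomass composition is model-specific.
* Per-sample QP + FVA on genome-scale models is LP-heavy; the toy-scale
  defaults here are chosen for validation, not benchmarking.
* No tissue-specific model extraction, loopless/parsimonious FBA, or flux
  sampling; the analysis is deliberately limited to the constructs above.
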