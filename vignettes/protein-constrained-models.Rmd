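---
title: "Protein-constrained metabolic models with transcriptome overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-constrained metabolic models with transcriptome overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcflux)
```

## The model

A genome-scale metabolic model (M-model) predicts flux distributions by
linear programming: maximise an objective flux $c^Tv$ subject to steady
state $Sv = 0$ and bounds $v^{lb} \le v \le v^{ub}$.  Plain flux balance
analysis (FBA) knows nothing about the cost of the enzymes that carry
those fluxes, and nothing about gene expression.  `pcflux` augments the
M-model into a protein-constrained model (PC-model) with three extra
variable blocks:

* **proteins** $p \ge 0$ (nmol/gDW), one per model gene;
* **complexes** $x \ge 0$, one per minimal satisfying gene set of a
  gene-protein-reaction (GPR) rule ("and" = subunits, "or" = isozymes);
  a complex shared by several reactions is represented once, so isozyme
  sharing is a genuine resource trade-off;
* **enzymes** $e_{for}, e_{rev} \ge 0$, a forward/reverse pair per
  gene-associated reaction pooling all complexes able to catalyse it.

The constraints are
$$Sv = 0, \qquad Cx \le p, \qquad e_{for} + e_{rev} = B\,\mathrm{diag}(r)\,x,$$
$$-\kappa e_{rev} \le v_{enz} \le \kappa e_{for}, \qquad 0 \le p \le p^{ub},
\qquad p^Td \le P.$$

$C$ counts subunit copies per complex, $B$ routes complexes to the
reactions they catalyse, and $d$ holds protein molecular masses (mg/nmol)
computed from sequence with average residue masses.  Excess protein is
allowed ($Cx \le p$ has slack); spontaneous reactions receive no enzyme
and keep their original bounds.

### Parameters and units

* **$K_{eff}^{avg}$** (default 65 s$^{-1}$): the basal effective rate
  constant.  Each complex carries a dimensionless ratio $r_i$, so its rate
  constant is $r_i K_{eff}^{avg}$.  Initially
  $r^{ori}_i = (X_i/\bar X)^{3/4}$ with complex mass $X = C^Td$ — the
  catalytic-surface-to-mass scaling — renormalised to mean exactly 1.
* **$\kappa$**: fluxes are mmol/gDW/h while enzymes are nmol/gDW and rate
  constants s$^{-1}$, so the capacity coupling is
  $\kappa = K_{eff}^{avg}\cdot 3600\cdot 10^{-6}$ (0.234 at 65 s$^{-1}$).
  It is a configurable field of `RateConstants` for users with other unit
  conventions.
* **$P$** (mg/gDW): the proteome budget, the maximal summed mass of
  modelled proteins.  `estimateProteomeBudget()` scales a total proteome
  fraction (600 mg/gDW by default) by the modelled share of transcript
  mass, with a correction for unmeasured genes.
* **$p^{ub}$**: per-protein cap, defaulting to $P/\min(d)$ — no single
  protein can outweigh the whole budget anyway.

## Overlaying a transcriptome

Assuming proteome abundances roughly track transcript abundances, one
sample is overlaid by the convex quadratic program
$$\min_{v,p,x,e} \sum_j w_j\,(p_j - t_j)^2$$
over the full PC constraint set, after scaling $t$ so that $t^Td = P$.
Weights are $w_j = 1/t_j$ for $t_j>0$, $1$ for $t_j=0$ and $0$ for
unmeasured genes: inverse-abundance weighting keeps lowly- and
un-expressed proteins from being silently inflated, and unmeasured genes
do not enter the objective at all.  The fitted proteome $p'$ then defines
a **context-specific model** through
$(1-s)p'_j \le p_j \le p'_j$ for measured genes (unmeasured genes keep
$[0, p^{ub}]$).  The slack $s$ (default 0.02) leaves budget headroom for
unmeasured proteins; on our fixtures the downstream optimum changes by
well under 5 % across $s \in [0.01, 0.05]$, which the test suite checks.

## Calibrating rate constants

With $Q$ sample groups the ratios $r$ become decision variables shared
across per-group PC blocks:
$$\min \sum_{k=1}^{Q} \sum_j w'_j (p^k_j - t^k_j)^2,\qquad
\tfrac1N\sum_i r_i = 1,$$
with binary weights $w'$ (0 for unmeasured genes) and
$0.1\,r^{ori}_i \le r_i \le 1.9\,r^{ori}_i$ for *free* complexes — those
with at least one subunit at or above its group's mean abundance in some
group.  Complexes with uniformly low subunit evidence stay at $r^{ori}$,
which keeps the number of adjusted rate constants small.  The constraint
$e = B\,\mathrm{diag}(r)\,x$ makes the program bilinear.  Two solution
strategies are provided:

* `method = "bilinear"` — a value-function decomposition: for fixed $r$
  the problem separates into $Q$ convex QPs, so the free components of
  $r$ are optimised directly (deterministic multi-start bounded
  quasi-Newton; golden-section plus local grid refinement when only one
  effective degree of freedom remains after the mean constraint).
* `method = "alternating"` — a block-coordinate heuristic: fix $r$ and
  solve the per-group QPs; then fix the complex levels and re-solve a
  joint convex QP over proteomes, enzymes and the free $r$.  Both steps
  re-optimise a feasible block, so the objective never increases.  It is
  labelled `heuristic` in the output and restarted from seeded random
  points (default 3).

Samples are grouped beforehand by hierarchical clustering on
$\log_{10}(x+1)$ abundances with correlation distance and average
linkage (`clusterSamples()`); the transform, distance and linkage are
choices of this package — the method only requires *some* grouping of
similar metabolic modes — and are therefore configurable and recorded.
Group means may come with group-specific model variants (for example
condition-specific uptake bounds) via `groupModels`.

## Debottlenecking

Given a context model, `debottleneck()` relaxes the measured-protein caps
to $p'_j + \epsilon_j$ with a shared allowance $\sum\epsilon \le E$ and
maximises a production flux by LP.  Ties among optimal allocations are
broken canonically: lexicographically minimise $\sum\epsilon$, then the
proteome mass $p^Td$.  `selectBudget()` scans a grid of budgets and
returns the first point after the optimum-vs-E curve settles into its
final constant slope (slope agreement within 1 % of the curve's largest
slope): beyond that point no single protein is blocking the objective.
The allowances are reported in nmol/gDW alongside the per-protein fold
overexpression $(p'_j+\epsilon_j)/p'_j$.

## Unbiased analysis

`pcFVA()` computes per-reaction flux ranges with the production objective
held at 0 %, 50 %, 90 % and 99 % of its optimum (0 % applies no cut);
ranges at a higher fraction are always nested inside lower ones, which is
asserted in the tests against exhaustive vertex enumeration on small
networks.  `classifyReactions()` ranks, across samples, each reaction's
maximal flux against the summed abundance of its associated transcripts
(Spearman, average ranks on ties; the statistic defaults to the
fraction-0 maximum and is configurable): $\rho \ge 0.8$ is
expression-dependent, $0.5 \le \rho < 0.8$ expression-correlated,
anything else (including spontaneous reactions and undefined, constant
series) expression-independent.  `consistencyReport()` quantifies
fit-vs-data agreement with $R^2$ on raw pairs and $R^{2*}$ on
$\log_{10}$ pairs (strictly positive pairs only), and flags genes whose
symmetric ratio $\max(p/t, t/p)$ reaches 3 (outliers) or 10 (far
outliers); a zero against a positive value counts as infinitely
inconsistent, and (0,0) pairs are uninformative and dropped.
`flagPersistentOutliers()` lists genes that are far outliers in many
samples — candidates for GPR mis-annotation, left to manual review.

## Numerical design

All optimisation reduces to linear or diagonal-Hessian convex quadratic
programs, solved by a sparse primal-dual interior-point method
(Mehrotra predictor-corrector on the normal equations, per-row
regularised Cholesky, relative convergence tolerance $10^{-9}$).
Degenerate optimal faces — routine in flux cones — are handled by three
safeguards: scale-aware elimination of numerically fixed variables, a
residual-based acceptance for stationary iterates, and an exact
bounded-variable two-phase simplex (Bland's rule) that takes over any
pure LP the interior-point method cannot finish.  Alternate optima are
resolved reproducibly: PC-FBA returns the point that additionally
minimises proteome mass, implemented by perturbation-based lexicographic
weighting small enough (relative $10^{-5}$ per level) not to move the
optimal vertex of the level above.  The reported objective always comes
from the dedicated primary solve.

## What the synthetic fixtures do and do not show

`makeToyModel()` draws seeded, feasible chain-and-branch networks with
mixed GPR forms and random protein sequences; `makeCalvinFixture()` is a
carbon- and phosphate-balanced Calvin–Benson cycle whose triose-phosphate
export provably costs 9 ATP and 6 NADH; `makeKeffFixture()` is a
three-pathway network with per-group demands built so that the true rate
ratios are point-identified from noiseless data;
`makeSyntheticTranscriptomes()` emits transcript vectors from minimal
feasible proteomes under multiplicative lognormal noise ($\sigma = 0.2$
by default, matching RNA-seq-like dispersion at desk scale) with a
random 5 % of genes unmeasured.  Problem sizes used throughout the tests
are desk-scale by design: networks of 8–20 reactions, tens of genes, 50
fitted samples, two calibration groups.  Passing tests therefore
demonstrate correctness of the optimisation machinery and recovery under
the stated noise model — not that transcript abundance is a faithful
proxy for enzyme abundance in real cells, nor that the fixed basal rate
constant or the proteome-budget estimate is accurate for any particular
organism.  On real data those assumptions carry the usual caveats:
translation efficiency, protein turnover and compartmentalisation are
not modelled.

## Known limitations

* Enzymes are not compartmentalised, and there is no
  translation/ribosome machinery — this is not an ME-model.
* One rate constant per complex, regardless of which reaction it
  catalyses.
* A model gene found in the sequence file is assumed to yield exactly one
  protein; the protein count is derived strictly from model genes.
* The per-gene transcript-to-proteome proportionality is the method's
  central assumption; the inverse-abundance weighting is one reasonable
  choice among several, and alternative weightings can be passed to
  `fitProteome()` directly.
* Reproducing organism-scale results additionally needs a curated
  genome-scale reconstruction, quantified RNA-seq for every sample and a
  bilinear-capable commercial solver for the full-size calibration;
  with those in hand the pipeline is the same: read the model and FASTA,
  `buildPCModel()`, fit each sample, cluster, `solveKeffNCQP()`, refit,
  then `debottleneck()`/`pcFVA()`/`classifyReactions()`.

## A worked run

```{r example}
fx <- makeToyModel(seed = 1)
pcm <- buildPCModel(fx$model, fx$proteins, P = 10)
pcm

tr <- makeSyntheticTranscriptomes(pcm, nSamples = 1, sigma = 0.2, seed = 1)
t <- scaleTranscriptome(tr$T[1, ], pcm@d, proteomeBudget(pcm))
fit <- fitProteome(pcm, t)
fit
ctx <- contextualize(pcm, fit, s = 0.02)
consistencyReport(fittedProteome(fit), t)

db <- debottleneck(ctx, "EX", E = 2)
db
head(pcFVA(ctx, "EX", fractions = c(0, 0.9)))
```
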