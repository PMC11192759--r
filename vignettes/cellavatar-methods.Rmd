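---
title: "Simulating cell-line avatars: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cell-line avatars: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellavatar)
```

This vignette documents the science inside `cellavatar`: the dynamical model
and its assumptions, how omics data condition it, the parameters that matter,
what the synthetic fixtures do and do not emulate, and the numerical and design
decisions taken where more than one defensible choice existed.

## The dynamical model

The simulator runs discrete-time, continuous-valued dynamics on a signed,
weighted, directed signaling graph. Every node carries two variables:

* **activity** $a_i(t) \in [a_i^{\min}, a_i^{\max}] \subseteq [0,1]$, the
  evolving state (e.g. fraction of active protein);
* **concentration** $c_i > 0$, a static scale for how strongly the node
  influences its targets.

The synchronous update for node $j$ is

$$
a_j(t+1) \;=\; \mathrm{clamp}\!\left(
  \sigma\!\Big(b_j + \sum_i s_{ij}\, w_{ij}\, a_i(t)\, \hat c_i\Big),
  \; a_j^{\min},\, a_j^{\max}\right),
\qquad
\hat c_i = \frac{c_i}{1+c_i},
$$

with $\sigma$ the logistic function, $s_{ij} \in \{-1,+1\}$ the edge sign,
$w_{ij} > 0$ the edge weight, and the bias $b_j = \mathrm{logit}(a_j^{\mathrm{base}})$
(logit clamped to $[10^{-6}, 1-10^{-6}]$ so boundary base activities stay
finite).

Why this rule, among the continuous-logic family:

* it is continuous-valued and saturates in $[0,1]$, so activities are always
  interpretable as fractional activation;
* a node with no incoming edges is a fixed point at its base activity
  ($\sigma(\mathrm{logit}(p)) = p$), which makes hand calibration of resting
  states transparent;
* weighted signed sums followed by a sigmoid implement soft logic gates: two
  converging pathways with individually sufficient weights give an OR, a
  deeper-biased target needing both inputs gives an AND;
* the rule sits behind a single internal interface (`step_matrix()`), so a
  different gate family (e.g. normalized-Hill) can be swapped without touching
  the rest of the machinery.

Concentrations do not evolve. They enter through the saturating transform
$\hat c = c/(1+c)$ so that expression fold-changes modulate edge influence
boundedly: a 5-fold overexpression cannot make an edge arbitrarily strong,
which matches the saturable nature of molecular interactions and keeps the
dynamics numerically tame. The update is synchronous across nodes;
asynchronous schedules are out of scope.

**Noise.** Intratumor heterogeneity is modeled as multiplicative log-normal
noise applied once, at initialization, to both activities and concentrations
($x \mapsto x\,e^{\varepsilon}$, $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$,
activities then clamped to their bounds). Per-step noise is deliberately not
used: the biological picture is a population of cells differing in initial
state, each then following deterministic signaling, and initialization-only
noise keeps every replicate's attractor well defined.

**Attractors.** A trajectory stops at a fixed point when the largest activity
change in one step falls below `attractor_tol` ($10^{-6}$), or at a limit
cycle when a state (rounded to 6 decimals) recurs within
`cycle_detection_window` (20) steps; otherwise it runs to `max_steps` (300)
and is flagged as non-converged. Phenotype scores are the mean activity of the
cell-cycle and apoptosis readout nodes at the attractor — averaged over one
period for a limit cycle, taken at the final state for non-converged runs.

**Verdict.** A replicate is *alive* iff cell-cycle score $\ge 0.6$ **and**
apoptosis score $\le 0.2$ (both boundaries inclusive). Active apoptosis kills
the cell even when proliferation is intact. An ensemble's
`survival_fraction` is the alive fraction over replicates.

## Conditioning a cell line

* **Expression**: fold-change per gene is $(x_{\mathrm{cell}} + \varepsilon) /
  (\bar x_{\mathrm{baseline}} + \varepsilon)$ with pseudocount
  $\varepsilon = 1$ (configurable) guarding against zero baselines; effective
  concentration is base concentration × fold-change. Fold-changes are not
  capped — the saturating $\hat c$ already bounds their dynamical effect.
* **Mutations**: inputs arrive pre-annotated with a pathogenicity boolean and
  a consequence class; annotation pipelines themselves are out of scope.
  Pathogenic hits on tumor suppressors are loss-of-function; on oncogenes,
  gain-of-function unless clearly truncating (frameshift, stop gain).
  Loss-of-function sets $a^{\max} = 0$, gain-of-function sets $a^{\min} = 1$;
  the node is thereby pinned for the entire simulation. A gain- and a
  loss-of-function call on the same node is an error rather than a silent
  precedence — with synthetic inputs, a loud failure is safer than an
  arbitrary rule.

## Pharmacology

Compound bioactivity records are filtered to human binding-assay measurements
with confidence above 5, affinity at most $10^4$ nM and exact (`=`) relations;
duplicate drug–target pairs collapse to the strongest affinity. Dose is
converted to target inhibition by a one-site occupancy hyperbola
$d/(d+K)$ (Hill coefficient configurable, default 1) — the standard
receptor-occupancy form, chosen because it is monotone in dose, parameter-free
beyond the measured affinity, and half-maximal exactly at $d = K$. Inhibition
acts as an activity ceiling on the target ($a^{\max} \leftarrow \min(a^{\max},
1 - \mathrm{inh})$); multiple drugs on one target combine by the lowest
ceiling. Only the activity cap is modified, not the concentration: occupancy
blocks function, it does not degrade protein. A drug's mechanism-of-action
group is the pathway of its strongest binder, ties broken lexicographically.

## Dose-response and synergy

The standard axis is 16 doses: 0 plus 15 log-spaced points from 1 to
$10^4$ nM (log-uniform coverage is the pharmacological norm; spacing is
configurable). Viability at dose $d$ is survival at $d$ divided by the
same-seed untreated survival, which cancels initialization noise and forces
viability 1 at dose 0. The IC50 is fitted with a four-parameter logistic on
$\log_{10}$ dose (zero dose floored at 0.1 nM for the log axis) and defined
at **absolute** viability 0.5 rather than half-max effect — absolute potency
is what the downstream sub-IC50 synergy restriction needs; curves never
reaching 0.5 inside the grid are censored above $10^4$ nM, as are
non-convergent fits.

Combination grids are scored by Bliss excess — observed killrate minus the
independence expectation $k_A + k_B - k_A k_B$ — with negative excess set to
zero for scoring: only synergy is quantified, antagonism is not assessed. The
summary statistics are the maximum clamped excess over the whole grid
(`bliss_score`) and over the cells where both doses lie strictly below the
respective monotherapy IC50s (`bliss_max_ic50`), with the argmax dose pair
recorded (first in row-major order on ties). Synergy lives on a 0–1 scale
internally; the ×100 presentation scale appears only at the benchmarking
boundary.

Grid quality control enforces dose-response principles on the margins: a
marginal viability rising by more than $\tau = 0.1$ anywhere along its dose
axis, or any non-finite entry, fails the grid. $\tau$ absorbs replicate-level
Monte-Carlo jitter while still catching genuine non-monotonicity.

Synergy scores are discretized into non/moderate/strong classes by
one-dimensional $k$-means ($k = 3$, 100 restarts, seeded). Thresholds between
adjacent clusters are placed at the midpoint of the boundary gap (mean of the
lower cluster's maximum and the upper cluster's minimum); published threshold
values of this kind are data outcomes, not constants, so the package computes
them from whatever scores it is given.

## Biomarker screening

Perturbations use the field's shorthand: `0.0` knock-out
($a^{\max} := 0$), `1.0` constitutive activation ($a^{\min} := 1$), `mc5.0`
overexpression (concentration ×5), `mc0.3` underexpression (×0.3). Protein
complexes are ordinary nodes; perturbing one perturbs that node only.

For each (perturbation, cell line) the screen reruns both monotherapy screens
and the combination grid, then measures the Bliss-score shift, the killrate
shift, and both drugs' $\log_{10}$ IC50 shifts. Two exclusion filters mirror
the screen design: pairs whose baseline synergy argmax is not sub-IC50 for
both drugs are not analyzed (such synergies carry no dose-sparing benefit),
and triplets where survival drops significantly while synergy collapses below
the non-synergy threshold are discarded as suspected model artifacts.

Significance uses a two-sided Wilcoxon rank-sum test on replicate-level
scores, exact when both samples are ≤ 25 without ties, normal approximation
with tie correction otherwise; effects with $p < 0.001$ count. The unit of
replication is the per-cell-line replicate ensemble by default (an
across-cell-line mode is a matter of feeding the per-line results into the
same test). Shifts are evaluated at the synergy argmax of whichever grid —
baseline or perturbed — shows the stronger synergy: a sensitivity biomarker
creates synergy at doses where the baseline had none, so measuring at the
baseline argmax would systematically miss it. "No IC50 shift" means
$|\Delta\log_{10}\mathrm{IC50}| < 0.2$ for both drugs (censored-to-censored
comparisons count as zero shift); a significant effect without IC50 shift is
combination-specific, otherwise it is monotherapy-specific for the shifted
drug. The two-stage prescreen idea (cheap single-replicate pass, then
full-ensemble confirmation) is available simply by running the screen twice
with different `n_replicates`.

## The synthetic fixtures

`fixture_spec()` generates a small world with known ground truth: `n_pathways`
parallel receptor→kinase pathways converging on a cell-cycle readout wired as
OR (redundant pathways — the substrate for combination synergy) or AND (each
pathway essential — the substrate for monotherapy kill), an apoptosis readout
inhibited by the cell-cycle node, and disconnected decoy nodes. Gate weights
are chosen so the alive/dead margins are wide relative to the default
initialization noise (cell-cycle ≈ 0.9 alive vs ≈ 0.1 dead). The default
bundle (seed 1, three pathways, three viable cell lines plus one natively dead
line, log-normal fold-changes with $\mathrm{sd}_{\log} = 0.15$) plants its
ground truth through the cell lines: `CL1` carries an `RTK3` stop-gain, so
blocking pathways 1 and 2 is synergistic there and nowhere else; in wild-type
`CL2` the same loss is recoverable as a combination-specific sensitivity
biomarker, and pinning the third pathway's kinase on is a resistance
biomarker in `CL1`.

What the fixtures deliberately do **not** emulate: realistic human pathway
topology, feedback-rich dynamics (the fixture graph is feed-forward, so every
trajectory reaches a unique fixed point within a handful of steps),
graded dose-response at the single-replicate level (verdicts are
near-deterministic given the wide gate margins), or the scale of curated
networks with thousands of nodes. Passing tests therefore demonstrate the
correctness of the machinery — conditioning, dynamics, scoring, filtering,
statistics — not predictive accuracy on real tumor biology, which depends
entirely on the quality of the supplied network and omics data.

## Numerical choices and degenerate inputs

* Fixed-point tolerance $10^{-6}$ on the max per-step activity change; cycle
  detection on 6-decimal rounded states over a 20-step window.
* The 4PL fit runs Levenberg–Marquardt with box constraints (plateaus in
  $[0,1.2]$, midpoint within ±2 log units of the dose range, slope in
  $[0.05, 50]$); the IC50 crossing is located on a 2000-point grid of the
  fitted curve with linear interpolation. Flat curves, non-convergent fits
  and curves never crossing 0.5 are censored, never guessed.
* Reproducibility: every stochastic component (initialization noise, k-means
  restarts, splits, baseline models) is seeded; replicate noise comes from
  replicate-indexed substreams of the master seed, so ensembles are
  bit-identical across reruns and machines, and CLI artifacts regenerate
  byte-identically from their manifest.
* Ties: path tracing breaks shortest-path ties lexicographically on the
  node-id sequence; the synergy argmax takes the first maximum in row-major
  order; MoA ties take the lexicographically smallest target.
* Degenerate inputs fail loudly: empty gene intersections, conflicting
  GoF+LoF calls, natively dead cell lines entering a screen, single-class
  references for BA/AUC, fewer than 3 distinct scores for discretization,
  infeasible entity hold-outs.

## Benchmarking

Predictions are compared to reference panels by balanced accuracy after
dichotomizing both sides (≥ threshold counts as synergistic; the edge
inclusion is a declared convention), by ROC AUC computed from the
Mann–Whitney rank statistic with midranks for ties, and by Pearson
correlation of $\log_{10}$ IC50 over the overlap (censored values excluded
and counted). Train/test splits are exclusive by cell line (CEX), drug (DEX)
or both (AEX, mixed rows dropped). The ML baselines — ridge regression
(`glmnet`), a small one-hidden-layer neural network (`nnet`, 16 units, weight
decay $10^{-3}$), and gradient-boosted trees (`xgboost`, 200 rounds, depth 4,
learning rate 0.1) — are trained to regress monotherapy killrate on
concatenated expression and dose-dependent target-inhibition features;
combination synergy for baselines follows by feeding their predicted
monotherapy killrates through the same Bliss machinery. Hyperparameters are
fixed in code: the baselines are yardsticks, not contenders to tune.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on the synthetic
fixtures: 10-node networks, 16-dose axes, 10–50 replicates per ensemble in
unit tests, and ≥ 1000 aggregate trajectories at 300 steps for the attractor
convergence check. These sizes were chosen so every oracle (exhaustive path
enumeration, full Wilcoxon enumeration, exhaustive 1-D partition search,
brute-force AUC pair counting) remains feasible in the same run.

## Known limitations

* Concentrations are static; no synthesis/degradation dynamics.
* Synchronous updates can manufacture limit cycles that asynchronous schemes
  would not show; readouts over a cycle period mitigate but do not remove
  this.
* The occupancy model ignores pharmacokinetics, plasma binding and transport;
  dose is intracellular free concentration by assumption.
* Bliss is the only synergy model implemented (Loewe/ZIP/HSA are not), and
  antagonism is deliberately not quantified.
* Edge weights are fixed scalars; dose- or context-dependent edge strengths
  are not modeled.
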