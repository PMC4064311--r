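---
title: "Detecting pleiotropic disease modules on interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pleiotropic disease modules on interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomod)
```

## The model

`pleiomod` asks whether several diseases, profiled as case/control
expression studies on a common cell type, perturb a shared neighbourhood
of an interactome — a *pleiotropic module* — and whether that shared
machinery predicts treatment response.

The unit of analysis is the **maximal clique**: a fully connected
subgraph not contained in any larger one. Cliques are the most
conservative notion of a functional neighbourhood — every member
interacts with every other — and, unlike connected components or
k-cores, they do not bleed across hubs. For a disease with per-gene
differential-expression P-values $p_g$, each clique $C$ receives the
weight

$$W(C) \;=\; \sum_{g \in C} -\log_{10} p_g ,$$

so a clique is heavy when its members are jointly differentially
expressed. Significance is empirical: the gene-to-P assignment is
shuffled over the whole gene universe, all cliques are re-weighted on
the same shuffle (preserving the correlation between overlapping
cliques under the null), and the clique's empirical P is
$(r+1)/(n_{\text{perm}}+1)$ where $r$ counts shuffles reaching its real
weight. The disease module is the union of cliques with empirical
$P < \alpha$. No FDR is applied across cliques: the threshold is a
fixed per-clique $\alpha$, and module-level error control comes from
the randomized-null analysis below, which reruns the entire procedure.

**Assumptions.** (i) The interactome is a fixed, undirected scaffold;
edge confidences act only as an inclusion filter (default ≥ 0.7 on a
[0, 1] scale; STRING's 0–999 integers are divided by 1000). (ii)
P-values are exchangeable across genes under the null — the shuffle
destroys the gene–P coupling but keeps the empirical P-value
distribution exactly. (iii) Genes present in the network but never
measured carry $p = 1$ (weight 0) rather than disqualifying their
cliques; on sparsely measured universes, discarding such cliques would
delete most large ones.

## Pleiotropy against a full-pipeline null

Modules are detected per disease and intersected. Because the
intersection of eight (or even four) module detections has no tractable
closed-form null, the package reruns the *entire* detection for every
disease on independently randomized P-values, `n_repeats` times
(100 at full scale), and records:

* the intersection-size empirical P, $(r+1)/(n_{\text{repeats}}+1)$;
* the fold enrichment FE = observed size / mean null size, flagged
  undefined when the null mean is exactly 0 (an empty null means the
  observed overlap beats any finite enrichment);
* a per-gene pleiotropy P — the floored fraction of repeats in which the
  gene lands in at least as many modules as observed.

The clique enumeration is reused across all runs (the network never
changes); only the P-shuffles and weight nulls are recomputed. Inside
each null repeat the clique-permutation count may be reduced (default
1,000) to keep the nested null tractable; this is recorded in the
result object.

## Enrichment with degree-matched nulls

Fold enrichment of an annotation in a test set is the frequency ratio
$\mathrm{FE} = (k/n)/(K/N)$; e.g. 53 annotated genes in a 158-gene set
against 2,298 of 22,500 gives $33.5\%/10.2\% = 3.3$. The universe $N$
is an explicit parameter — printed FEs are only reproducible when the
background is stated. One-sided Fisher tests use the hypergeometric
upper tail, and BH step-up FDR is applied across sets.

Interactome gene sets are hub-biased: high-degree genes accumulate
annotations of every kind. `degree_matched_sets()` therefore samples
random sets with every member above the test set's minimum degree and
the set median within a tolerance (default ±2%) of the test set's
median degree, by stratifying each draw into halves above and below the
target median and rejecting draws outside the band. The
degree-controlled P is the usual $(r+1)/(n+1)$ against those matched
sets. The unit tests construct an annotation that tracks degree alone
and show the uniform-null P collapsing to its floor while the matched
null stays unremarkable.

## Set statistics and extreme tails

Whether a *fixed* gene set responds is scored by the mean of squared
two-sample t statistics. For $m$ independent null genes and large
groups, $m$ times the statistic is approximately $\chi^2(m)$ — a
convenient effect-size scale (the per-gene noncentrality adds directly)
— but inference always uses label permutations, which respect
inter-gene correlation. Note the $\chi^2$ reference counts *genes*;
with small samples the squared t has heavier tails than $\chi^2_1$,
which is another reason the permutation path is the primary one.

Permutation P-values cannot resolve below $1/(n+1)$. When fewer than 10
null exceedances remain, `gpd_tail_pvalue()` fits a generalized Pareto
distribution by maximum likelihood to the exceedances above the upper
`tail_fraction` quantile (default 0.1) and extrapolates
$p = \text{tail\_fraction} \times S_{\text{GPD}}(x - u)$. Degenerate
(constant) nulls fall back to the empirical estimator with a warning.
Extrapolation accuracy degrades with distance: the tests check a
factor-of-two agreement with the analytic exponential tail just beyond
the empirical range, and only sign/ordering far beyond it.

## Responder classification

Cohorts are paired pre/post-treatment matrices with high/low responder
labels. Candidate genes must respond to the drug (paired t, $P < 0.05$,
all samples pooled) — this filter is applied *before* the outer
cross-validation loop, mirroring common practice for treatment-response
signatures; since the filter uses no outcome labels, it leaks no label
information, but an inside-fold filtering mode can be composed from the
exported pieces if desired. Candidates may further be restricted to
genes in at least `min_modules` disease modules or to one named module.

The classifier is L1-penalized logistic regression over a 100-point
penalty grid log-spaced from $\lambda_{\max}$ (the smallest penalty
zeroing every coefficient, computed under glmnet's population-SD
standardization) down to $10^{-4}\lambda_{\max}$. The penalty minimizes
mean held-out binomial deviance over leave-one-out folds, ties broken
toward the sparser model. Reported probabilities are *outer*
leave-one-out predictions with the penalty re-selected inside every
training fold; calls are made at the 0.5 border.

Significance reruns the complete cross-validation under label
permutations. Two statistics are exposed: the correct-call count (the
default, directly interpretable) and the summed cross-validated
deviance. The correct-call count is integer-valued and heavily tied, so
its empirical P is conservative by construction; calibration checks use
the continuous deviance statistic. A related subtlety: under the null,
leave-one-out accuracy with balanced classes sits *below* 0.5 (removing
a sample leaves its class in the training minority), which is harmless
here because observed and null statistics are computed by the identical
pipeline. The per-group perturbation statistic — mean squared paired t
within each label — quantifies which responder group the treatment
moves more.

## The synthetic-data generator

`simulation_scenario()` plants every structure the analysis assumes:

* a background graph (scale-free preferential attachment by default,
  Erdős–Rényi optionally) with the core and each disease-specific set
  completed into cliques; planted edges carry confidence 0.9 so the
  default 0.7 filter never removes them, background confidences are
  uniform on [0.7, 1];
* per-disease Gaussian expression (unit within-group SD) with cases
  shifted on core ∪ specific genes;
* an annotation whose expected overlap with the core realizes a target
  fold enrichment;
* a paired cohort where the drug shifts its target genes by per-label
  amounts, with within-subject noise (default SD 0.5) smaller than the
  unit between-subject SD, as in paired designs.

Default study conditions: 300 genes, 4 diseases, a 20-gene core at
effect size 2 SD with 10 cases vs 10 controls per disease, one 8-gene
specific clique per disease, and an 8 vs 8 cohort with the
low-responder group shifted by 1.5 SD on 10 genes. These scales keep a
full pleiotropy null (50 repeats × 4 diseases × 1,000 clique
permutations) under ten seconds while leaving the planted signal
recoverable but not trivial.

What the generator does **not** emulate: probe-level artifacts, batch
effects, heavy-tailed or count-distributed expression, correlated
background genes, and annotation biases beyond degree. Passing tests
therefore demonstrate the machinery's correctness and calibration, not
performance on any real cohort.

## Numerical choices and degenerate inputs

* Empirical P-values use $(r+1)/(n+1)$ throughout — never exactly zero,
  conservative under ties.
* Clique weights use log base 10; empirical significance is invariant
  to the base (a global positive rescaling preserves all comparisons).
* Zero-variance genes get $t = 0$, $p = 1$ instead of being dropped, so
  gene universes stay aligned with the network.
* Quantile normalization resolves within-column ties to the mean of the
  tied target quantiles; the log2 transform (when requested) follows
  normalization.
* Component ties in `largest_connected_component()` and clique output
  order are broken lexicographically, making every pipeline stage
  deterministic given a seed.
* The P-shuffle universe is sorted before permuting, so results do not
  depend on clique order or DE-table row order.
* Degree-matched sampling fails loudly, with diagnostics, after a
  bounded number of rejections rather than looping forever on an
  infeasible constraint.

## Problem sizes used by the test suite

The suite runs at desk scale: clique-null calibration pools ~12
graph/P-value repetitions at 999 permutations; set-statistic and
classifier calibrations use ≥100 repetitions at 99 and 19 permutations
respectively (with a reduced 15-point penalty grid); planted-core
recovery uses the default scenario with 50 null repeats; the
degree-matched contract draws 10,000 sets on a 2,000-node graph. The
whole suite completes in roughly six minutes on one CPU. Full-scale
analyses (10,000 clique permutations, 100 null repeats, $10^6$
permutation defaults) use the same code paths with larger arguments.

## Known limitations

* Ordinary pooled-variance t statistics stand in for moderated
  (empirical-Bayes) statistics; any per-gene P table can be supplied
  instead, so moderated inputs are a drop-in substitution.
* Two-group designs only; no paired or multi-factor differential
  expression beyond the paired drug-response filter.
* Clique enumeration is exponential in the worst case; on dense graphs
  raise the confidence threshold or `min_size`.
* The GPD tail is an extrapolation; treat P-values far beyond the
  permutation range as order-of-magnitude statements.
* Fold enrichment depends on the declared universe; comparisons across
  studies require a common background.
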