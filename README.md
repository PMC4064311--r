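# pleiomod

Disease-module detection and pleiotropy analysis on gene interaction
networks, with degree-controlled enrichment statistics and penalized
responder classification.

## The scientific problem

Many diseases that look clinically unrelated perturb overlapping sets of
interacting genes. `pleiomod` implements a network strategy for finding
and exploiting that shared machinery from case/control expression
profiling of several diseases measured on a common cell type:

1. **Disease modules from weighted cliques.** Given an undirected
   protein–protein interaction network (STRING-style edge list,
   confidence ≥ 0.7) and per-gene differential-expression P-values for
   one disease, every maximal clique *C* of the network is scored by

   *W(C) = Σ<sub>g∈C</sub> −log₁₀ p<sub>g</sub>*

   The null distribution of each clique's weight is obtained by
   shuffling the gene → P-value assignment over the whole gene universe
   (one global shuffle per permutation, shared by all cliques) and
   re-scoring; a clique is significant when its empirical P,
   (r+1)/(n<sub>perm</sub>+1), falls below α = 0.01. The disease module
   is the union of significant cliques.

2. **Pleiotropic overlap.** Modules are detected for every disease and
   intersected. The intersection is compared with a null in which each
   disease's P-values are independently randomized and the *entire*
   detection pipeline is rerun (default 100 repeats at full scale):
   this yields an empirical P for the intersection size, a fold
   enrichment (observed size / mean null size), and a per-gene
   pleiotropy P (how often a gene enters at least as many null modules
   as observed).

3. **Enrichment with honest nulls.** Annotation enrichment uses the
   fold-enrichment ratio FE = (k/n)/(K/N), one-sided Fisher tests,
   Benjamini–Hochberg FDR, and — because interactome annotations are
   biased toward hubs — random gene sets matched to the test set's
   minimum and median degree.

4. **Responder stratification.** For paired pre/post-treatment cohorts,
   genes responsive to the drug (paired t, P < 0.05) and lying in
   multiple disease modules feed an L1-penalized logistic classifier
   whose penalty is chosen by minimum leave-one-out deviance; reported
   probabilities are fully cross-validated (the held-out sample never
   touches standardization, the path, or the penalty choice), and
   significance comes from rerunning the whole cross-validation under
   label permutations. A per-group perturbation statistic (mean squared
   paired t) quantifies which responder group the drug moves more.

A synthetic-data generator plants all of this structure (dense cliques
in a scale-free interactome, a shared differentially expressed core plus
disease-specific modules, enriched annotations, unevenly perturbed
responder groups) so the full pipeline is testable end to end without
any external downloads.

## Worked example

```r
library(pleiomod)

sc   <- simulation_scenario(seed = 42)      # 300 genes, 4 diseases, 20-gene core
net  <- simulate_interactome(sc)
coll <- simulate_disease_collection(net, sc)
de   <- lapply(coll$studies, per_gene_ttest)

pl <- pleiotropy_null(net, de, n_repeats = 50, n_perm = 1000, seed = 42,
                      verbose = FALSE)
pl
#> pleiotropy_result over 4 diseases
#>   intersection: 22 gene(s); p = 0.0196
#>   fold enrichment vs null: undefined (null mean 0)
length(intersect(pl$intersection, sc$core_genes))
#> [1] 20
```

All 20 planted core genes are recovered in the 22-gene intersection; its
permutation P sits at the floor 1/(50+1) = 0.0196, and every one of the
50 randomized-null repeats produced an *empty* intersection, so the fold
enrichment over the null is reported as undefined (the observed overlap
exceeds any finite enrichment).

```r
ann <- simulate_annotations(sc$genes, sc$core_genes, fe_target = 3,
                            K = 30, seed = 43)
k <- length(intersect(pl$intersection, ann))
fold_enrichment(k, length(pl$intersection), length(ann), sc$n_genes)
#> [1] 2.73     # Fisher p = 0.0143

cohort <- simulate_cohort(sc)               # drug shifts LRs, not HRs
genes  <- restrict_to_modules(drug_responsive_genes(cohort),
                              pl$module_count, min_modules = 2)
rep <- classifier_permutation_test(t(cohort$post[genes, ]), cohort$labels,
                                   n_perm = 200, seed = 44)
rep
#> classifier_report: 15 / 16 correct cross-validated calls; lambda = 0.00915; permutation p = 0.00498
```

The annotation built to be ~3-fold enriched in the core realizes FE 2.7
in the detected intersection, and the module-restricted classifier
separates 15 of 16 responders with permutation P ≈ 0.005.

A command-line wrapper over the same functions ships in
`inst/cli/pleiomod.R` (subcommands `simulate`, `detect`, `pleiotropy`,
`enrich`, `degree-null`, `classify`, `run`).

## Documentation

The methods vignette (`vignettes/disease-modules.Rmd`) describes the
model, its assumptions, the tunable parameters, the synthetic-data
design, and known limitations.
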