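#' Define a simulation scenario with planted modular structure
#'
#' A scenario describes a sparse interactome containing dense planted
#' cliques, a collection of diseases sharing a differentially expressed
#' core module plus disease-specific modules, an annotation set enriched
#' in the core, and a paired-treatment responder cohort in which the drug
#' perturbs one responder group more than the other.
#'
#' Defaults describe a desk-scale study: a 300-gene scale-free
#' interactome, 4 diseases sharing a 20-gene core with an expression
#' shift of 2 within-group standard deviations in cases (10 cases vs 10
#' controls per disease), one 8-gene disease-specific clique per disease,
#' and an 8-vs-8 responder cohort in which the drug shifts 10 genes by
#' 1.5 SD in low responders and not at all in high responders.
#'
#' @param n_genes Number of genes in the interactome.
#' @param topology `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"` background graph.
#' @param n_diseases Number of diseases.
#' @param core_size Genes in the shared (pleiotropic) core module.
#' @param specific_size Genes in each disease-specific module.
#' @param effect_size Case-vs-control mean shift on planted genes, in
#'   within-group SD units.
#' @param n_case,n_control Samples per group per disease.
#' @param annotation_fe_target Target fold enrichment of the synthetic
#'   annotation in the core.
#' @param annotation_size Size of the synthetic annotation set.
#' @param n_hr,n_lr Responder cohort group sizes.
#' @param n_drug_genes Genes the drug perturbs.
#' @param effect_hr,effect_lr Drug-induced shift per group, in
#'   within-subject SD units (defaults emulate a stronger perturbation of
#'   low responders).
#' @param drug_noise_sd Within-subject (pre-to-post) noise SD; smaller
#'   than the between-subject SD of 1, as in paired designs.
#' @param er_p Edge probability for the `erdos_renyi` topology.
#' @param pa_m Edges per new vertex for the `scale_free` topology.
#' @param seed Integer seed; all generators are reproducible given the
#'   scenario.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_genes = 300L,
                                topology = c("scale_free", "erdos_renyi"),
                                n_diseases = 4L,
                                core_size = 20L,
                                specific_size = 8L,
                                effect_size = 2,
                                n_case = 10L, n_control = 10L,
                                annotation_fe_target = 3,
                                annotation_size = 30L,
                                n_hr = 8L, n_lr = 8L,
                                n_drug_genes = 10L,
                                effect_hr = 0, effect_lr = 1.5,
                                drug_noise_sd = 0.5,
                                er_p = 0.02, pa_m = 2L,
                                seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 10, n_diseases >= 1, core_size >= 2,
            specific_size >= 2, effect_size >= 0,
            n_case >= 2, n_control >= 2, n_hr + n_lr >= 4)
  needed <- core_size + n_diseases * specific_size
  if (needed > n_genes) {
    stop("planted structure (", needed, " genes) exceeds n_genes", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  core <- genes[seq_len(core_size)]
  specific <- lapply(seq_len(n_diseases), function(d) {
    genes[core_size + (d - 1L) * specific_size + seq_len(specific_size)]
  })
  names(specific) <- paste0("disease", seq_len(n_diseases))
  drug_genes <- core[seq_len(min(n_drug_genes, core_size))]
  structure(list(n_genes = n_genes, genes = genes, topology = topology,
                 n_diseases = n_diseases, core_genes = core,
                 specific_genes = specific, effect_size = effect_size,
                 n_case = n_case, n_control = n_control,
                 annotation_fe_target = annotation_fe_target,
                 annotation_size = annotation_size,
                 n_hr = n_hr, n_lr = n_lr, drug_genes = drug_genes,
                 effect_hr = effect_hr, effect_lr = effect_lr,
                 drug_noise_sd = drug_noise_sd,
                 er_p = er_p, pa_m = pa_m, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("simulation_scenario:", x$n_genes, "genes (", x$topology, "),",
      x$n_diseases, "diseases, core of", length(x$core_genes),
      "genes, effect", x$effect_size, "SD\n")
  invisible(x)
}

#' Simulate an interactome with planted cliques
#'
#' Builds a background graph of the scenario's topology, then adds all
#' edges of the planted cliques (the core module as one clique and each
#' disease-specific module as another). Planted edges carry confidence
#' 0.9 so the conventional 0.7 confidence filter never removes planted
#' structure; background edges draw confidences uniformly from
#' \[0.7, 1\].
#'
#' @param scenario A [simulation_scenario()].
#' @return An `igraph` network with a `confidence` edge attribute.
#' @export
simulate_interactome <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  withr_seed(scenario$seed, {
    g <- if (scenario$topology == "scale_free") {
      igraph::sample_pa(scenario$n_genes, power = 1, m = scenario$pa_m,
                        directed = FALSE)
    } else {
      igraph::sample_gnp(scenario$n_genes, scenario$er_p)
    }
    igraph::V(g)$name <- scenario$genes
    planted <- c(list(scenario$core_genes), scenario$specific_genes)
    planted_pairs <- do.call(cbind, lapply(planted, utils::combn, m = 2L))
    g <- igraph::add_edges(g, as.vector(planted_pairs))
    g <- igraph::simplify(g)
    igraph::E(g)$confidence <- stats::runif(igraph::ecount(g), 0.7, 1)
    eids <- igraph::get_edge_ids(g, as.vector(planted_pairs))
    igraph::E(g)$confidence[eids] <- 0.9
    g
  })
}

#' Simulate expression studies for a disease collection
#'
#' One genes-by-samples Gaussian matrix (unit within-group SD) per
#' disease; cases are shifted by the scenario effect size on the shared
#' core plus that disease's specific genes.
#'
#' @param net The simulated interactome (gene names define the universe).
#' @param scenario A [simulation_scenario()].
#' @return A list with `studies` (named list of [expression_study()])
#'   and `truth` (planted memberships).
#' @export
simulate_disease_collection <- function(net, scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  genes <- igraph::V(net)$name
  if (!all(scenario$core_genes %in% genes)) {
    stop("core genes missing from network", call. = FALSE)
  }
  n_s <- scenario$n_case + scenario$n_control
  labels <- c(rep("case", scenario$n_case), rep("control", scenario$n_control))
  studies <- withr_seed(scenario$seed + 1L, {
    lapply(seq_len(scenario$n_diseases), function(d) {
      m <- matrix(stats::rnorm(length(genes) * n_s), nrow = length(genes),
                  dimnames = list(genes, sprintf("d%d_s%02d", d, seq_len(n_s))))
      affected <- union(scenario$core_genes, scenario$specific_genes[[d]])
      m[affected, seq_len(scenario$n_case)] <-
        m[affected, seq_len(scenario$n_case)] + scenario$effect_size
      expression_study(m, labels)
    })
  })
  names(studies) <- names(scenario$specific_genes)
  list(studies = studies,
       truth = list(core = scenario$core_genes,
                    specific = scenario$specific_genes,
                    effect_size = scenario$effect_size))
}

#' Simulate an annotation set with a target fold enrichment
#'
#' Samples an annotation of size `K` whose expected overlap with
#' `target_set` realizes fold enrichment approximately `fe_target`:
#' `round(fe_target * K * |target| / N)` genes from the target set, the
#' rest from outside it.
#'
#' @param universe Character vector of all genes.
#' @param target_set Genes the annotation should be enriched in.
#' @param fe_target Target fold enrichment (>= 0); must satisfy
#'   `fe_target * K / N <= 1` and an expected overlap no larger than the
#'   target set.
#' @param K Annotation size.
#' @param seed Integer seed.
#' @return Character vector of annotated genes.
#' @export
simulate_annotations <- function(universe, target_set, fe_target, K, seed = 1L) {
  universe <- unique(as.character(universe))
  target_set <- intersect(unique(as.character(target_set)), universe)
  N <- length(universe)
  if (K > N) stop("annotation size K exceeds the universe", call. = FALSE)
  k_in <- round(fe_target * K * length(target_set) / N)
  if (fe_target * K / N > 1 || k_in > length(target_set) || k_in > K) {
    stop("infeasible enrichment target: fe_target * K/N must be <= 1 and ",
         "the implied overlap must fit in the target set", call. = FALSE)
  }
  withr_seed(seed, {
    inside <- sample(target_set, k_in)
    outside <- sample(setdiff(universe, target_set), K - k_in)
    sort(c(inside, outside))
  })
}

#' Simulate a paired-treatment responder cohort
#'
#' Pre-treatment expression is Gaussian with unit between-subject SD;
#' post-treatment expression adds within-subject noise
#' (`drug_noise_sd`) plus a drug effect on the scenario's drug genes
#' whose size differs by responder group, emulating a treatment that
#' perturbs one group more than the other.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [responder_cohort()] with labels `"HR"` and `"LR"`.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (scenario$n_hr + scenario$n_lr < 4L) {
    stop("need at least 4 cohort samples", call. = FALSE)
  }
  genes <- scenario$genes
  n_s <- scenario$n_hr + scenario$n_lr
  labels <- c(rep("HR", scenario$n_hr), rep("LR", scenario$n_lr))
  ids <- sprintf("subj%02d", seq_len(n_s))
  withr_seed(scenario$seed + 2L, {
    pre <- matrix(stats::rnorm(length(genes) * n_s), nrow = length(genes),
                  dimnames = list(genes, ids))
    post <- pre + matrix(stats::rnorm(length(genes) * n_s,
                                      sd = scenario$drug_noise_sd),
                         nrow = length(genes))
    shift <- ifelse(labels == "HR", scenario$effect_hr, scenario$effect_lr)
    post[scenario$drug_genes, ] <- post[scenario$drug_genes, ] +
      rep(shift, each = length(scenario$drug_genes))
    responder_cohort(pre, post, labels)
  })
}
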