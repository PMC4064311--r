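#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate -> per-disease module detection -> pleiotropy
#' null -> annotation enrichment -> responder classification, writing all
#' stage outputs and a run manifest (parameters and seeds) to
#' `out_dir`. Reruns with the same configuration produce identical
#' payloads.
#'
#' @param config Either a path to a YAML file or a list. Recognized
#'   fields: `scenario` (a list of [simulation_scenario()] arguments;
#'   presence selects simulation mode), or `network`, `de` (paths; `de` a
#'   named list of DE TSVs) for pre-computed inputs; plus `n_perm`,
#'   `n_repeats`, `alpha`, `fdr`, `seed`, `min_size`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the pipeline results (`pleiotropy`,
#'   `enrichment`, `classifier`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  n_perm <- config$n_perm %||% 1000L
  n_repeats <- config$n_repeats %||% 50L
  alpha <- config$alpha %||% 0.01
  fdr <- config$fdr %||% 0.05
  seed <- config$seed %||% 1L
  min_size <- config$min_size %||% 2L
  stopifnot(alpha > 0, alpha < 1, fdr > 0, fdr < 1, n_perm >= 1, n_repeats >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package_version = as.character(utils::packageVersion("pleiomod")),
                   params = list(n_perm = n_perm, n_repeats = n_repeats,
                                 alpha = alpha, fdr = fdr, seed = seed,
                                 min_size = min_size),
                   stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    write_manifest()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(err),
         call. = FALSE)
  }

  simulated <- !is.null(config$scenario)
  scenario <- NULL
  tryCatch({
    if (simulated) {
      scenario <- do.call(simulation_scenario,
                          c(config$scenario, list(seed = seed)))
      net <- simulate_interactome(scenario)
      coll <- simulate_disease_collection(net, scenario)
      de_list <- lapply(coll$studies, per_gene_ttest)
      annotation <- simulate_annotations(scenario$genes, scenario$core_genes,
                                         scenario$annotation_fe_target,
                                         scenario$annotation_size,
                                         seed = seed + 3L)
      write_edge_list(net, file.path(out_dir, "edges.tsv"))
      for (d in names(coll$studies)) {
        write_expression_study(coll$studies[[d]],
                               file.path(out_dir, paste0(d, "_expr.tsv")),
                               file.path(out_dir, paste0(d, "_labels.tsv")))
      }
      write_gmt(list(planted_core = coll$truth$core,
                     annotation = annotation),
                file.path(out_dir, "truth_sets.gmt"))
      jsonlite::write_json(coll$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$simulate <- list(status = "ok",
                                       n_genes = scenario$n_genes,
                                       n_diseases = scenario$n_diseases)
    } else {
      if (is.null(config$network) || is.null(config$de)) {
        stop("config needs either `scenario` or `network` + `de` paths")
      }
      net <- load_network(config$network,
                          score_threshold = config$score_threshold %||% 0.7)
      de_list <- lapply(config$de, read_de_result)
      annotation <- if (!is.null(config$annotation_gmt)) {
        read_gmt(config$annotation_gmt)[[1L]]
      } else NULL
      manifest$stages$load <- list(status = "ok",
                                   n_genes = igraph::vcount(net),
                                   n_diseases = length(de_list))
    }
  }, error = function(e) fail("inputs", e))

  for (d in names(de_list)) {
    write_de_result(de_list[[d]], file.path(out_dir, paste0(d, "_de.tsv")))
  }

  pleio <- tryCatch(
    pleiotropy_null(net, de_list, n_repeats = n_repeats, n_perm = n_perm,
                    alpha = alpha, min_size = min_size, seed = seed,
                    verbose = FALSE),
    error = function(e) fail("pleiotropy", e))
  for (m in pleio$modules) {
    jsonlite::write_json(
      list(disease_name = m$disease_name, genes = m$genes,
           cliques = lapply(seq_along(m$source_cliques$genes), function(i) {
             list(genes = m$source_cliques$genes[[i]],
                  weight = m$source_cliques$weight[i],
                  empirical_p = m$source_cliques$empirical_p[i])
           })),
      file.path(out_dir, paste0("module_", m$disease_name, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(diseases = pleio$diseases, intersection = pleio$intersection,
         module_count = as.list(pleio$module_count),
         null_intersection_sizes = pleio$null_intersection_sizes,
         fold_enrichment = pleio$fold_enrichment, p = pleio$p,
         params = pleio$params),
    file.path(out_dir, "pleiotropy.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$pleiotropy <- list(status = "ok",
                                     intersection_size = length(pleio$intersection),
                                     p = pleio$p,
                                     fold_enrichment = pleio$fold_enrichment)

  enrich <- NULL
  if (!is.null(annotation) && length(pleio$intersection) > 0L) {
    enrich <- tryCatch({
      universe <- igraph::V(net)$name
      k <- length(intersect(pleio$intersection, annotation))
      n <- length(pleio$intersection)
      K <- length(intersect(annotation, universe))
      N <- length(universe)
      data.frame(set = "annotation", k = k, n = n, K = K, N = N,
                 FE = fold_enrichment(k, n, K, N),
                 p = fisher_enrichment(k, n, K, N))
    }, error = function(e) fail("enrichment", e))
    enrich$q <- bh_fdr(enrich$p)
    utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrichment <- list(status = "ok", FE = enrich$FE,
                                       p = enrich$p)
  }

  classifier <- NULL
  if (simulated) {
    classifier <- tryCatch({
      cohort <- simulate_cohort(scenario)
      cand <- drug_responsive_genes(cohort, alpha = 0.05)
      genes_used <- restrict_to_modules(cand, pleio$module_count,
                                        min_modules = 2L)
      if (length(genes_used) < 2L) genes_used <- cand
      X <- t(cohort$post[genes_used, , drop = FALSE])
      classifier_permutation_test(X, cohort$labels,
                                  n_perm = config$class_n_perm %||% 200L,
                                  seed = seed + 4L)
    }, error = function(e) fail("classification", e))
    jsonlite::write_json(
      list(genes_used = classifier$genes_used, lambda = classifier$lambda,
           probabilities = as.list(classifier$probabilities),
           calls = as.list(classifier$calls),
           n_correct = classifier$n_correct,
           permutation_p = classifier$permutation_p),
      file.path(out_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$classification <-
      list(status = "ok", n_correct = classifier$n_correct,
           n_samples = length(classifier$labels),
           permutation_p = classifier$permutation_p)
  }

  write_manifest()
  invisible(list(pleiotropy = pleio, enrichment = enrich,
                 classifier = classifier, manifest = manifest))
}
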