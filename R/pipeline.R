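#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. The
#' defaults reproduce the standard parameterization of the analysis: floor
#' computed from negative controls (conventionally 100), fold-change
#' threshold 1.2, PFP alpha 0.05, sample-graph correlation threshold 0.85
#' with inflation 3.0, probe-graph threshold 0.80 with inflation 2.2.
#'
#' @param ... Named overrides of the defaults; unknown keys are an error.
#'   `config` may also be a path to a YAML file with the same keys.
#' @returns A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    floor = NULL,                  # NULL = compute from negative controls
    fc_threshold = 1.2,
    pfp_alpha = 0.05,
    n_permutations = 100L,
    max_pairs = 100L,
    scale = "raw",
    sample_r = 0.85,
    probe_r = 0.80,
    inflation_sample = 3.0,
    inflation_probe = 2.2,
    collapse_rule = "max_mean",
    exclude = "induction",
    simulate = list()              # overrides passed to simulate_study()
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.character(over[[1]])) {
    over <- yaml::read_yaml(over[[1]])
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  structure(modifyList(defaults, over), class = "pipeline_config")
}

# Paths of the files each stage writes; later stages read them back, so a
# stage subset can resume from a previous run in the same out_dir.
stage_paths <- function(out_dir) {
  list(
    expression = file.path(out_dir, "expression.tsv"),
    controls = file.path(out_dir, "control_probes.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    normalized = file.path(out_dir, "normalized.tsv"),
    de_table = file.path(out_dir, "de_table.tsv"),
    sample_graph = file.path(out_dir, "sample_graph.graphml"),
    sample_clusters = file.path(out_dir, "sample_clusters.tsv"),
    probe_clusters = file.path(out_dir, "probe_clusters.tsv"),
    cluster_profiles = file.path(out_dir, "cluster_profiles.tsv"),
    meta_table = file.path(out_dir, "meta_analysis.tsv"),
    concordance = file.path(out_dir, "concordance.tsv"),
    sensitivity = file.path(out_dir, "sensitivity.tsv"),
    report = file.path(out_dir, "run_report.json")
  )
}

require_stage_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(paste0("missing input '", basename(path), "': run the '", produced_by,
                 "' stage first"))
  }
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a shared output directory with file-based
#' handoff: `simulate` writes a synthetic study; `preprocess` background
#' corrects, normalizes and floor filters; `de` runs the rank-product
#' analysis; `network` builds and clusters the sample and probe graphs;
#' `meta` simulates two replication studies and pools standardized mean
#' differences over the common genes; `sensitivity` re-derives fold changes
#' without induced/augmented samples. A machine-readable JSON run report
#' records the configuration, seed, floor, filter counts and stage outputs.
#' Every output is bit-identical given the same config and seed.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by it).
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "de", "network", "meta", "sensitivity")`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @returns The run report, invisibly (a named list, also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess", "de",
                                    "network", "meta", "sensitivity"),
                         out_dir = NULL) {
  if (is.character(config)) config <- pipeline_config(config)
  all_stages <- c("simulate", "preprocess", "de", "network", "meta", "sensitivity")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  out_dir <- out_dir %||% config$out_dir %||% abort("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(out_dir)
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 stages = stages, warnings = character(0))
  note <- function(msg) report$warnings <<- c(report$warnings, msg)

  if ("simulate" %in% stages) {
    study <- do.call(simulate_study, c(list(seed = config$seed), config$simulate))
    write_study_tsv(study, out_dir)
    report$simulate <- list(n_probes = nrow(study$expression),
                            n_samples = nrow(study$metadata))
  }

  if ("preprocess" %in% stages) {
    expr <- read_expression_tsv(require_stage_file(p$expression, "simulate"),
                                p$controls)
    meta <- read_metadata_tsv(p$metadata)
    pre <- withCallingHandlers(
      preprocess_study(expr, meta, floor = config$floor),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    write_expression_tsv(pre$expression, p$normalized)
    report$preprocess <- c(list(floor = pre$floor), pre$counts)
  }

  if ("de" %in% stages) {
    expr <- read_expression_tsv(require_stage_file(p$normalized, "preprocess"))
    meta <- read_metadata_tsv(p$metadata)
    fit <- rank_product_de(expr, meta,
                           fc_threshold = config$fc_threshold,
                           pfp_alpha = config$pfp_alpha,
                           n_permutations = config$n_permutations,
                           max_pairs = config$max_pairs,
                           scale = config$scale, seed = config$seed)
    readr::write_tsv(fit$table, p$de_table)
    report$de <- glance(fit)
  }

  if ("network" %in% stages) {
    expr <- read_expression_tsv(require_stage_file(p$normalized, "preprocess"))
    meta <- read_metadata_tsv(p$metadata)
    de_tab <- readr::read_tsv(require_stage_file(p$de_table, "de"),
                              show_col_types = FALSE)
    sel <- select_differential(de_tab, config$fc_threshold, config$pfp_alpha)
    de_probes <- c(sel$up, sel$down)
    if (length(de_probes) < 2) abort("too few differential probes for network analysis")
    de_expr <- expr[expr$probe_id %in% de_probes, , drop = FALSE]

    sg <- correlation_graph(de_expr, "sample", config$sample_r)
    sc <- mcl_cluster(sg, inflation = config$inflation_sample)
    assoc <- cluster_trait_association(sc, meta, "group")
    write_graphml(sg, p$sample_graph, metadata = meta, clustering = sc)
    readr::write_tsv(sc$assignment, p$sample_clusters)

    pg <- correlation_graph(de_expr, "probe", config$probe_r)
    pc <- mcl_cluster(pg, inflation = config$inflation_probe)
    readr::write_tsv(pc$assignment, p$probe_clusters)
    prof <- cluster_profiles(de_expr, pc)
    readr::write_tsv(prof, p$cluster_profiles)
    if (!sc$converged || !pc$converged) note("MCL did not converge")
    report$network <- list(
      n_de_probes = length(de_probes),
      sample_clusters = sc$n_clusters, probe_clusters = pc$n_clusters,
      labour_association = list(method = assoc$method, p_value = assoc$p_value))
  }

  if ("meta" %in% stages) {
    expr <- read_expression_tsv(require_stage_file(p$expression, "simulate"),
                                p$controls)
    meta <- read_metadata_tsv(p$metadata)
    reps <- simulate_multistudy(
      designs = list(list(n_labour = 6, n_nonlabour = 6),
                     list(n_labour = 7, n_nonlabour = 6)),
      shared_gene_fraction = 0.8, attenuation = c(1, 1),
      seed = config$seed + 1L)
    studies <- c(list(index = list(expression = expr, metadata = meta)),
                 lapply(reps, function(s) s[c("expression", "metadata")]))
    studies <- lapply(studies, function(s) {
      pre <- preprocess_study(s$expression, s$metadata, floor = config$floor)
      list(expression = pre$expression, metadata = s$metadata)
    })
    mr <- meta_analyse(studies, rule = config$collapse_rule)
    readr::write_tsv(mr$table, p$meta_table)
    readr::write_tsv(mr$smd, file.path(out_dir, "study_smd.tsv"))
    report$meta <- list(n_genes = nrow(mr$table), k = length(studies))
  }

  if ("sensitivity" %in% stages) {
    expr <- read_expression_tsv(require_stage_file(p$normalized, "preprocess"))
    meta <- read_metadata_tsv(p$metadata)
    sens <- subgroup_sensitivity(expr, meta, exclude = config$exclude)
    readr::write_tsv(sens, p$sensitivity)
    report$sensitivity <- as.list(sens)
  }

  jsonlite::write_json(report, p$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
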