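# broom-style tidiers for the package's fitted objects.

#' Tidy a rank-product DE fit
#'
#' @param x An `rp_de` object.
#' @param ... Unused.
#' @returns The per-probe result tibble.
#' @method tidy rp_de
#' @export
tidy.rp_de <- function(x, ...) x$table

#' One-row summary of a rank-product DE fit
#'
#' @param x An `rp_de` object.
#' @param ... Unused.
#' @returns A one-row tibble: probe counts, up/down calls, configuration.
#' @method glance rp_de
#' @export
glance.rp_de <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$table),
    n_up = sum(x$table$call == "up"),
    n_down = sum(x$table$call == "down"),
    n_comparisons = x$config$n_comparisons,
    n_permutations = x$config$n_permutations,
    fc_threshold = x$config$fc_threshold,
    pfp_alpha = x$config$pfp_alpha,
    scale = x$config$scale,
    seed = x$config$seed
  )
}

#' Tidy an MCL clustering
#'
#' @param x An `mcl_clustering` object.
#' @param ... Unused.
#' @returns The node-to-cluster assignment tibble.
#' @method tidy mcl_clustering
#' @export
tidy.mcl_clustering <- function(x, ...) x$assignment

#' One-row summary of an MCL clustering
#'
#' @param x An `mcl_clustering` object.
#' @param ... Unused.
#' @returns A one-row tibble with cluster counts and convergence info.
#' @method glance mcl_clustering
#' @export
glance.mcl_clustering <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$assignment),
    n_clusters = x$n_clusters,
    n_singletons = sum(x$assignment$is_singleton),
    inflation = x$inflation,
    iterations = x$iterations,
    converged = x$converged,
    max_colsum_dev = x$max_colsum_dev
  )
}

#' Tidy a meta-analysis result
#'
#' @param x A `meta_result` object.
#' @param ... Unused.
#' @returns The per-gene pooled-effect tibble (fixed and random estimates,
#'   heterogeneity statistics).
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) x$table

#' One-row summary of a meta-analysis result
#'
#' @param x A `meta_result` object.
#' @param ... Unused.
#' @returns A one-row tibble with gene/study counts and heterogeneity
#'   summaries.
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    k_studies = length(unique(x$smd$study)),
    median_tau2 = median(x$table$tau2),
    prop_heterogeneous = mean(x$table$p_Q < 0.05, na.rm = TRUE)
  )
}
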