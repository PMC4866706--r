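#' Thresholded Pearson correlation graph
#'
#' Builds an undirected weighted graph whose nodes are samples
#' (`mode = "sample"`) or probes (`mode = "probe"`). An edge joins two nodes
#' iff their Pearson correlation is *strictly above* the threshold; negative
#' correlations therefore never create edges at the positive thresholds used
#' here (0.85 for samples, 0.80 for probes). In sample mode each probe's
#' values are standardized (z-scored across samples) before correlation —
#' pairwise correlations are location/scale invariant per probe, but
#' standardization fixes a definite convention for the multi-probe profile.
#' Zero-variance node vectors are dropped with a warning.
#'
#' @param expr Expression tibble; for sample mode, typically restricted to
#'   the differentially expressed probes.
#' @param mode `"sample"` or `"probe"`.
#' @param threshold Correlation cutoff (strictly-greater semantics).
#' @param log_scale Correlate log2-transformed intensities (the standard
#'   scale for co-expression networks; default TRUE, requires positive
#'   values).
#' @returns An object of class `correlation_graph`: list with `nodes`
#'   (character), `edges` (tibble `from`, `to`, `weight`), `threshold`,
#'   `mode`, and `dropped` (zero-variance nodes).
#' @export
correlation_graph <- function(expr, mode = c("sample", "probe"),
                              threshold = if (match.arg(mode) == "sample") 0.85 else 0.80,
                              log_scale = TRUE) {
  mode <- match.arg(mode)
  parts <- expr_parts(expr)
  mat <- parts$mat
  if (log_scale) {
    if (any(mat <= 0)) abort("log_scale correlation requires positive intensities")
    mat <- log2(mat)
  }
  if (mode == "sample") {
    mu <- rowMeans(mat)
    s <- apply(mat, 1, sd)
    keep <- s > 0
    if (!all(keep)) warn(paste0(sum(!keep), " zero-variance probes dropped before correlation"))
    mat <- (mat[keep, , drop = FALSE] - mu[keep]) / s[keep]
    vecs <- mat                       # columns are the node vectors
  } else {
    vecs <- t(mat)                    # columns are probes
  }
  if (nrow(vecs) < 3) abort("need >= 3 observations per correlation")
  all_nodes <- colnames(vecs)
  v <- apply(vecs, 2, sd)
  keep <- v > 0
  if (!all(keep)) {
    warn(paste0(sum(!keep), " zero-variance nodes dropped: ",
                paste(head(colnames(vecs)[!keep], 5), collapse = ", ")))
    vecs <- vecs[, keep, drop = FALSE]
  }
  if (ncol(vecs) == 0) abort("all nodes dropped (zero variance)")

  cm <- cor(vecs)
  nodes <- colnames(vecs)
  idx <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    weight = cm[idx]
  )
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold, mode = mode,
         dropped = setdiff(all_nodes, nodes)),
    class = "correlation_graph"
  )
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("<correlation_graph> ", x$mode, "-mode, ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges at r > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Markov Clustering (MCL) of a weighted graph
#'
#' A dense implementation of the MCL algorithm. The weighted adjacency
#' matrix (plus a self-loop on every node) is column-normalized to a
#' stochastic matrix and then iterated through *expansion* (matrix power,
#' simulating longer random-walk flow) and *inflation* (elementwise power
#' followed by column renormalization, strengthening strong flows), with
#' pruning of near-zero entries, until the matrix change falls below `tol`.
#' Clusters are the connected components of the non-zero structure of the
#' limit matrix (the attractor systems); because components yield a
#' partition directly, a node attracted to several attractors in the same
#' component belongs to that component's cluster. Larger inflation gives
#' finer clusterings. Fully deterministic.
#'
#' @param graph A `correlation_graph` (or any list with `nodes` and an edge
#'   tibble `from`/`to`/`weight`).
#' @param inflation Inflation exponent (> 1); 3.0 is used for sample graphs
#'   and 2.2 for probe graphs in the default pipeline.
#' @param expansion Integer matrix-power (default 2).
#' @param self_loop_weight Weight added to each diagonal (default 1).
#' @param prune_below Entries below this value are zeroed each iteration.
#' @param tol Convergence tolerance on the max absolute change.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   clustering with `converged = FALSE` and a warning.
#' @returns An object of class `mcl_clustering`: list with `assignment`
#'   (tibble `node`, `cluster`, `is_singleton`; cluster 1 is the largest,
#'   ties broken by smallest member label), `n_clusters`, `converged`,
#'   `iterations`, and `max_colsum_dev` (worst deviation of any column sum
#'   from 1 across all normalization steps).
#' @export
mcl_cluster <- function(graph, inflation, expansion = 2L,
                        self_loop_weight = 1, prune_below = 1e-5,
                        tol = 1e-6, max_iter = 200L) {
  if (inflation <= 1) abort("inflation must be > 1")
  check_positive(tol, "tol")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) abort("empty graph")

  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    fi <- match(e$from, nodes); ti <- match(e$to, nodes)
    A[cbind(fi, ti)] <- e$weight
    A[cbind(ti, fi)] <- e$weight
  }
  diag(A) <- diag(A) + self_loop_weight

  colnorm <- function(M) sweep(M, 2, colSums(M), `/`)
  max_dev <- 0
  M <- colnorm(A)
  max_dev <- max(max_dev, max(abs(colSums(M) - 1)))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M2 <- M
    for (p in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- colnorm(M2^inflation)
    M2[M2 < prune_below] <- 0
    M2 <- colnorm(M2)
    max_dev <- max(max_dev, max(abs(colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("MCL did not converge within max_iter; returning current clustering")

  structure_graph <- igraph::graph_from_adjacency_matrix(
    (M + t(M)) > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(structure_graph)$membership

  # Relabel clusters: 1 = largest, ties by smallest member label.
  sizes <- table(comp)
  first_member <- vapply(names(sizes), function(cl) min(nodes[comp == as.integer(cl)]),
                         character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  cluster <- unname(relabel[as.character(comp)])

  assignment <- tibble::tibble(
    node = nodes, cluster = cluster,
    is_singleton = cluster %in% which(tabulate(cluster) == 1)
  )
  structure(
    list(assignment = assignment, n_clusters = max(cluster),
         converged = converged, iterations = iter, max_colsum_dev = max_dev,
         inflation = inflation, mode = graph$mode %||% NA_character_),
    class = "mcl_clustering"
  )
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat("<mcl_clustering> ", x$n_clusters, " clusters over ",
      nrow(x$assignment), " nodes (inflation ", x$inflation, ", ",
      x$iterations, " iterations", if (!x$converged) ", NOT converged", ")\n",
      sep = "")
  invisible(x)
}

#' Association between cluster membership and a binary trait
#'
#' Cross-tabulates MCL cluster membership (sample mode) against a binary
#' sample trait and tests for association: Fisher's exact test when any
#' expected cell count is below 5, otherwise Pearson's chi-squared test
#' (without continuity correction). Singleton clusters are pooled into a
#' single "unclustered" row by default: a cluster of one carries no grouping
#' information of its own, and a table padded with singleton rows makes the
#' exact test degenerate. A degenerate table (a zero margin or fewer than
#' two rows) returns p = 1 with a warning.
#'
#' @param clustering An `mcl_clustering` from a sample-mode graph.
#' @param metadata Sample metadata tibble.
#' @param trait Name of a metadata column (coerced to a binary factor), or a
#'   vector of trait values aligned with `metadata$sample_id`.
#' @param singletons `"pool"` (default): merge singleton clusters into one
#'   "unclustered" row; `"keep"`: one row per singleton.
#' @param test `"auto"` (default, expected-cell rule), or force `"fisher"` /
#'   `"chisq"`.
#' @returns A list with `method`, `statistic` (NA for Fisher), `p_value` and
#'   the contingency `table`.
#' @export
cluster_trait_association <- function(clustering, metadata, trait,
                                      singletons = c("pool", "keep"),
                                      test = c("auto", "fisher", "chisq")) {
  singletons <- match.arg(singletons)
  test <- match.arg(test)
  a <- clustering$assignment
  if (singletons == "pool" && any(a$is_singleton)) {
    a$cluster <- ifelse(a$is_singleton, 0L, a$cluster)
  }
  idx <- match(a$node, metadata$sample_id)
  if (all(is.na(idx))) {
    abort("cluster nodes missing from metadata (sample-mode clustering required)")
  }
  # metadata may cover a subset of samples (e.g. a within-group test of a
  # treatment covariate); nodes without metadata are left out of the table.
  a <- a[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  tr <- if (length(trait) == 1 && is.character(trait)) {
    if (!trait %in% names(metadata)) abort(paste0("no metadata column '", trait, "'"))
    metadata[[trait]][idx]
  } else {
    trait[idx]
  }
  tr <- factor(tr)
  if (nlevels(tr) != 2) abort("trait must be binary")
  tab <- table(cluster = a$cluster, trait = tr)

  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || nrow(tab) < 2) {
    warn("degenerate contingency table; no association testable")
    return(list(method = "none", statistic = NA_real_, p_value = 1, table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(test, auto = any(expected < 5), fisher = TRUE,
                       chisq = FALSE)
  if (use_fisher) {
    ht <- fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p_value = ht$p.value, table = tab)
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(method = "chisq", statistic = unname(ht$statistic),
         p_value = ht$p.value, table = tab)
  }
}

#' Mean expression profiles of probe clusters
#'
#' For each probe cluster, the per-sample mean expression over member probes
#' with its standard error (SD over member probes divided by the square root
#' of the cluster size; singleton clusters report SE = 0 and are flagged).
#'
#' @param expr Expression tibble covering all clustered probes.
#' @param clustering An `mcl_clustering` from a probe-mode graph.
#' @returns A tibble of class `cluster_profiles`: `cluster`, `n_probes`,
#'   `sample_id`, `mean`, `se`, `is_singleton`.
#' @export
cluster_profiles <- function(expr, clustering) {
  parts <- expr_parts(expr)
  a <- clustering$assignment
  miss <- setdiff(a$node, rownames(parts$mat))
  if (length(miss)) abort(paste0("probes missing from matrix: ",
                                 paste(head(miss, 5), collapse = ", ")))
  out <- purrr::map_dfr(sort(unique(a$cluster)), function(cl) {
    probes <- a$node[a$cluster == cl]
    sub <- parts$mat[probes, , drop = FALSE]
    m <- colMeans(sub)
    se <- if (nrow(sub) > 1) apply(sub, 2, sd) / sqrt(nrow(sub)) else rep(0, ncol(sub))
    tibble::tibble(cluster = cl, n_probes = nrow(sub),
                   sample_id = colnames(sub), mean = unname(m),
                   se = unname(se), is_singleton = nrow(sub) == 1)
  })
  class(out) <- c("cluster_profiles", class(out))
  out
}

#' Export a correlation graph as GraphML
#'
#' Writes the graph with edge weights (and optional node attributes from
#' metadata or a clustering) in GraphML for use in external viewers.
#'
#' @param graph A `correlation_graph`.
#' @param path Output file path.
#' @param metadata Optional sample metadata (sample-mode graphs): columns
#'   become node attributes.
#' @param clustering Optional `mcl_clustering`: adds a `cluster` attribute.
#' @returns The path, invisibly.
#' @export
write_graphml <- function(graph, path, metadata = NULL, clustering = NULL) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  if (!is.null(metadata)) {
    idx <- match(graph$nodes, metadata$sample_id)
    for (col in setdiff(names(metadata), "sample_id")) {
      g <- igraph::set_vertex_attr(g, col, value = metadata[[col]][idx])
    }
  }
  if (!is.null(clustering)) {
    idx <- match(graph$nodes, clustering$assignment$node)
    g <- igraph::set_vertex_attr(g, "cluster",
                                 value = clustering$assignment$cluster[idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
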