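test_that("edges appear exactly where correlation exceeds the threshold", {
  # identical probe vectors -> r = 1 -> edge at any threshold < 1
  expr <- tibble::tibble(probe_id = c("a", "b", "c"),
                         S01 = c(1, 2, 4), S02 = c(2, 4, 3),
                         S03 = c(3, 6, 2), S04 = c(4, 8, 1))
  g <- correlation_graph(expr, "probe", threshold = 0.85, log_scale = FALSE)
  expect_true(any(g$edges$from == "a" & g$edges$to == "b"))
  # perfectly anti-correlated pair never crosses a positive threshold
  expect_false(any((g$edges$from == "a" & g$edges$to == "c") |
                     (g$edges$from == "c" & g$edges$to == "a")))
})

test_that("probe-graph edge set equals direct pairwise Pearson computation", {
  withr::with_seed(23, {
    mat <- matrix(rlnorm(4 * 10, 3, 0.5), nrow = 10)
    colnames(mat) <- sprintf("S%02d", 1:4)
    expr <- expr_from_matrix(t(mat), probe_ids = sprintf("N%d", 1:4))
    thr <- 0.3
    g <- correlation_graph(expr, "probe", threshold = thr, log_scale = TRUE)
    cm <- cor(log2(mat))
    for (i in 1:3) for (j in (i + 1):4) {
      present <- any((g$edges$from == paste0("N", i) & g$edges$to == paste0("N", j)) |
                       (g$edges$from == paste0("N", j) & g$edges$to == paste0("N", i)))
      expect_identical(present, cm[i, j] > thr)
      if (present) {
        w <- g$edges$weight[(g$edges$from == paste0("N", i) & g$edges$to == paste0("N", j)) |
                              (g$edges$from == paste0("N", j) & g$edges$to == paste0("N", i))]
        expect_equal(w, cm[i, j], tolerance = 1e-12)
      }
    }
  })
})

test_that("sample-mode z-scoring drops zero-variance probes with a warning", {
  expr <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                         S01 = c(1, 5, 5, 2), S02 = c(2, 5, 6, 4),
                         S03 = c(3, 5, 7, 8))
  expect_warning(g <- correlation_graph(expr, "sample", threshold = 0.5,
                                        log_scale = FALSE),
                 "zero-variance probes")
  expect_identical(g$nodes, c("S01", "S02", "S03"))
})

test_that("MCL returns disjoint cliques exactly for any inflation > 1", {
  g <- clique_graph(c(5, 4, 3))
  for (infl in c(1.5, 2.2, 3.0, 4.0)) {
    cl <- mcl_cluster(g, inflation = infl)
    expect_identical(cl$n_clusters, 3L)
    expect_equal(adjusted_rand_index(cl$assignment$cluster, g$truth), 1.0)
    expect_lte(cl$max_colsum_dev, 1e-9)
  }
  # cluster 1 is the largest
  cl <- mcl_cluster(g, inflation = 2.2)
  expect_identical(unname(table(cl$assignment$cluster)[1]), 5L)
})

test_that("a single self-looped node forms one cluster", {
  g <- list(nodes = "n1", edges = tibble::tibble(from = character(0),
                                                 to = character(0),
                                                 weight = numeric(0)),
            mode = "sample")
  cl <- mcl_cluster(g, inflation = 3)
  expect_identical(cl$n_clusters, 1L)
  expect_true(cl$assignment$is_singleton)
})

test_that("planted 3-block correlation structure is recovered perfectly", {
  pb <- planted_blocks(seed = 31)
  expr <- expr_from_matrix(pb$mat, probe_ids = rownames(pb$mat))
  g <- correlation_graph(expr, "probe", threshold = 0.80, log_scale = FALSE)
  cl <- mcl_cluster(g, inflation = 2.2)
  expect_equal(adjusted_rand_index(cl$assignment$cluster, pb$truth), 1.0)
  expect_lte(cl$max_colsum_dev, 1e-9)
})

test_that("cluster count never decreases with inflation on a fixed graph", {
  pb <- planted_blocks(noise = 0.8, seed = 17)
  expr <- expr_from_matrix(pb$mat, probe_ids = rownames(pb$mat))
  g <- correlation_graph(expr, "probe", threshold = 0.3, log_scale = FALSE)
  ks <- vapply(c(1.5, 2.2, 3.0, 4.0),
               function(i) mcl_cluster(g, inflation = i)$n_clusters, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("association test picks Fisher vs chi-squared by expected counts", {
  f <- clustering_for_table(5, 0, 0, 5)
  res <- cluster_trait_association(f$clustering, f$metadata, "trait")
  expect_identical(res$method, "fisher")
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)

  f2 <- clustering_for_table(10, 10, 5, 5)
  res2 <- cluster_trait_association(f2$clustering, f2$metadata, "trait")
  expect_equal(res2$p_value, 1.0)

  f3 <- clustering_for_table(20, 10, 10, 20)
  res3 <- cluster_trait_association(f3$clustering, f3$metadata, "trait")
  expect_identical(res3$method, "chisq")
  expect_equal(res3$statistic,
               unname(suppressWarnings(
                 chisq.test(matrix(c(20, 10, 10, 20), 2, byrow = TRUE),
                            correct = FALSE)$statistic)))
})

test_that("degenerate contingency tables return p = 1 with a warning", {
  f <- clustering_for_table(5, 5, 0, 0)   # second cluster empty
  f$clustering$assignment <- f$clustering$assignment[1:10, ]
  expect_warning(res <- cluster_trait_association(f$clustering, f$metadata, "trait"),
                 "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("cluster profiles equal direct mean and standard-error computation", {
  mat <- rbind(c(1, 5, 2), c(3, 7, 4), c(10, 10, 10))
  expr <- expr_from_matrix(mat, probe_ids = c("p1", "p2", "p3"))
  cl <- structure(list(assignment = tibble::tibble(
    node = c("p1", "p2", "p3"), cluster = c(1L, 1L, 2L),
    is_singleton = c(FALSE, FALSE, TRUE))), class = "mcl_clustering")
  prof <- cluster_profiles(expr, cl)
  c1 <- prof[prof$cluster == 1, ]
  expect_equal(c1$mean, c(2, 6, 3))
  expect_equal(c1$se, rep(sd(c(1, 3)) / sqrt(2), 3))  # = 1 at every sample
  expect_equal(c1$se, rep(1, 3))
  c2 <- prof[prof$cluster == 2, ]
  expect_equal(c2$mean, c(10, 10, 10))
  expect_equal(c2$se, rep(0, 3))
  expect_true(all(c2$is_singleton))

  # random cluster against direct recomputation
  withr::with_seed(41, {
    m <- matrix(rnorm(50), 10, 5)
    e <- expr_from_matrix(m)
    asn <- tibble::tibble(node = e$probe_id,
                          cluster = rep(1:2, each = 5), is_singleton = FALSE)
    p <- cluster_profiles(e, structure(list(assignment = asn),
                                       class = "mcl_clustering"))
    expect_equal(p$mean[p$cluster == 2], colMeans(m[6:10, ]))
    expect_equal(p$se[p$cluster == 2], apply(m[6:10, ], 2, sd) / sqrt(5))
  })
})

test_that("graphml export writes node and edge attributes", {
  pb <- planted_blocks(n_blocks = 2, probes_per_block = 4, n_samples = 6, seed = 3)
  expr <- expr_from_matrix(pb$mat, probe_ids = rownames(pb$mat))
  g <- correlation_graph(expr, "probe", threshold = 0.5, log_scale = FALSE)
  cl <- mcl_cluster(g, inflation = 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path, clustering = cl)
  reread <- igraph::read_graph(path, format = "graphml")
  expect_identical(sort(igraph::V(reread)$name), sort(g$nodes))
  expect_true("cluster" %in% igraph::vertex_attr_names(reread))
  expect_equal(sort(igraph::E(reread)$weight), sort(g$edges$weight),
               tolerance = 1e-6)
})
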