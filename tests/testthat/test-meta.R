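test_that("probe collapsing keeps the highest-mean probe per gene", {
  expr <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene_symbol = c("GENE1", "GENE1", "GENE2"),
    S01 = c(400, 150, 7), S02 = c(600, 250, 9))
  out <- collapse_probes(expr)
  expect_identical(out$probe_id, c("GENE1", "GENE2"))
  expect_equal(out$S01[1], 400)  # the 500-mean probe wins over the 200-mean one

  avg <- collapse_probes(expr, rule = "mean")
  expect_equal(avg$S01[avg$gene_symbol == "GENE1"], mean(c(400, 150)))
})

test_that("harmonization intersects gene sets and errors on disjoint studies", {
  e1 <- tibble::tibble(probe_id = c("p1", "p2"), gene_symbol = c("A", "B"),
                       S01 = c(1, 2), S02 = c(3, 4))
  e2 <- tibble::tibble(probe_id = c("q1", "q2"), gene_symbol = c("B", "C"),
                       T01 = c(5, 6), T02 = c(7, 8))
  harm <- harmonize_genes(list(x = e1, y = e2))
  expect_identical(harm$x$gene_symbol, "B")
  expect_identical(harm$y$gene_symbol, "B")

  same <- harmonize_genes(list(x = e1, y = e1))
  expect_identical(same$x$gene_symbol, c("A", "B"))

  e3 <- tibble::tibble(probe_id = "r1", gene_symbol = "Z", U01 = 1, U02 = 2)
  expect_error(harmonize_genes(list(x = e1, z = e3)), "no genes shared")
})

test_that("Hedges g and its variance follow the closed forms", {
  s <- tibble::tibble(gene = "g1", mean_L = 12, mean_NL = 10,
                      sd_L = 2, sd_NL = 2, n_L = 10, n_NL = 10)
  out <- smd(s)
  expect_equal(out$d, 1.0)
  expect_equal(out$g, (1 - 3 / 71) * 1.0, tolerance = 1e-12)
  expect_equal(out$g, 0.95775, tolerance = 1e-4)
  expect_equal(out$var_g, 20 / 100 + out$g^2 / 40, tolerance = 1e-12)
  expect_equal(out$var_g, 0.22293, tolerance = 1e-4)

  # equal means: d = g = 0 and var reduces to the sample-size term
  s0 <- dplyr::mutate(s, mean_L = 10)
  out0 <- smd(s0)
  expect_equal(out0$g, 0)
  expect_equal(out0$var_g, 20 / 100)

  # antisymmetry under group swap
  swapped <- tibble::tibble(gene = "g1", mean_L = 10, mean_NL = 12,
                            sd_L = 2, sd_NL = 2, n_L = 10, n_NL = 10)
  out_sw <- smd(swapped)
  expect_equal(out_sw$g, -out$g, tolerance = 1e-12)
  expect_equal(out_sw$var_g, out$var_g, tolerance = 1e-12)

  degen <- dplyr::mutate(s, sd_L = 0, sd_NL = 0)
  expect_warning(outd <- smd(degen), "zero pooled SD")
  expect_true(is.na(outd$g))
})

test_that("fixed-effect pooling reproduces the hand-computed fixture", {
  res <- pool_smd(c(0.5, 1.0), c(0.1, 0.2))
  expect_equal(res$fixed, (0.5 / 0.1 + 1.0 / 0.2) / (1 / 0.1 + 1 / 0.2),
               tolerance = 1e-12)
  expect_equal(res$fixed, 2 / 3, tolerance = 1e-12)
  expect_equal(res$fixed_se, 1 / sqrt(15), tolerance = 1e-12)
  expect_equal(res$fixed_se, 0.2582, tolerance = 1e-4)
  expect_true(res$fixed_ci_lo < res$fixed && res$fixed < res$fixed_ci_hi)
})

test_that("identical studies show no heterogeneity and random equals fixed", {
  res <- pool_smd(c(0.8, 0.8, 0.8), c(0.05, 0.05, 0.05))
  expect_equal(res$Q, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$random, res$fixed)
  expect_equal(res$random_se, res$fixed_se)

  single <- pool_smd(0.4, 0.1)
  expect_equal(single$fixed, 0.4)
  expect_equal(single$random, 0.4)
  expect_equal(single$Q, 0)
})

test_that("pooling agrees with metafor's DerSimonian-Laird implementation", {
  skip_if_not_installed("metafor")
  withr::with_seed(71, {
    for (rep in 1:5) {
      k <- sample(3:6, 1)
      g <- rnorm(k, 0.5, 0.4)
      v <- runif(k, 0.02, 0.3)
      ours <- pool_smd(g, v)
      fe <- metafor::rma(yi = g, vi = v, method = "FE")
      re <- metafor::rma(yi = g, vi = v, method = "DL")
      expect_equal(ours$fixed, unname(fe$beta[1]), tolerance = 1e-10)
      expect_equal(ours$fixed_se, fe$se, tolerance = 1e-10)
      expect_equal(ours$Q, re$QE, tolerance = 1e-10)
      expect_equal(ours$tau2, re$tau2, tolerance = 1e-10)
      expect_equal(ours$random, unname(re$beta[1]), tolerance = 1e-10)
      expect_equal(ours$random_se, re$se, tolerance = 1e-10)
    }
  })
})

test_that("pooling invariants: information gain, order invariance, continuity", {
  withr::with_seed(53, {
    g <- rnorm(4, 0.6, 0.3); v <- runif(4, 0.05, 0.4)
    res <- pool_smd(g, v)
    expect_true(res$fixed_se <= min(sqrt(v)))
    perm <- sample(4)
    expect_equal(pool_smd(g[perm], v[perm]), res, tolerance = 1e-12)
    # tau2 = 0 whenever Q <= df
    gq <- c(0.5, 0.5001, 0.4999); vq <- c(0.2, 0.2, 0.2)
    rq <- pool_smd(gq, vq)
    expect_lte(rq$Q, rq$df)
    expect_equal(rq$tau2, 0)
    expect_equal(rq$random, rq$fixed)
  })
})

test_that("meta-analysis of simulated studies pools towards the truth", {
  cat <- tiny_catalog()
  sims <- simulate_multistudy(
    designs = list(list(n_labour = 8, n_nonlabour = 8),
                   list(n_labour = 6, n_nonlabour = 6),
                   list(n_labour = 7, n_nonlabour = 6)),
    catalog = cat, shared_gene_fraction = 0.8, attenuation = c(1, 1, 1),
    seed = 12)
  studies <- lapply(sims, function(s) {
    pre <- preprocess_study(s$expression, s$metadata)
    list(expression = pre$expression, metadata = s$metadata)
  })
  mr <- meta_analyse(studies)
  expect_s3_class(mr, "meta_result")
  tab <- tidy(mr)
  expect_true(all(tab$tau2 >= 0))
  expect_true(all(tab$fixed_ci_lo <= tab$fixed & tab$fixed <= tab$fixed_ci_hi))
  # induced genes should pool to positive g, repressed to negative
  cls <- cat$class[match(tab$gene, cat$gene_id)]
  expect_gt(mean(tab$fixed[cls == "labour_induced"] > 0), 0.9)
  expect_gt(mean(tab$fixed[cls == "labour_repressed"] < 0), 0.9)
  g <- glance(mr)
  expect_identical(g$k_studies, 3L)
})

test_that("concordance percentages count directions as defined", {
  tab_a <- tibble::tibble(
    gene_symbol = paste0("g", 1:10),
    signed_fc = c(2, 1.5, -1.4, 1.3, -2, 1.1, -1.1, 3, -3, 1.6),
    call = c("up", "up", "down", "up", "down", rep("not_significant", 3),
             "down", "up"))
  # identical results: full replication, no conflicts
  self <- de_concordance(tab_a, tab_a)
  expect_equal(self$pct_sig_replicated_same_direction, 100)
  expect_equal(self$pct_same_direction_all, 100)
  expect_equal(self$pct_direction_conflict_among_sig, 0)

  # all signs flipped: nothing replicates, everything conflicts
  flipped <- dplyr::mutate(tab_a, signed_fc = -signed_fc)
  flip <- de_concordance(tab_a, flipped)
  expect_equal(flip$pct_sig_replicated_same_direction, 0)
  expect_equal(flip$pct_same_direction_all, 0)
  expect_equal(flip$pct_direction_conflict_among_sig, 100)

  # hand-constructed overlap: A significant at g1,g2,g3,g4,g5,g9,g10 (7);
  # B significant same-direction at g1,g3 (2 of 7); B same sign regardless of
  # significance at g1,g2,g3,g10 (4 of 7); among jointly significant
  # (g1,g3,g5): conflict at g5 -> 1/3.
  tab_b <- tibble::tibble(
    gene_symbol = paste0("g", 1:10),
    signed_fc = c(2, 1.5, -1.4, -1.3, 2, 1.1, -1.1, -3, 3, 1.6),
    call = c("up", "not_significant", "down", "not_significant", "up",
             rep("not_significant", 4), "not_significant"))
  res <- de_concordance(tab_a, tab_b)
  expect_equal(res$n_sig_a, 7L)
  expect_equal(res$pct_sig_replicated_same_direction, 100 * 2 / 7)
  expect_equal(res$pct_same_direction_all, 100 * 4 / 7)
  expect_equal(res$pct_direction_conflict_among_sig, 100 * 1 / 3)

  none <- dplyr::mutate(tab_a, call = "not_significant")
  expect_warning(nres <- de_concordance(none, tab_b), "no significant genes")
  expect_true(is.na(nres$pct_same_direction_all))
})
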