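test_that("catalog invariants hold and construction is deterministic", {
  cat1 <- gene_catalog(seed = 5)
  cat2 <- gene_catalog(seed = 5)
  expect_identical(cat1, cat2)
  expect_silent(validate_catalog(cat1))

  ms <- cat1[cat1$class == "muscle_specific", ]
  expect_true(all(ms$mu_muscle > 0) && all(ms$mu_leukocyte == 0))
  ls <- cat1[cat1$class == "leukocyte_specific", ]
  expect_true(all(ls$mu_leukocyte > 0) && all(ls$mu_muscle == 0))
  nc <- cat1[cat1$class == "negative_control", ]
  expect_true(all(nc$mu_muscle == 0) && all(nc$beta == 1))
  expect_true(all(cat1$beta[cat1$class == "labour_induced"] > 1))
  expect_true(all(cat1$beta[cat1$class == "labour_repressed"] < 1))
  expect_true(all(cat1$beta[!cat1$class %in%
                              c("labour_induced", "labour_repressed")] == 1))

  bad <- cat1
  bad$beta[bad$class == "housekeeping"][1] <- 2
  expect_error(validate_catalog(bad), "beta")
})

test_that("null configuration produces identical group means for every gene", {
  cat <- tiny_catalog(n_control = 20)
  study <- simulate_study(cat, n_labour = 4, n_nonlabour = 4,
                          f_labour = c(2e8, 38e8), f_nonlabour = c(2e8, 38e8),
                          noise_sd_log = 0, background_mean = 100,
                          background_sd = 0, scale_spread = 0, seed = 3)
  # all beta = 1 genes: labour and non-labour means must coincide (up to the
  # point-mass approximation of the fraction distribution)
  parts <- study$expression
  mat <- as.matrix(parts[, grep("^S", names(parts))])
  grp <- study$metadata$group
  null_genes <- study$truth$beta == 1
  ml <- rowMeans(mat[null_genes, grp == "labour"])
  mn <- rowMeans(mat[null_genes, grp == "nonlabour"])
  expect_equal(ml, mn, tolerance = 1e-4)
})

test_that("mixture formula gives the expected dilution fold change", {
  # muscle gene mu_muscle = 1000, leukocyte fraction 0.05 vs 0.30, beta = 1:
  # expected intensity ratio 0.70/0.95 and signed fold change ~ -1.357
  cat <- tibble::tibble(
    gene_id = c(sprintf("M%02d", 1:3), sprintf("N%02d", 1:10)),
    class = c(rep("muscle_specific", 3), rep("negative_control", 10)),
    mu_muscle = c(rep(1000, 3), rep(0, 10)),
    mu_leukocyte = 0, beta = 1)
  study <- simulate_study(cat, n_labour = 6, n_nonlabour = 6,
                          f_labour = c(3e8, 7e8), f_nonlabour = c(5e7, 95e7),
                          noise_sd_log = 0, background_mean = 1e-6,
                          background_sd = 0, scale_spread = 0, seed = 2)
  mat <- as.matrix(study$expression[, grep("^S", names(study$expression))])
  grp <- study$metadata$group
  ratio <- rowMeans(mat[1:3, grp == "labour"]) / rowMeans(mat[1:3, grp == "nonlabour"])
  expect_equal(unname(ratio), rep(0.70 / 0.95, 3), tolerance = 1e-4)
  fc <- signed_fold_change(rowMeans(mat[1:3, grp == "labour"]),
                           rowMeans(mat[1:3, grp == "nonlabour"]))
  expect_equal(unname(fc), rep(-0.95 / 0.70, 3), tolerance = 1e-4)
  # truth object encodes the same expectation
  expect_equal(study$truth$compositional_ratio[1], 0.70 / 0.95, tolerance = 1e-12)
  expect_equal(study$truth$expected_compositional_direction[1], "down")
})

test_that("same seed reproduces the study bit-identically", {
  cat <- tiny_catalog()
  s1 <- simulate_study(cat, n_labour = 4, n_nonlabour = 5, seed = 99)
  s2 <- simulate_study(cat, n_labour = 4, n_nonlabour = 5, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_study(cat, n_labour = 4, n_nonlabour = 5, seed = 100)
  expect_false(identical(s1$expression, s3$expression))
})

test_that("intensities are strictly positive, finite, and truth matches dims", {
  study <- simulate_study(tiny_catalog(), n_labour = 5, n_nonlabour = 5, seed = 4)
  mat <- as.matrix(study$expression[, grep("^S", names(study$expression))])
  expect_true(all(mat > 0))
  expect_true(all(is.finite(mat)))
  expect_identical(nrow(study$truth), nrow(study$expression))
  expect_identical(nrow(study$fractions), ncol(mat))
})

test_that("truth directions follow the mixture expectation under pure dilution", {
  study <- simulate_study(tiny_catalog(), n_labour = 4, n_nonlabour = 4, seed = 8)
  tr <- study$truth
  expect_true(all(tr$expected_compositional_direction[tr$class == "muscle_specific"] == "down"))
  expect_true(all(tr$expected_compositional_direction[tr$class == "leukocyte_specific"] == "up"))
  expect_true(all(tr$expected_compositional_direction[tr$class == "housekeeping"] == "none"))
  # direction equals the sign of the mixture-formula expectation exactly
  fL <- 3 / 10; fN <- 2 / 40
  cat <- gene_catalog(20, 20, 5, 5, 60, 20, seed = 1)
  num <- (1 - fL) * cat$mu_muscle + fL * cat$mu_leukocyte
  den <- (1 - fN) * cat$mu_muscle + fN * cat$mu_leukocyte
  manual <- ifelse(den > 0, ifelse(abs(num / den - 1) < 1e-12, "none",
                                   ifelse(num / den > 1, "up", "down")), NA)
  expect_identical(tr$expected_compositional_direction, manual)
})

test_that("negative-control median tracks the configured background floor", {
  cat <- gene_catalog(5, 5, 0, 0, 10, 1000, seed = 2)
  study <- simulate_study(cat, n_labour = 3, n_nonlabour = 3, seed = 6)
  ctrl <- as.matrix(study$expression[study$expression$is_control,
                                     grep("^S", names(study$expression))])
  expect_gt(median(ctrl), 0.9 * 100)
  expect_lt(median(ctrl), 1.1 * 100)
})

test_that("multistudy collections control probe overlap and attenuation", {
  cat <- tiny_catalog()
  sims <- simulate_multistudy(
    designs = list(list(n_labour = 3, n_nonlabour = 3),
                   list(n_labour = 3, n_nonlabour = 3),
                   list(n_labour = 3, n_nonlabour = 3)),
    catalog = cat, shared_gene_fraction = 1.0,
    attenuation = c(1, 1, 1), seed = 10)
  for (s in sims) expect_setequal(s$expression$probe_id, cat$gene_id)

  sims2 <- simulate_multistudy(
    designs = list(list(n_labour = 3, n_nonlabour = 3),
                   list(n_labour = 3, n_nonlabour = 3)),
    catalog = cat, shared_gene_fraction = 0.9,
    attenuation = c(1, 0), seed = 10)
  expect_true(all(sims2$study2$truth$beta == 1))

  # intersection of a larger catalog approximately hits the target fraction
  big <- gene_catalog(100, 100, 50, 25, 600, 50, seed = 3)
  sims3 <- simulate_multistudy(
    designs = list(list(n_labour = 2, n_nonlabour = 2),
                   list(n_labour = 2, n_nonlabour = 2),
                   list(n_labour = 2, n_nonlabour = 2)),
    catalog = big, shared_gene_fraction = 0.5,
    attenuation = c(1, 1, 1), seed = 11)
  shared <- Reduce(intersect, lapply(sims3, function(s) s$expression$probe_id))
  nc <- sum(big$class == "negative_control")
  g_nc <- nrow(big) - nc
  n_shared_genes <- length(setdiff(shared, big$gene_id[big$class == "negative_control"]))
  expect_lt(abs(n_shared_genes - 0.5 * g_nc), 4 * sqrt(g_nc * 0.5 * 0.5))

  expect_error(simulate_multistudy(
    designs = list(list(n_labour = 2, n_nonlabour = 2),
                   list(n_labour = 2, n_nonlabour = 2)),
    catalog = cat, attenuation = c(1, 1, 1), seed = 1),
    "one entry per study")
})

test_that("invalid generator parameters name the offending field", {
  cat <- tiny_catalog()
  expect_error(simulate_study(cat, noise_sd_log = -1, seed = 1), "noise_sd_log")
  expect_error(simulate_study(cat, background_mean = 0, seed = 1), "background_mean")
  expect_error(simulate_study(cat, n_labour = 1, seed = 1), "group sizes")
  expect_error(simulate_study(cat, induced_fraction = 2, seed = 1), "induced_fraction")
})
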