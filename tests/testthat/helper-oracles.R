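# Independent oracles and small fixture builders shared across the suite.
# Every oracle is written from the definition, independent of the package
# code paths it checks.

# --- fixtures ---------------------------------------------------------------

tiny_catalog <- function(n_muscle = 20, n_leukocyte = 20, n_induced = 5,
                         n_repressed = 5, n_housekeeping = 60,
                         n_control = 20, seed = 1) {
  gene_catalog(n_muscle, n_leukocyte, n_induced, n_repressed,
               n_housekeeping, n_control, seed = seed)
}

# Expression tibble straight from a matrix (no controls).
expr_from_matrix <- function(mat, probe_ids = NULL, is_control = NULL) {
  if (is.null(probe_ids)) probe_ids <- sprintf("P%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  ann <- tibble::tibble(probe_id = probe_ids)
  if (!is.null(is_control)) ann$is_control <- is_control
  dplyr::bind_cols(ann, tibble::as_tibble(mat))
}

meta_two_groups <- function(sample_ids, n_labour) {
  tibble::tibble(
    sample_id = sample_ids,
    group = c(rep("labour", n_labour),
              rep("nonlabour", length(sample_ids) - n_labour))
  )
}

# --- rank product -----------------------------------------------------------

# Explicit per-pair ranking, explicit product, K-th root.
brute_force_rank_product <- function(mat, grp, scale = "raw") {
  li <- which(grp == "labour"); nj <- which(grp == "nonlabour")
  pairs <- expand.grid(i = li, j = nj)
  G <- nrow(mat)
  prod_up <- rep(1, G); prod_down <- rep(1, G)
  for (k in seq_len(nrow(pairs))) {
    ratio <- if (scale == "raw") mat[, pairs$i[k]] / mat[, pairs$j[k]]
             else log2(mat[, pairs$i[k]]) - log2(mat[, pairs$j[k]])
    ord_up <- rank(-ratio, ties.method = "average")
    ord_down <- rank(ratio, ties.method = "average")
    prod_up <- prod_up * ord_up
    prod_down <- prod_down * ord_down
  }
  list(rp_up = prod_up^(1 / nrow(pairs)), rp_down = prod_down^(1 / nrow(pairs)))
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive PFP for G probes, 2 comparisons: enumerate every joint rank
# assignment, compute E[count of null rp <= rp_g] and its variance per
# single replicate, then pfp = E/rho with the same monotone enforcement the
# estimator applies.
exhaustive_pfp_two_comparisons <- function(rp_obs) {
  G <- length(rp_obs)
  perms <- all_perms(G)
  counts <- matrix(0, nrow(perms)^2, G)
  row <- 0
  for (a in seq_len(nrow(perms))) for (b in seq_len(nrow(perms))) {
    row <- row + 1
    rp_null <- sqrt(perms[a, ] * perms[b, ])
    counts[row, ] <- vapply(rp_obs, function(x) sum(rp_null <= x), numeric(1))
  }
  E <- colMeans(counts)
  V <- apply(counts, 2, function(x) mean((x - mean(x))^2))
  rho <- rank(rp_obs, ties.method = "average")
  pfp <- E / rho
  ord <- order(rp_obs)
  pfp[ord] <- cummax(pfp[ord])
  list(pfp = pfp, E = E, var_count = V)
}

# --- normexp ----------------------------------------------------------------

# Posterior mean E[S | O = o] for O = B + S, B ~ N(mu, sigma^2),
# S ~ Exp(mean theta), by numerical quadrature over s in (0, Inf).
normexp_posterior_mean_quadrature <- function(o, mu, sigma, theta) {
  # dense trapezoid over the full support; the posterior is a truncated
  # normal whose peak can sit far from 0, so fixed fine gridding is safer
  # than adaptive quadrature
  upper <- o - mu + 12 * sigma
  if (upper <= 0) upper <- 12 * sigma
  s <- seq(1e-9, upper, length.out = 2e5)
  w <- dnorm(o - s, mu, sigma) * exp(-s / theta)
  sum(s * w) / sum(w)
}

# --- quantile normalization -------------------------------------------------

# Plain sort/average reference construction (valid when there are no ties).
naive_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) ref[rank(x)])
  dimnames(out) <- dimnames(mat)
  out
}

# --- Fisher's exact test ----------------------------------------------------

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed that of the observed table (with the classical 1e-7
# relative tolerance for ties).
fisher_2x2_enumeration <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build a sample-mode clustering + metadata realizing a 2x2 cluster-by-trait
# table, so the association test can be exercised on arbitrary tables.
clustering_for_table <- function(a, b, c, d) {
  n <- a + b + c + d
  ids <- sprintf("S%03d", seq_len(n))
  cluster <- rep(c(1L, 1L, 2L, 2L), times = c(a, b, c, d))
  trait <- rep(c("x", "y", "x", "y"), times = c(a, b, c, d))
  clustering <- structure(
    list(assignment = tibble::tibble(node = ids, cluster = cluster,
                                     is_singleton = FALSE),
         n_clusters = 2L, converged = TRUE, iterations = 1L,
         max_colsum_dev = 0, inflation = 2, mode = "sample"),
    class = "mcl_clustering")
  md <- tibble::tibble(sample_id = ids, trait = trait)
  list(clustering = clustering, metadata = md)
}

# --- planted-partition fixture ----------------------------------------------

# Probe data with 3 blocks driven by independent latent factors: strong
# within-block correlation, none between.
planted_blocks <- function(n_blocks = 3, probes_per_block = 15,
                           n_samples = 20, noise = 0.25, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n_blocks), function(b) {
      u <- rnorm(n_samples)
      t(vapply(seq_len(probes_per_block),
               function(i) u + rnorm(n_samples, 0, noise),
               numeric(n_samples)))
    })
    mat <- do.call(rbind, mats)
    rownames(mat) <- sprintf("B%d_%02d", rep(seq_len(n_blocks), each = probes_per_block),
                             rep(seq_len(probes_per_block), n_blocks))
    colnames(mat) <- sprintf("S%02d", seq_len(n_samples))
    list(mat = mat,
         truth = rep(seq_len(n_blocks), each = probes_per_block))
  })
}

# Adjusted Rand index between two labelings (direct formula).
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  (a - expected) / (maxi - expected)
}

# --- t test -----------------------------------------------------------------

# Pooled-variance two-sample t statistic and two-sided p, textbook form.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Disjoint cliques with known membership.
clique_graph <- function(sizes, weight = 1) {
  nodes <- sprintf("n%02d", seq_len(sum(sizes)))
  groups <- rep(seq_along(sizes), sizes)
  edges <- NULL
  for (cl in seq_along(sizes)) {
    members <- nodes[groups == cl]
    if (length(members) > 1) {
      pairs <- t(combn(members, 2))
      edges <- rbind(edges, data.frame(from = pairs[, 1], to = pairs[, 2],
                                       weight = weight))
    }
  }
  list(nodes = nodes, edges = tibble::as_tibble(edges), mode = "probe",
       truth = groups)
}

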