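#' Signed fold change between group means
#'
#' Ratio of labouring to non-labouring mean intensity, reported with the
#' conventional signed-magnitude encoding: `+R` when expression is higher in
#' labour (`R = mean_L / mean_NL >= 1`), `-1/R` when lower, so the magnitude
#' is always >= 1 and the sign encodes direction.
#'
#' @param mean_L,mean_NL Positive group mean intensities (vectorized).
#' @returns Signed fold change(s).
#' @examples
#' signed_fold_change(200, 100)  # +2
#' signed_fold_change(100, 120)  # -1.2
#' @export
signed_fold_change <- function(mean_L, mean_NL) {
  if (any(mean_L <= 0) || any(mean_NL <= 0)) {
    abort("group means must be > 0 (apply the floor filter first)")
  }
  r <- mean_L / mean_NL
  ifelse(r >= 1, r, -1 / r)
}

# Build the (labour i, nonlabour j) comparison pairs, capped at max_pairs by
# seeded subsampling.
make_pairs <- function(grp, max_pairs, seed) {
  li <- which(grp == "labour")
  nj <- which(grp == "nonlabour")
  if (length(li) < 2 || length(nj) < 2) abort("need >= 2 samples per group")
  pairs <- expand.grid(i = li, j = nj)
  if (nrow(pairs) > max_pairs) {
    pairs <- withr::with_seed(seed, pairs[sample.int(nrow(pairs), max_pairs), ])
  }
  if (nrow(pairs) < 1) abort("no pairwise comparisons available")
  pairs
}

#' Rank-product statistics
#'
#' The rank product of a probe is the geometric mean, over many pairwise
#' between-group comparisons, of the rank of its expression ratio among all
#' probes: small `rp_up` means the probe is consistently near the top of the
#' up-regulated ordering (rank 1 = largest labour/non-labour ratio), and
#' `rp_down` is the analogue on the reversed ordering. All `nL x nNL` sample
#' pairs are used, capped at `max_pairs` by seeded subsampling; ratios are
#' taken on the raw normalized scale by default (differences of log2 values
#' when `scale = "log2"`, an order-equivalent choice). Ties receive average
#' ranks; geometric means are computed in log space.
#'
#' @param expr Normalized, filtered expression tibble.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param scale `"raw"` or `"log2"`.
#' @param max_pairs Cap on the number of pairwise comparisons.
#' @param seed Seed for pair subsampling.
#' @returns A tibble with `probe_id`, `rp_up`, `rp_down`, plus attribute
#'   `n_comparisons`.
#' @export
rank_product <- function(expr, metadata, scale = c("raw", "log2"),
                         max_pairs = 100, seed = 1L) {
  scale <- match.arg(scale)
  parts <- expr_parts(expr)
  mat <- parts$mat
  if (!all(mat > 0) && scale == "log2") abort("log2 scale requires positive values")
  grp <- group_vector(mat, metadata)
  core <- rp_core(mat, which(grp == "labour"), which(grp == "nonlabour"),
                  scale, max_pairs, seed)
  out <- tibble::tibble(
    probe_id = rownames(mat),
    rp_up = core$rp_up,
    rp_down = core$rp_down
  )
  attr(out, "n_comparisons") <- core$K
  out
}

# Geometric-mean rank products for an explicit labour/non-labour column split.
rp_core <- function(mat, li, nj, scale, max_pairs, seed) {
  grp <- rep("nonlabour", ncol(mat))
  grp[li] <- "labour"
  grp <- factor(grp, levels = c("labour", "nonlabour"))
  pairs <- make_pairs(grp, max_pairs, seed)
  K <- nrow(pairs)
  log_up <- numeric(nrow(mat))
  log_down <- numeric(nrow(mat))
  for (k in seq_len(K)) {
    ratio <- if (scale == "raw") {
      mat[, pairs$i[k]] / mat[, pairs$j[k]]
    } else {
      log2(mat[, pairs$i[k]]) - log2(mat[, pairs$j[k]])
    }
    log_up <- log_up + log(rank(-ratio, ties.method = "average"))
    log_down <- log_down + log(rank(ratio, ties.method = "average"))
  }
  list(rp_up = unname(exp(log_up / K)), rp_down = unname(exp(log_down / K)),
       K = K)
}

# Null rank products under sample-label permutation: reassigns group labels
# to columns B times and recomputes both directions on the real data, so the
# null carries the same between-comparison dependence (shared samples,
# per-probe variance differences) as the observed statistics.
null_rank_products_labels <- function(mat, n_labour, scale, max_pairs,
                                      n_permutations, seed) {
  n <- ncol(mat)
  withr::with_seed(seed, {
    up <- matrix(0, n_permutations, nrow(mat))
    down <- matrix(0, n_permutations, nrow(mat))
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      core <- rp_core(mat, perm[seq_len(n_labour)],
                      perm[(n_labour + 1):n], scale, max_pairs, seed + b)
      up[b, ] <- core$rp_up
      down[b, ] <- core$rp_down
    }
    list(up = up, down = down)
  })
}

# Null rank products under independent uniform rank permutations:
# a B x G matrix (each row one permutation replicate's rp values).
null_rank_products <- function(n_probes, n_comparisons, n_permutations, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(b) {
      acc <- numeric(n_probes)
      for (k in seq_len(n_comparisons)) {
        acc <- acc + log(sample.int(n_probes))
      }
      exp(acc / n_comparisons)
    }, numeric(n_probes)))
  })
}

#' Percentage-of-false-positives (PFP) estimates for rank products
#'
#' For each permutation replicate the probe labels are permuted independently
#' within each pairwise comparison (equivalently, each probe receives an
#' independent uniform random rank per comparison) and the rank products are
#' recomputed. For an observed probe with ascending rank-product rank
#' \eqn{\rho_g}, the expected number of null probes at least as extreme is
#' \eqn{E_g = c_g / B} where \eqn{c_g} counts permuted rank products
#' \eqn{\le rp_g} over all replicates and probes; then
#' \eqn{PFP_g = E_g / \rho_g} and the per-probe permutation p-value is
#' \eqn{c_g / (B G)}. PFP values are made monotone non-decreasing along the
#' ascending rank-product order so that significance sets are nested in the
#' threshold. Deterministic given the seed.
#'
#' @param rp Observed rank products (one per probe, same configuration as
#'   the null).
#' @param n_comparisons Number of pairwise comparisons K used for `rp`.
#' @param n_permutations Number of permutation replicates B (>= 10).
#' @param seed Integer seed.
#' @returns A tibble with `rp`, `pfp`, `pvalue`.
#' @export
estimate_pfp <- function(rp, n_comparisons, n_permutations = 100, seed = 1L) {
  if (n_permutations < 10) abort("n_permutations must be >= 10")
  G <- length(rp)
  null <- null_rank_products(G, n_comparisons, n_permutations, seed)
  pfp_from_null(rp, null)
}

# Shared core: compute PFP/p-values of observed rp against a null matrix.
pfp_from_null <- function(rp, null) {
  B <- nrow(null)
  G <- length(rp)
  sorted_null <- sort(as.vector(null))
  cg <- findInterval(rp, sorted_null)    # null rps <= observed
  rho <- rank(rp, ties.method = "average")
  pfp <- (cg / B) / rho
  ord <- order(rp)
  pfp[ord] <- cummax(pfp[ord])
  tibble::tibble(rp = rp, pfp = pfp, pvalue = cg / (B * G))
}

#' Rank-product differential expression analysis
#'
#' The full differential-expression stage: group means and signed fold
#' changes, rank products in both directions, permutation PFP values, and
#' the significance call. A probe is called `up` when `pfp_up <= pfp_alpha`
#' and `signed_fc >= +fc_threshold`, `down` symmetrically; if both
#' directions qualify the smaller PFP wins (then the larger magnitude; an
#' exact tie is excluded with a warning).
#'
#' Two permutation nulls are reported. The RP-PFP values (`pfp_up`,
#' `pfp_down`), which drive the calls, use the classical rank-product null
#' of [estimate_pfp()] (independent uniform rank permutations per
#' comparison). The per-probe p-values (`pvalue_up`, `pvalue_down`) instead
#' permute sample group labels and reference each probe against its own
#' permuted rank products: this null preserves the dependence between
#' comparisons that share samples and each probe's variance, so these raw
#' p-values are calibrated (uniform under a global null).
#'
#' @param expr Normalized, filtered expression tibble.
#' @param metadata Sample metadata.
#' @param fc_threshold Minimum absolute signed fold change (default 1.2).
#' @param pfp_alpha PFP significance threshold (default 0.05).
#' @param n_permutations Permutation replicates B (default 100).
#' @param max_pairs Cap on pairwise comparisons (default 100).
#' @param scale Ratio scale, `"raw"` (default) or `"log2"`.
#' @param seed Integer seed controlling pair subsampling and permutations.
#' @returns An object of class `rp_de`: a list with `table` (per-probe
#'   tibble: `probe_id`, `gene_symbol`, `mean_L`, `mean_NL`, `signed_fc`,
#'   `rp_up`, `rp_down`, `pfp_up`, `pfp_down`, `pvalue_up`, `pvalue_down`,
#'   `call`) and `config`. Use [tidy()] / [glance()] to extract results.
#' @export
rank_product_de <- function(expr, metadata, fc_threshold = 1.2,
                            pfp_alpha = 0.05, n_permutations = 100,
                            max_pairs = 100, scale = c("raw", "log2"),
                            seed = 1L) {
  scale <- match.arg(scale)
  check_positive(fc_threshold, "fc_threshold")
  check_positive(pfp_alpha, "pfp_alpha")
  parts <- expr_parts(expr)
  mat <- parts$mat
  grp <- group_vector(mat, metadata)

  mean_L <- rowMeans(mat[, grp == "labour", drop = FALSE])
  mean_NL <- rowMeans(mat[, grp == "nonlabour", drop = FALSE])
  fc <- signed_fold_change(mean_L, mean_NL)

  rp <- rank_product(expr, metadata, scale = scale, max_pairs = max_pairs,
                     seed = seed)
  K <- attr(rp, "n_comparisons")
  null <- null_rank_products(nrow(mat), K, n_permutations, seed)
  up <- pfp_from_null(rp$rp_up, null)
  down <- pfp_from_null(rp$rp_down, null)
  # calibrated per-probe p-values: each probe is referenced against its own
  # rank products under sample-label permutation, so neither the shared-sample
  # dependence nor other probes' signal distorts the null
  labs <- null_rank_products_labels(mat, sum(grp == "labour"), scale,
                                    max_pairs, n_permutations, seed)
  p_up <- colMeans(sweep(labs$up, 2, rp$rp_up, `<=`))
  p_down <- colMeans(sweep(labs$down, 2, rp$rp_down, `<=`))

  tab <- tibble::tibble(
    probe_id = rownames(mat),
    gene_symbol = if ("gene_symbol" %in% names(expr)) expr$gene_symbol else rownames(mat),
    mean_L = unname(mean_L), mean_NL = unname(mean_NL),
    signed_fc = unname(fc),
    rp_up = rp$rp_up, rp_down = rp$rp_down,
    pfp_up = up$pfp, pfp_down = down$pfp,
    pvalue_up = p_up, pvalue_down = p_down
  )

  up_ok <- tab$pfp_up <= pfp_alpha & tab$signed_fc >= fc_threshold
  down_ok <- tab$pfp_down <= pfp_alpha & tab$signed_fc <= -fc_threshold
  call <- rep("not_significant", nrow(tab))
  call[up_ok] <- "up"
  call[down_ok] <- "down"
  both <- up_ok & down_ok
  if (any(both)) {
    pick_up <- tab$pfp_up[both] < tab$pfp_down[both] |
      (tab$pfp_up[both] == tab$pfp_down[both] & tab$signed_fc[both] > 0)
    call[both] <- ifelse(pick_up, "up", "down")
    exact <- tab$pfp_up[both] == tab$pfp_down[both] & tab$signed_fc[both] == 0
    if (any(exact)) {
      warn("probes tied between up and down calls were excluded")
      call[which(both)[exact]] <- "not_significant"
    }
  }
  tab$call <- call

  structure(
    list(table = tab,
         config = list(fc_threshold = fc_threshold, pfp_alpha = pfp_alpha,
                       n_permutations = n_permutations, max_pairs = max_pairs,
                       n_comparisons = K, scale = scale, seed = seed)),
    class = "rp_de"
  )
}

#' @export
print.rp_de <- function(x, ...) {
  n <- table(factor(x$table$call, levels = c("up", "down", "not_significant")))
  cat("<rp_de> ", nrow(x$table), " probes, ", x$config$n_comparisons,
      " comparisons, B = ", x$config$n_permutations, "\n", sep = "")
  cat("  up: ", n[["up"]], "  down: ", n[["down"]],
      "  (PFP <= ", x$config$pfp_alpha, ", |FC| >= ",
      x$config$fc_threshold, ")\n", sep = "")
  invisible(x)
}

#' Select differentially expressed probes
#'
#' Applies the joint PFP and fold-change thresholds to a DE table and
#' returns the up- and down-regulated probe lists (each probe in at most one
#' list; the call column of [rank_product_de()] already resolves direction
#' ties).
#'
#' @param results An `rp_de` object or its `table` tibble.
#' @param fc_threshold,pfp_alpha Selection thresholds; default to the values
#'   stored in the `rp_de` config (or 1.2 / 0.05 for a bare table).
#' @returns A list with character vectors `up` and `down`.
#' @export
select_differential <- function(results, fc_threshold = NULL, pfp_alpha = NULL) {
  if (inherits(results, "rp_de")) {
    fc_threshold <- fc_threshold %||% results$config$fc_threshold
    pfp_alpha <- pfp_alpha %||% results$config$pfp_alpha
    tab <- results$table
  } else {
    fc_threshold <- fc_threshold %||% 1.2
    pfp_alpha <- pfp_alpha %||% 0.05
    tab <- results
  }
  up_ok <- tab$pfp_up <= pfp_alpha & tab$signed_fc >= fc_threshold
  down_ok <- tab$pfp_down <= pfp_alpha & tab$signed_fc <= -fc_threshold
  both <- up_ok & down_ok
  if (any(both)) {
    keep_up <- tab$pfp_up[both] < tab$pfp_down[both] |
      (tab$pfp_up[both] == tab$pfp_down[both] & tab$signed_fc[both] > 0)
    up_ok[both] <- keep_up
    down_ok[both] <- !keep_up
  }
  list(up = tab$probe_id[up_ok], down = tab$probe_id[down_ok])
}
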