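#' Collapse probes to genes
#'
#' Reduces a probe-level matrix to one row per gene symbol. The default rule
#' keeps the probe with the highest mean intensity across the study's
#' samples (a deterministic choice requiring no external annotation); the
#' alternative averages all probes of a gene.
#'
#' @param expr Expression tibble with a `gene_symbol` column.
#' @param rule `"max_mean"` (default) or `"mean"`.
#' @returns An expression tibble with unique `gene_symbol` (also used as
#'   `probe_id`).
#' @export
collapse_probes <- function(expr, rule = c("max_mean", "mean")) {
  rule <- match.arg(rule)
  if (!"gene_symbol" %in% names(expr)) abort("collapse requires a 'gene_symbol' column")
  parts <- expr_parts(expr)
  mat <- parts$mat
  sym <- expr$gene_symbol
  if (rule == "max_mean") {
    rm <- rowMeans(mat)
    keep <- unlist(lapply(split(seq_along(sym), sym), function(ix) ix[which.max(rm[ix])]))
    out <- expr[sort(keep), , drop = FALSE]
    out$probe_id <- out$gene_symbol
    out
  } else {
    agg <- rowsum(mat, sym) / as.vector(table(sym)[sort(unique(sym))])
    dplyr::bind_cols(
      tibble::tibble(probe_id = rownames(agg), gene_symbol = rownames(agg)),
      tibble::as_tibble(agg)
    )
  }
}

#' Restrict studies to their common gene set
#'
#' Collapses each study's probes to genes and intersects the gene-symbol
#' sets; every returned matrix is indexed identically by gene symbol.
#'
#' @param studies Named list of expression tibbles (each with
#'   `gene_symbol`).
#' @param rule Probe collapsing rule, see [collapse_probes()].
#' @returns A named list of expression tibbles over the common genes, in a
#'   common gene order.
#' @export
harmonize_genes <- function(studies, rule = "max_mean") {
  if (length(studies) < 2) abort("need >= 2 studies")
  collapsed <- purrr::map(studies, collapse_probes, rule = rule)
  sets <- purrr::map(collapsed, "gene_symbol")
  common <- Reduce(intersect, sets)
  if (length(common) == 0) {
    smallest <- names(which.min(lengths(sets))) %||% which.min(lengths(sets))
    abort(paste0("no genes shared across studies (smallest contributor: ",
                 smallest, ")"))
  }
  common <- sort(common)
  purrr::map(collapsed, function(x) x[match(common, x$gene_symbol), , drop = FALSE])
}

#' Per-gene group summaries of a study on the log2 scale
#'
#' Log2-transforms the (positive) expression values and returns, for each
#' gene, group means, SDs and sizes — the sufficient statistics for a
#' standardized mean difference.
#'
#' @param expr Expression tibble (typically collapsed to genes).
#' @param metadata Sample metadata.
#' @returns A tibble: `gene`, `mean_L`, `mean_NL`, `sd_L`, `sd_NL`, `n_L`,
#'   `n_NL`.
#' @export
study_summary <- function(expr, metadata) {
  parts <- expr_parts(expr)
  if (any(parts$mat <= 0)) abort("log2 summaries require positive intensities")
  lmat <- log2(parts$mat)
  grp <- group_vector(lmat, metadata)
  L <- lmat[, grp == "labour", drop = FALSE]
  NL <- lmat[, grp == "nonlabour", drop = FALSE]
  if (ncol(L) < 2 || ncol(NL) < 2) abort("need >= 2 samples per group")
  tibble::tibble(
    gene = if ("gene_symbol" %in% names(expr)) expr$gene_symbol else expr$probe_id,
    mean_L = rowMeans(L), mean_NL = rowMeans(NL),
    sd_L = apply(L, 1, sd), sd_NL = apply(NL, 1, sd),
    n_L = ncol(L), n_NL = ncol(NL)
  )
}

#' Hedges-corrected standardized mean difference
#'
#' Cohen's d with the pooled SD, the small-sample correction factor
#' `J = 1 - 3 / (4(n_L + n_NL - 2) - 1)`, Hedges' `g = J d`, and its
#' large-sample sampling variance
#' `var_g = (n_L + n_NL) / (n_L n_NL) + g^2 / (2 (n_L + n_NL))`.
#'
#' @param summary A [study_summary()] tibble (or any tibble with `mean_L`,
#'   `mean_NL`, `sd_L`, `sd_NL`, `n_L`, `n_NL`).
#' @returns The input with columns `d`, `g`, `var_g` appended; genes with a
#'   zero pooled SD get NA with a warning.
#' @export
smd <- function(summary) {
  need <- c("mean_L", "mean_NL", "sd_L", "sd_NL", "n_L", "n_NL")
  miss <- setdiff(need, names(summary))
  if (length(miss)) abort(paste0("summary lacks columns: ", paste(miss, collapse = ", ")))
  with(summary, {
    if (any(n_L < 2) || any(n_NL < 2)) abort("group sizes must be >= 2")
    df <- n_L + n_NL - 2
    sp <- sqrt(((n_L - 1) * sd_L^2 + (n_NL - 1) * sd_NL^2) / df)
    if (any(sp == 0)) warn("degenerate genes with zero pooled SD set to NA")
    d <- ifelse(sp > 0, (mean_L - mean_NL) / sp, NA_real_)
    J <- 1 - 3 / (4 * df - 1)
    g <- J * d
    var_g <- (n_L + n_NL) / (n_L * n_NL) + g^2 / (2 * (n_L + n_NL))
    dplyr::bind_cols(summary, tibble::tibble(d = d, g = g, var_g = var_g))
  })
}

#' Inverse-variance pooling of study effects
#'
#' Fixed-effect pooling weights each study by `1/var`; heterogeneity is
#' summarized by Cochran's Q (chi-squared with k-1 df) and the
#' DerSimonian–Laird between-study variance
#' `tau2 = max(0, (Q - df) / C)`, `C = sum(w) - sum(w^2)/sum(w)`. The
#' random-effects estimate reweights by `1/(var + tau2)`. 95% CIs use
#' `estimate +/- 1.96 SE`. With one study both estimates equal that study
#' and Q = tau2 = 0.
#'
#' @param g Study effect estimates (Hedges g).
#' @param var_g Their sampling variances (> 0).
#' @returns A one-row tibble: `k`, fixed estimate/SE/CI, `Q`, `df`, `p_Q`,
#'   `tau2`, random estimate/SE/CI.
#' @examples
#' pool_smd(c(0.5, 1.0), c(0.1, 0.2))
#' @export
pool_smd <- function(g, var_g) {
  ok <- is.finite(g) & is.finite(var_g)
  g <- g[ok]; var_g <- var_g[ok]
  k <- length(g)
  if (k == 0) abort("no studies to pool")
  if (any(var_g <= 0)) abort("variances must be > 0")
  w <- 1 / var_g
  est_f <- sum(w * g) / sum(w)
  se_f <- sqrt(1 / sum(w))
  if (k == 1) {
    Q <- 0; df <- 0; p_Q <- NA_real_; tau2 <- 0
    est_r <- est_f; se_r <- se_f
  } else {
    Q <- sum(w * (g - est_f)^2)
    df <- k - 1
    p_Q <- pchisq(Q, df, lower.tail = FALSE)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    wr <- 1 / (var_g + tau2)
    est_r <- sum(wr * g) / sum(wr)
    se_r <- sqrt(1 / sum(wr))
  }
  z <- qnorm(0.975)
  tibble::tibble(
    k = k,
    fixed = est_f, fixed_se = se_f,
    fixed_ci_lo = est_f - z * se_f, fixed_ci_hi = est_f + z * se_f,
    Q = Q, df = df, p_Q = p_Q, tau2 = tau2,
    random = est_r, random_se = se_r,
    random_ci_lo = est_r - z * se_r, random_ci_hi = est_r + z * se_r
  )
}

#' Cross-study standardized-mean-difference meta-analysis
#'
#' Harmonizes the studies to their common gene set, computes per-study
#' Hedges g on log2 intensities, and pools each gene by fixed- and
#' random-effects inverse-variance weighting with heterogeneity statistics.
#' Both pooled models are always reported.
#'
#' @param studies Named list of studies; each element is a list with
#'   `expression` and `metadata` (a `synthetic_study` works directly).
#' @param genes Optional gene subset to analyse after harmonization.
#' @param rule Probe collapsing rule.
#' @returns An object of class `meta_result`: list with `table` (per-gene
#'   pooled results), `smd` (long per-study effect tibble: `study`, `gene`,
#'   `g`, `var_g`), and `genes` (the common gene set).
#' @export
meta_analyse <- function(studies, genes = NULL, rule = "max_mean") {
  if (is.null(names(studies))) names(studies) <- paste0("study", seq_along(studies))
  exprs <- purrr::map(studies, "expression")
  metas <- purrr::map(studies, "metadata")
  harm <- harmonize_genes(exprs, rule = rule)
  if (!is.null(genes)) {
    harm <- purrr::map(harm, function(x) {
      found <- x$gene_symbol %in% genes
      if (!any(found)) abort("none of the requested genes are in the common set")
      x[found, , drop = FALSE]
    })
  }
  long <- purrr::map2_dfr(harm, metas, function(e, m) smd(study_summary(e, m)),
                          .id = "study")
  long <- dplyr::select(long, "study", "gene", "g", "var_g")
  # genes degenerate (zero pooled SD) in every study cannot be pooled
  poolable <- long |>
    dplyr::filter(is.finite(.data$g)) |>
    dplyr::pull("gene") |>
    unique()
  tab <- long |>
    dplyr::filter(.data$gene %in% poolable) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ pool_smd(.x$g, .x$var_g)) |>
    dplyr::ungroup()
  structure(list(table = tab, smd = long,
                 genes = sort(unique(long$gene))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("<meta_result> ", nrow(x$table), " genes pooled over ",
      length(unique(x$smd$study)), " studies\n", sep = "")
  invisible(x)
}

#' Cross-study concordance of differential-expression calls
#'
#' Compares two DE result sets over their shared gene set and reports, from
#' the perspective of study A:
#' * `pct_sig_replicated_same_direction`: % of A's significant genes also
#'   significant in B with the same fold-change sign;
#' * `pct_same_direction_all`: % of A's significant genes whose sign matches
#'   in B regardless of B's significance;
#' * `pct_direction_conflict_among_sig`: % of genes significant in *both*
#'   studies with opposite signs.
#'
#' @param results_a,results_b `rp_de` objects or their `table` tibbles (with
#'   `gene_symbol`, `signed_fc`, `call`).
#' @param shared Optional gene set; defaults to the genes present in both.
#' @returns A one-row tibble with the three percentages and gene counts;
#'   percentages are NA with a warning when A has no significant genes.
#' @export
de_concordance <- function(results_a, results_b, shared = NULL) {
  tab_a <- if (inherits(results_a, "rp_de")) results_a$table else results_a
  tab_b <- if (inherits(results_b, "rp_de")) results_b$table else results_b
  shared <- shared %||% intersect(tab_a$gene_symbol, tab_b$gene_symbol)
  a <- tab_a[match(shared, tab_a$gene_symbol), ]
  b <- tab_b[match(shared, tab_b$gene_symbol), ]
  sig_a <- a$call != "not_significant"
  sig_b <- b$call != "not_significant"
  same_sign <- sign(a$signed_fc) == sign(b$signed_fc)
  n_sig_a <- sum(sig_a)
  n_sig_both <- sum(sig_a & sig_b)
  if (n_sig_a == 0) {
    warn("study A has no significant genes on the shared set; percentages undefined")
    return(tibble::tibble(
      n_shared_genes = length(shared), n_sig_a = 0L, n_sig_both = n_sig_both,
      pct_sig_replicated_same_direction = NA_real_,
      pct_same_direction_all = NA_real_,
      pct_direction_conflict_among_sig = NA_real_
    ))
  }
  tibble::tibble(
    n_shared_genes = length(shared),
    n_sig_a = n_sig_a,
    n_sig_both = n_sig_both,
    pct_sig_replicated_same_direction = 100 * sum(sig_a & sig_b & same_sign) / n_sig_a,
    pct_same_direction_all = 100 * sum(sig_a & same_sign) / n_sig_a,
    pct_direction_conflict_among_sig =
      if (n_sig_both > 0) 100 * sum(sig_a & sig_b & !same_sign) / n_sig_both else 0
  )
}
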