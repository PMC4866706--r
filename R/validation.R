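#' Subgroup sensitivity analysis of fold changes
#'
#' Recomputes signed fold changes after excluding a subgroup of samples
#' (e.g. women whose labour was pharmacologically induced or augmented) from
#' the *same* preprocessed matrix, and summarizes the agreement with the
#' full-cohort fold changes: the median absolute difference, the
#' interquartile range of the signed differences (which spans zero when the
#' exclusion is a null perturbation), the Pearson correlation of the two
#' fold-change vectors, and the percentage of probes keeping their sign.
#' All difference statistics are computed on the signed-fold-change scale.
#'
#' @param expr Preprocessed expression tibble.
#' @param metadata Sample metadata.
#' @param exclude Either the name of a metadata column (logical columns drop
#'   `TRUE` samples; character/factor columns drop samples whose value is
#'   not `"none"`) or a vector of sample ids to drop.
#' @returns A one-row tibble of class `sensitivity_report`: `n_probes`,
#'   `n_excluded`, `median_abs_diff`, `iqr_lo`, `iqr_hi`, `pearson_r`,
#'   `pct_same_direction`; per-probe details in `attr(, "probes")`.
#' @export
subgroup_sensitivity <- function(expr, metadata, exclude = "induction") {
  parts <- expr_parts(expr)
  mat <- parts$mat
  grp <- group_vector(mat, metadata)

  drop_ids <- if (length(exclude) == 1 && exclude %in% names(metadata)) {
    col <- metadata[[exclude]]
    if (is.logical(col)) metadata$sample_id[col] else metadata$sample_id[col != "none"]
  } else {
    as.character(exclude)
  }
  keep <- !(colnames(mat) %in% drop_ids)
  grp_red <- grp[keep]
  if (sum(grp_red == "labour") < 2 || sum(grp_red == "nonlabour") < 2) {
    abort("exclusion leaves fewer than 2 samples in a group")
  }

  fc_full <- signed_fold_change(
    rowMeans(mat[, grp == "labour", drop = FALSE]),
    rowMeans(mat[, grp == "nonlabour", drop = FALSE]))
  sub <- mat[, keep, drop = FALSE]
  fc_red <- signed_fold_change(
    rowMeans(sub[, grp_red == "labour", drop = FALSE]),
    rowMeans(sub[, grp_red == "nonlabour", drop = FALSE]))

  diff <- fc_red - fc_full
  iqr <- unname(quantile(diff, c(0.25, 0.75)))
  out <- tibble::tibble(
    n_probes = nrow(mat),
    n_excluded = sum(!keep),
    median_abs_diff = median(abs(diff)),
    iqr_lo = iqr[1], iqr_hi = iqr[2],
    pearson_r = if (sd(diff) == 0) 1 else cor(fc_full, fc_red),
    pct_same_direction = 100 * mean(sign(fc_full) == sign(fc_red))
  )
  attr(out, "probes") <- tibble::tibble(
    probe_id = rownames(mat), fc_full = fc_full, fc_reduced = fc_red,
    diff = diff)
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Two-group comparison of qRT-PCR delta-CT values
#'
#' For each target gene, computes per-sample delta-CT (raw CT of the target
#' minus raw CT of the reference gene) and compares groups with a two-sided
#' pooled-variance Student's t-test (Welch available via `var_equal =
#' FALSE`). Because CT is inversely related to abundance, a *lower* mean
#' delta-CT in labour is called "higher expression in labour". Group means
#' of the raw reference CT are reported so the reference-gene stability
#' contract can be checked.
#'
#' @param ct Long tibble of raw CT values: `sample_id`, `gene`, `ct`.
#' @param metadata Sample metadata.
#' @param reference Name of the reference gene (e.g. the 18S rRNA assay).
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @returns A tibble with one row per target gene: group delta-CT means,
#'   `t_stat`, `p_value`, `direction_call`, and reference-CT group means.
#' @export
delta_ct_compare <- function(ct, metadata, reference, var_equal = TRUE) {
  need <- c("sample_id", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) abort(paste0("ct table lacks columns: ", paste(miss, collapse = ", ")))
  ref <- ct[ct$gene == reference, ]
  if (nrow(ref) == 0) abort(paste0("reference gene '", reference, "' not in ct table"))

  if (anyNA(ct$ct)) {
    warn("samples with missing CT dropped per gene")
    ct <- ct[!is.na(ct$ct), ]
    ref <- ref[!is.na(ref$ct), ]
  }
  grp_of <- setNames(metadata$group, metadata$sample_id)
  ref_ct <- setNames(ref$ct, ref$sample_id)
  ref_means <- tapply(ref$ct, grp_of[ref$sample_id], mean)

  targets <- setdiff(unique(ct$gene), reference)
  purrr::map_dfr(targets, function(gn) {
    sub <- ct[ct$gene == gn, ]
    sub <- sub[sub$sample_id %in% names(ref_ct), ]
    dct <- sub$ct - ref_ct[sub$sample_id]
    grp <- grp_of[sub$sample_id]
    if (sum(grp == "labour") < 2 || sum(grp == "nonlabour") < 2) {
      abort(paste0("fewer than 2 usable samples per group for ", gn))
    }
    ht <- t.test(dct[grp == "labour"], dct[grp == "nonlabour"],
                 var.equal = var_equal)
    m_L <- mean(dct[grp == "labour"]); m_NL <- mean(dct[grp == "nonlabour"])
    tibble::tibble(
      gene = gn, mean_dct_L = m_L, mean_dct_NL = m_NL,
      t_stat = unname(ht$statistic), p_value = ht$p.value,
      direction_call = if (m_L < m_NL) "higher expression in labour"
                       else if (m_L > m_NL) "lower expression in labour"
                       else "no difference",
      ref_ct_L = unname(ref_means["labour"]),
      ref_ct_NL = unname(ref_means["nonlabour"])
    )
  })
}

#' Cross-platform concordance of log2 expression ratios
#'
#' Correlates per-gene log2 group-ratio estimates from two platforms (e.g.
#' microarray vs qRT-PCR) over their shared genes and tabulates per-gene
#' direction agreement.
#'
#' @param ratios_a,ratios_b Tibbles with `gene` and `log2_ratio` (or named
#'   numeric vectors).
#' @returns A list with `pearson_r`, `n_genes`, `pct_same_direction`, and a
#'   per-gene `agreement` tibble.
#' @export
crossplatform_concordance <- function(ratios_a, ratios_b) {
  as_tbl <- function(x) {
    if (is.data.frame(x)) x else tibble::tibble(gene = names(x), log2_ratio = unname(x))
  }
  a <- as_tbl(ratios_a); b <- as_tbl(ratios_b)
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3) abort("need >= 3 shared genes")
  va <- a$log2_ratio[match(shared, a$gene)]
  vb <- b$log2_ratio[match(shared, b$gene)]
  agreement <- tibble::tibble(
    gene = shared, log2_ratio_a = va, log2_ratio_b = vb,
    same_direction = sign(va) == sign(vb))
  list(pearson_r = cor(va, vb), n_genes = length(shared),
       pct_same_direction = 100 * mean(agreement$same_direction),
       agreement = agreement)
}
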