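# Internal helpers shared across modules.

# Columns of an expression tibble that are probe annotation, not samples.
.reserved_cols <- c("probe_id", "gene_symbol", "class", "is_control")

#' Split an expression tibble into annotation and an intensity matrix
#'
#' Expression data travel through the package as a tibble with a `probe_id`
#' column, optional annotation columns (`gene_symbol`, `class`, `is_control`)
#' and one numeric column per sample. This helper separates the two parts.
#'
#' @param expr Expression tibble.
#' @returns A list with `info` (annotation tibble) and `mat` (numeric matrix,
#'   probes in rows, rownames = probe ids).
#' @keywords internal
#' @noRd
expr_parts <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"probe_id" %in% names(expr)) {
    abort("expression table must have a 'probe_id' column")
  }
  if (anyDuplicated(expr$probe_id)) {
    abort("duplicate probe ids in expression table")
  }
  info_cols <- intersect(.reserved_cols, names(expr))
  sample_cols <- setdiff(names(expr), info_cols)
  bad <- sample_cols[!vapply(expr[sample_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric sample columns: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(sample_cols)) abort("duplicate sample ids")
  mat <- as.matrix(expr[sample_cols])
  rownames(mat) <- expr$probe_id
  if (!all(is.finite(mat))) abort("expression values must be finite")
  list(info = expr[info_cols], mat = mat)
}

# Rebuild an expression tibble from annotation + matrix.
expr_rebuild <- function(info, mat) {
  dplyr::bind_cols(info, tibble::as_tibble(mat))
}

# Logical control-probe flag, defaulting to all-FALSE when absent.
control_flag <- function(expr) {
  if ("is_control" %in% names(expr)) {
    flag <- expr$is_control
    if (!is.logical(flag)) abort("'is_control' must be logical")
    flag & !is.na(flag)
  } else {
    rep(FALSE, nrow(expr))
  }
}

# Match sample metadata to the columns of an expression matrix and return the
# binary group factor (labour / nonlabour) in column order.
group_vector <- function(mat, metadata) {
  stopifnot(is.data.frame(metadata))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) abort(paste0("metadata lacks columns: ", paste(miss, collapse = ", ")))
  idx <- match(colnames(mat), metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing from metadata: ",
                 paste(colnames(mat)[is.na(idx)], collapse = ", ")))
  }
  grp <- as.character(metadata$group[idx])
  bad <- setdiff(unique(grp), c("labour", "nonlabour"))
  if (length(bad)) abort(paste0("group labels must be labour/nonlabour, got: ",
                                paste(bad, collapse = ", ")))
  factor(grp, levels = c("labour", "nonlabour"))
}

# Round half away from zero (deterministic across platforms, unlike round()).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Check that a scalar parameter is finite and positive (or non-negative).
check_positive <- function(value, field, allow_zero = FALSE) {
  ok <- length(value) >= 1 && all(is.finite(value)) &&
    if (allow_zero) all(value >= 0) else all(value > 0)
  if (!ok) {
    abort(paste0("invalid value for '", field, "': must be finite and ",
                 if (allow_zero) ">= 0" else "> 0"))
  }
  invisible(value)
}
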