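# TSV reading/writing for the pipeline's file dialect: expression matrices
# (first column probe_id, remaining columns sample ids), a companion
# single-column control-probe list, sample metadata, and ground-truth tables.

#' Write / read an expression matrix as TSV
#'
#' The on-disk dialect has `probe_id` as the first column and one column per
#' sample; negative-control probe ids go to a companion single-column TSV.
#' Other annotation columns (`gene_symbol`, `class`) are written alongside
#' `probe_id` when present and recovered on read.
#'
#' @param expr Expression tibble.
#' @param path Matrix TSV path.
#' @param controls_path Optional companion TSV of control probe ids.
#' @returns `write_expression_tsv()`: `path`, invisibly.
#'   `read_expression_tsv()`: the expression tibble (with `is_control` when
#'   a controls file is given).
#' @export
write_expression_tsv <- function(expr, path, controls_path = NULL) {
  out <- expr
  if (!is.null(controls_path) && "is_control" %in% names(expr)) {
    readr::write_tsv(tibble::tibble(probe_id = expr$probe_id[control_flag(expr)]),
                     controls_path)
  }
  out$is_control <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, controls_path = NULL) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(controls_path)) {
    ctrl <- readr::read_tsv(controls_path, show_col_types = FALSE)
    flag <- expr$probe_id %in% ctrl$probe_id
    ann <- intersect(.reserved_cols, names(expr))
    expr <- dplyr::bind_cols(expr[ann], tibble::tibble(is_control = flag),
                             expr[setdiff(names(expr), ann)])
  }
  expr
}

#' Write / read sample metadata as TSV
#'
#' @param metadata Metadata tibble (`sample_id`, `group`, covariates).
#' @param path TSV path.
#' @returns The path (write) or the metadata tibble (read).
#' @export
write_metadata_tsv <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a synthetic study to a directory
#'
#' Writes the raw expression matrix, control-probe list, sample metadata,
#' per-gene truth and per-sample leukocyte fractions as TSV files.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @returns The directory, invisibly.
#' @export
write_study_tsv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(study$expression, file.path(dir, "expression.tsv"),
                       file.path(dir, "control_probes.tsv"))
  write_metadata_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(study$fractions, file.path(dir, "leukocyte_fractions.tsv"))
  invisible(dir)
}
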