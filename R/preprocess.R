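#' Estimate normexp background parameters from negative-control probes
#'
#' Under the normal + exponential convolution model an observed intensity is
#' `O = B + S` with background `B ~ N(mu, sigma^2)` and signal
#' `S ~ Exp(mean = theta)`. Negative-control probes measure `B` alone, so for
#' each sample `mu` and `sigma` are their mean and SD, and `theta` is the
#' mean excess of regular probes over `mu` (floored at a small positive
#' constant).
#'
#' @param expr Raw expression tibble with an `is_control` column.
#' @param samples Sample ids to estimate for (default: all).
#' @returns A tibble with columns `sample_id`, `mu`, `sigma`, `theta`.
#' @export
estimate_normexp_params <- function(expr, samples = NULL) {
  eps <- 1e-6
  parts <- expr_parts(expr)
  ctrl <- control_flag(expr)
  if (sum(ctrl) < 10) abort("need >= 10 negative-control probes to estimate background")
  samples <- samples %||% colnames(parts$mat)
  purrr::map_dfr(samples, function(s) {
    x <- parts$mat[, s]
    mu <- mean(x[ctrl])
    sigma <- sd(x[ctrl])
    if (!is.finite(sigma) || sigma < eps) {
      warn(paste0("zero variance among control probes in ", s,
                  "; sigma floored"))
      sigma <- eps
    }
    theta <- max(mean(x[!ctrl]) - mu, eps)
    tibble::tibble(sample_id = s, mu = mu, sigma = sigma, theta = theta)
  })
}

#' Normexp background correction
#'
#' Replaces each observed intensity by the posterior mean of the true signal
#' under the normal + exponential convolution model (the background model
#' underlying RMA), `E[S | O = o]` with `S` a priori exponential and the
#' background normal. The closed form is the mean of a normal truncated to
#' the positive half-line:
#' \deqn{E[S|O=o] = a + \sigma\,\phi(a/\sigma)/\Phi(a/\sigma),\quad
#'   a = o - \mu - \sigma^2/\theta.}
#' Computation is delegated to `limma::normexp.signal()`, which evaluates
#' this form in log space to avoid cancellation; the result is strictly
#' positive and monotone increasing in `o`.
#'
#' @param expr Raw expression tibble.
#' @param params Per-sample parameter tibble from
#'   [estimate_normexp_params()]; estimated from `expr` when `NULL`.
#' @returns The expression tibble with corrected intensities.
#' @export
normexp_correct <- function(expr, params = NULL) {
  parts <- expr_parts(expr)
  params <- params %||% estimate_normexp_params(expr)
  miss <- setdiff(colnames(parts$mat), params$sample_id)
  if (length(miss)) {
    abort(paste0("no normexp params for samples: ", paste(miss, collapse = ", ")))
  }
  mat <- parts$mat
  for (s in colnames(mat)) {
    p <- params[params$sample_id == s, ]
    mat[, s] <- limma::normexp.signal(
      par = c(p$mu, log(p$sigma), log(p$theta)), x = mat[, s])
  }
  mat <- pmax(mat, 1e-6)
  expr_rebuild(parts$info, mat)
}

#' Quantile normalization
#'
#' Forces every sample onto a common intensity distribution: the value at
#' rank `r` becomes the across-sample mean of each sample's rank-`r` value.
#' Tied values within a sample receive the mean of the reference values over
#' their tied rank span, which makes the operation idempotent. Probe and
#' sample order are preserved and the grand mean of the matrix is conserved.
#'
#' @param expr Expression tibble (>= 2 samples, no missing values).
#' @returns The normalized expression tibble. A single-sample matrix is
#'   returned unchanged with a warning.
#' @examples
#' m <- tibble::tibble(probe_id = c("a", "b"), s1 = c(1, 2), s2 = c(3, 4))
#' quantile_normalize(m)   # both columns become (2, 3)
#' @export
quantile_normalize <- function(expr) {
  parts <- expr_parts(expr)
  mat <- parts$mat
  if (ncol(mat) < 2) {
    warn("single-sample matrix: quantile normalization is a no-op")
    return(expr)
  }
  ref <- rowMeans(apply(mat, 2, sort))
  csum <- c(0, cumsum(ref))
  out <- apply(mat, 2, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(mat)
  expr_rebuild(parts$info, out)
}

#' Detection floor from negative-control probes
#'
#' The floor below which a probe is considered unexpressed: the median of all
#' negative-control intensities across all samples, rounded to the nearest
#' integer (half away from zero). On Illumina-style data with background near
#' 100 this reproduces the conventional floor of 100.
#'
#' @param expr Raw expression tibble with at least one control probe.
#' @returns A single numeric floor value.
#' @export
compute_detection_floor <- function(expr) {
  parts <- expr_parts(expr)
  ctrl <- control_flag(expr)
  if (!any(ctrl)) {
    abort("no negative-control probes: supply an explicit floor instead")
  }
  round_half_away(median(parts$mat[ctrl, , drop = FALSE]))
}

#' Remove probes unexpressed in both groups
#'
#' A probe is retained iff its mean intensity reaches the floor in *either*
#' the labouring or the non-labouring group; probes below the floor in both
#' groups are deemed unexpressed and removed. Negative-control probes are
#' always removed from the analysis matrix.
#'
#' @param expr Expression tibble.
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param floor Intensity floor, e.g. from [compute_detection_floor()].
#' @returns The filtered expression tibble, with attributes `floor`,
#'   `n_removed_low` (probes below floor in both groups) and
#'   `n_removed_control`.
#' @export
floor_filter <- function(expr, metadata, floor) {
  check_positive(floor, "floor", allow_zero = TRUE)
  parts <- expr_parts(expr)
  ctrl <- control_flag(expr)
  grp <- group_vector(parts$mat, metadata)
  m_lab <- rowMeans(parts$mat[, grp == "labour", drop = FALSE])
  m_non <- rowMeans(parts$mat[, grp == "nonlabour", drop = FALSE])
  keep <- (m_lab >= floor | m_non >= floor) & !ctrl
  if (!any(keep)) abort("floor filter removed every probe")
  out <- expr[keep, , drop = FALSE]
  attr(out, "floor") <- floor
  attr(out, "n_removed_low") <- sum(!keep & !ctrl)
  attr(out, "n_removed_control") <- sum(ctrl)
  out
}

#' Full preprocessing chain
#'
#' Runs the complete preprocessing stage on a raw intensity matrix:
#' normexp background correction (parameters from negative controls),
#' quantile normalization, then detection-floor filtering. The floor is
#' computed from the *raw* negative-control intensities (their median is the
#' scale on which the conventional floor is defined; after background
#' correction control intensities shrink towards zero) and applied to the
#' corrected, normalized matrix. Deterministic: no randomness anywhere in
#' the chain.
#'
#' @param expr Raw expression tibble.
#' @param metadata Sample metadata.
#' @param floor Optional explicit floor; computed from controls when `NULL`.
#' @returns A list with `expression` (filtered normalized tibble), `floor`,
#'   `normexp_params`, and `counts` (probe bookkeeping).
#' @export
preprocess_study <- function(expr, metadata, floor = NULL) {
  params <- estimate_normexp_params(expr)
  floor <- floor %||% compute_detection_floor(expr)
  norm <- quantile_normalize(normexp_correct(expr, params))
  filtered <- floor_filter(norm, metadata, floor)
  list(
    expression = filtered,
    floor = floor,
    normexp_params = params,
    counts = list(
      n_probes = nrow(expr),
      n_control = sum(control_flag(expr)),
      n_removed_low = attr(filtered, "n_removed_low"),
      n_retained = nrow(filtered)
    )
  )
}
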