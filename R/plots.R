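# ggplot2 autoplot methods for the package's result objects.

#' Volcano-style plot of a rank-product DE fit
#'
#' Signed fold change (log2 magnitude, signed) against the
#' -log10 of the better-direction PFP value, coloured by call.
#'
#' @param object An `rp_de` object.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot rp_de
#' @export
autoplot.rp_de <- function(object, ...) {
  tab <- object$table |>
    dplyr::mutate(
      log2_fc = sign(.data$signed_fc) * log2(abs(.data$signed_fc)),
      pfp = pmin(.data$pfp_up, .data$pfp_down)
    )
  floor_p <- min(tab$pfp[tab$pfp > 0], 1) / 2
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2_fc,
                                    -log10(pmax(.data$pfp, floor_p)),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$config$fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(object$config$pfp_alpha),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            not_significant = "grey60")) +
    ggplot2::labs(x = "signed fold change (log2 scale)",
                  y = expression(-log[10] ~ "RP-PFP"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean expression profiles of probe clusters
#'
#' One panel per cluster: per-sample mean expression of member probes with
#' standard-error bars, samples ordered as in the data.
#'
#' @param object A `cluster_profiles` tibble.
#' @param clusters Optional subset of cluster ids to draw.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot cluster_profiles
#' @export
autoplot.cluster_profiles <- function(object, clusters = NULL, ...) {
  dat <- if (is.null(clusters)) object else object[object$cluster %in% clusters, ]
  dat$sample_id <- factor(dat$sample_id, levels = unique(dat$sample_id))
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample_id, .data$mean, group = 1)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::facet_wrap(~cluster, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "mean expression of member probes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
}

#' Forest plot of a meta-analysis result
#'
#' Per-study Hedges g with 95% intervals and the pooled fixed- and
#' random-effects estimates for each gene.
#'
#' @param object A `meta_result` object.
#' @param genes Optional subset of genes to draw.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, genes = NULL, ...) {
  smd <- object$smd
  tab <- object$table
  if (!is.null(genes)) {
    smd <- smd[smd$gene %in% genes, ]
    tab <- tab[tab$gene %in% genes, ]
  }
  z <- qnorm(0.975)
  rows <- dplyr::bind_rows(
    smd |> dplyr::transmute(.data$gene, label = .data$study, g = .data$g,
                            lo = .data$g - z * sqrt(.data$var_g),
                            hi = .data$g + z * sqrt(.data$var_g),
                            pooled = FALSE),
    tab |> dplyr::transmute(.data$gene, label = "pooled (fixed)",
                            g = .data$fixed, lo = .data$fixed_ci_lo,
                            hi = .data$fixed_ci_hi, pooled = TRUE),
    tab |> dplyr::transmute(.data$gene, label = "pooled (random)",
                            g = .data$random, lo = .data$random_ci_lo,
                            hi = .data$random_ci_hi, pooled = TRUE)
  )
  ggplot2::ggplot(rows, ggplot2::aes(.data$g, .data$label,
                                     colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             size = 0.3) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#c0392b"),
                                 guide = "none") +
    ggplot2::labs(x = "standardised mean difference (Hedges g, labour - non-labour)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
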