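#' Simulate a two-group bead-array myometrium study
#'
#' Generates raw probe intensities for a labouring vs non-labouring study
#' under an explicit tissue-composition model. Each sample `s` carries a
#' leukocyte fraction `f_s` drawn from a Beta distribution whose parameters
#' differ by labour status (infiltration raises the expected fraction at
#' labour). The expected signal of gene `g` in sample `s` is
#'
#' \deqn{t_{gs} = [(1 - f_s)\,\mu^{muscle}_g + f_s\,\mu^{leukocyte}_g]
#'   \cdot \beta_g^{[s\ labouring]}}
#'
#' and the observed intensity is
#' \eqn{y_{gs} = b_{gs} + c_s\, t_{gs}\, e^{\varepsilon_{gs}}} with additive
#' Gaussian background \eqn{b_{gs}} (truncated at a small positive constant),
#' per-sample scale factor \eqn{c_s} and multiplicative log-normal noise.
#' Negative-control probes have no target and receive background only.
#'
#' Under this model muscle-specific genes appear *down* at labour and
#' leukocyte-specific genes *up* even when no gene changes transcription —
#' the "dilution" confound the downstream pipeline is designed to expose.
#'
#' @param catalog Gene catalog tibble, see [gene_catalog()].
#' @param n_labour,n_nonlabour Group sizes (>= 2).
#' @param f_labour,f_nonlabour Length-2 shape vectors of the Beta
#'   distributions for the leukocyte fraction. Defaults Beta(3, 7) (mean
#'   0.30, wide) for labouring and Beta(2, 38) (mean 0.05, tight) for
#'   non-labouring samples; the wider labouring spread reproduces the greater
#'   between-sample heterogeneity seen at labour.
#' @param noise_sd_log SD of multiplicative *technical* measurement noise on
#'   the natural log scale (>= 0). The default 0.05 (~5% CV) matches the
#'   replicate precision of bead arrays, where each reported intensity
#'   averages many beads; sample-to-sample biological variation is carried
#'   by the leukocyte fraction and the labour effects, not by this term.
#' @param background_mean,background_sd Additive background intensity
#'   parameters; the default mean of 100 puts the median negative-control
#'   intensity at the conventional detection floor.
#' @param scale_spread SD (log scale) of the per-sample scale factor (>= 0).
#' @param n_chips Number of chips samples are randomly assigned to (recorded
#'   as a batch label; no batch effect is simulated by default).
#' @param induced_fraction Fraction of labouring samples flagged as
#'   pharmacologically induced/augmented (a null covariate by default).
#' @param seed Integer seed; the study is bit-identical given the seed.
#' @returns An object of class `synthetic_study`: a list with
#'   * `expression`: raw-intensity tibble (`probe_id`, `gene_symbol`, `class`,
#'     `is_control`, then one column per sample),
#'   * `metadata`: per-sample tibble (`sample_id`, `group`, `parity`, `bmi`,
#'     `maternal_age`, `gestational_weeks`, `induction`, `chip`),
#'   * `truth`: per-gene tibble with `beta`, the expected
#'     compositional intensity ratio (labour/non-labour at the group-mean
#'     leukocyte fractions, transcription held fixed) and the implied
#'     compositional and transcriptional directions,
#'   * `fractions`: per-sample true leukocyte fraction `f`.
#' @examples
#' study <- simulate_study(gene_catalog(50, 50, 10, 5, 100, 20),
#'                         n_labour = 4, n_nonlabour = 4, seed = 7)
#' study$expression[1:3, 1:6]
#' @export
simulate_study <- function(catalog = gene_catalog(),
                           n_labour = 22, n_nonlabour = 26,
                           f_labour = c(3, 7), f_nonlabour = c(2, 38),
                           noise_sd_log = 0.05,
                           background_mean = 100, background_sd = 15,
                           scale_spread = 0.1, n_chips = 4,
                           induced_fraction = 0.5, seed = 1L) {
  validate_catalog(catalog)
  if (n_labour < 2 || n_nonlabour < 2) abort("group sizes must be >= 2")
  check_positive(f_labour, "f_labour"); check_positive(f_nonlabour, "f_nonlabour")
  if (length(f_labour) != 2 || length(f_nonlabour) != 2) {
    abort("f_labour / f_nonlabour must be Beta shape pairs")
  }
  check_positive(noise_sd_log, "noise_sd_log", allow_zero = TRUE)
  check_positive(background_mean, "background_mean")
  check_positive(background_sd, "background_sd", allow_zero = TRUE)
  check_positive(scale_spread, "scale_spread", allow_zero = TRUE)
  check_positive(n_chips, "n_chips")
  if (induced_fraction < 0 || induced_fraction > 1) {
    abort("invalid value for 'induced_fraction': must be in [0, 1]")
  }

  n <- n_labour + n_nonlabour
  G <- nrow(catalog)

  withr::with_seed(seed, {
    sample_id <- sprintf("S%02d", seq_len(n))
    group <- c(rep("labour", n_labour), rep("nonlabour", n_nonlabour))

    f <- numeric(n)
    f[group == "labour"] <- rbeta(n_labour, f_labour[1], f_labour[2])
    f[group == "nonlabour"] <- rbeta(n_nonlabour, f_nonlabour[1], f_nonlabour[2])

    scale_s <- exp(rnorm(n, 0, scale_spread))

    # Null clinical covariates, group-balanced by construction.
    parity <- rpois(n, 1.2)
    bmi <- round(rnorm(n, 26, 4), 1)
    maternal_age <- round(rnorm(n, 30, 5), 1)
    gestational_weeks <- round(rnorm(n, 39.3, 1.2), 1)
    chip <- sample(seq_len(n_chips), n, replace = TRUE)
    induction <- rep("none", n)
    n_induced <- round(induced_fraction * n_labour)
    if (n_induced > 0) {
      picked <- sample(which(group == "labour"), n_induced)
      induction[picked] <- sample(c("prostaglandins", "oxytocin", "both"),
                                  n_induced, replace = TRUE,
                                  prob = c(3, 7, 1) / 11)
    }

    # Expected signal: mixture of the two pure-tissue baselines, labour
    # effect applied to labouring columns only.
    mixture <- outer(catalog$mu_muscle, 1 - f) + outer(catalog$mu_leukocyte, f)
    effect <- outer(catalog$beta, as.numeric(group == "labour"),
                    function(b, lab) b^lab)
    signal <- mixture * effect

    eps <- matrix(rnorm(G * n, 0, noise_sd_log), G, n)
    bg <- pmax(matrix(rnorm(G * n, background_mean, background_sd), G, n), 1e-8)
    y <- bg + sweep(signal * exp(eps), 2, scale_s, `*`)

    colnames(y) <- sample_id
    expression <- dplyr::bind_cols(
      tibble::tibble(probe_id = catalog$gene_id,
                     gene_symbol = catalog$gene_id,
                     class = catalog$class,
                     is_control = catalog$class == "negative_control"),
      tibble::as_tibble(y)
    )

    metadata <- tibble::tibble(
      sample_id = sample_id, group = group, parity = parity, bmi = bmi,
      maternal_age = maternal_age, gestational_weeks = gestational_weeks,
      induction = induction, chip = chip
    )

    fL <- f_labour[1] / sum(f_labour)
    fN <- f_nonlabour[1] / sum(f_nonlabour)
    num <- (1 - fL) * catalog$mu_muscle + fL * catalog$mu_leukocyte
    den <- (1 - fN) * catalog$mu_muscle + fN * catalog$mu_leukocyte
    comp_ratio <- ifelse(den > 0, num / den, NA_real_)
    dir_of <- function(r) {
      ifelse(is.na(r), NA_character_,
             ifelse(abs(r - 1) < 1e-12, "none", ifelse(r > 1, "up", "down")))
    }
    truth <- tibble::tibble(
      gene_id = catalog$gene_id,
      class = catalog$class,
      beta = catalog$beta,
      compositional_ratio = comp_ratio,
      expected_compositional_direction = dir_of(comp_ratio),
      expected_transcriptional_direction = dir_of(catalog$beta),
      expected_apparent_ratio = comp_ratio * catalog$beta
    )

    structure(
      list(expression = expression, metadata = metadata, truth = truth,
           fractions = tibble::tibble(sample_id = sample_id, group = group, f = f),
           params = list(n_labour = n_labour, n_nonlabour = n_nonlabour,
                         f_labour = f_labour, f_nonlabour = f_nonlabour,
                         noise_sd_log = noise_sd_log,
                         background_mean = background_mean,
                         background_sd = background_sd,
                         scale_spread = scale_spread, n_chips = n_chips,
                         induced_fraction = induced_fraction, seed = seed)),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat("<synthetic_study> ", nrow(x$expression), " probes x ",
      p$n_labour + p$n_nonlabour, " samples (", p$n_labour, " labour / ",
      p$n_nonlabour, " nonlabour), seed ", p$seed, "\n", sep = "")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$truth$class)),
                                  table(x$truth$class)), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a multi-study collection with partial probe overlap
#'
#' Emulates a meta-analysis setting in which several studies assay the same
#' tissue contrast on platforms with different probe complements and possibly
#' attenuated effects. Each study retains every negative-control probe and an
#' independent random subset of the remaining genes, chosen so that the
#' k-study intersection covers approximately `shared_gene_fraction` of the
#' catalog. Per-study transcriptional effects are `beta^attenuation[i]`
#' (exponent 0 silences the effect).
#'
#' @param designs List of per-study design lists; each may set any
#'   [simulate_study()] argument except `catalog` and `seed`. Defaults model
#'   one large index study (22/26) and two small published studies (6/6 and
#'   7/6).
#' @param catalog Shared gene catalog.
#' @param shared_gene_fraction Target fraction of catalog genes on all
#'   platforms, in (0, 1].
#' @param attenuation Numeric vector, one exponent per study.
#' @param seed Integer seed.
#' @returns A list of `synthetic_study` objects, one per design, named
#'   `study1`, `study2`, ...
#' @examples
#' sims <- simulate_multistudy(
#'   designs = list(list(n_labour = 4, n_nonlabour = 4),
#'                  list(n_labour = 3, n_nonlabour = 3)),
#'   catalog = gene_catalog(20, 20, 5, 5, 50, 15),
#'   shared_gene_fraction = 0.8, attenuation = c(1, 1), seed = 3)
#' names(sims)
#' @export
simulate_multistudy <- function(designs = list(
                                  list(n_labour = 22, n_nonlabour = 26),
                                  list(n_labour = 6, n_nonlabour = 6),
                                  list(n_labour = 7, n_nonlabour = 6)),
                                catalog = gene_catalog(),
                                shared_gene_fraction = 0.7,
                                attenuation = rep(1, length(designs)),
                                seed = 1L) {
  k <- length(designs)
  if (k < 2) abort("at least 2 studies required")
  if (length(attenuation) != k) {
    abort("'attenuation' must have one entry per study")
  }
  if (shared_gene_fraction <= 0 || shared_gene_fraction > 1) {
    abort("invalid value for 'shared_gene_fraction': must be in (0, 1]")
  }
  validate_catalog(catalog)

  keep_prob <- shared_gene_fraction^(1 / k)
  is_ctrl <- catalog$class == "negative_control"

  withr::with_seed(seed, {
    study_seeds <- sample.int(.Machine$integer.max - 1L, k)
    out <- vector("list", k)
    for (i in seq_len(k)) {
      keep <- is_ctrl | (runif(nrow(catalog)) < keep_prob)
      cat_i <- catalog[keep, , drop = FALSE]
      cat_i$beta <- cat_i$beta^attenuation[i]
      # beta^0 can leave stray labour-class betas at exactly 1; relabelling is
      # not needed because validate_catalog only constrains direction when != 1.
      cat_i$class[cat_i$beta == 1 &
                    cat_i$class %in% c("labour_induced", "labour_repressed")] <-
        "housekeeping"
      args <- c(list(catalog = cat_i, seed = study_seeds[i]), designs[[i]])
      out[[i]] <- do.call(simulate_study, args)
    }
    names(out) <- paste0("study", seq_len(k))
    out
  })
}
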