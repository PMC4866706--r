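#' Build a gene catalog for the bead-array simulator
#'
#' The catalog defines every simulated probe: its class, its expected
#' intensity in pure smooth-muscle and pure leukocyte tissue, and a
#' multiplicative transcriptional labour effect `beta`. Six classes are
#' modelled:
#'
#' * `muscle_specific`: expressed in smooth muscle only (`mu_leukocyte = 0`);
#'   apparent down-regulation at labour arises purely from leukocyte dilution.
#' * `leukocyte_specific`: expressed in leukocytes only (`mu_muscle = 0`);
#'   apparent up-regulation arises purely from infiltration.
#' * `labour_induced` / `labour_repressed`: expressed equally in both cell
#'   types with a true transcriptional effect (`beta > 1` or `beta < 1`).
#' * `housekeeping`: expressed equally in both cell types, `beta = 1`; their
#'   intensity spread (including genes below the detection floor) exercises
#'   floor filtering.
#' * `negative_control`: no target (`mu = 0`, `beta = 1`); these probes
#'   measure background only and define the detection floor.
#'
#' Baseline intensities are drawn from log-normal distributions on the
#' bead-array intensity scale (arbitrary units, background sits near 100).
#'
#' @param n_muscle,n_leukocyte,n_induced,n_repressed,n_housekeeping,n_control
#'   Class sizes. Defaults give a desk-scale catalog of 2050 probes that
#'   preserves the class structure of a genome-wide array.
#' @param beta_induced Multiplicative labour effect for induced genes (> 1).
#' @param beta_repressed Multiplicative labour effect for repressed genes
#'   (in (0, 1)).
#' @param seed Integer seed; the catalog is deterministic given the seed.
#' @returns A tibble with columns `gene_id`, `class`, `mu_muscle`,
#'   `mu_leukocyte`, `beta`.
#' @examples
#' cat6 <- gene_catalog(n_muscle = 2, n_leukocyte = 2, n_induced = 1,
#'                      n_repressed = 1, n_housekeeping = 0, n_control = 0)
#' cat6
#' @export
gene_catalog <- function(n_muscle = 200, n_leukocyte = 200, n_induced = 100,
                         n_repressed = 50, n_housekeeping = 1400,
                         n_control = 100, beta_induced = 2,
                         beta_repressed = 0.5, seed = 1L) {
  sizes <- c(n_muscle, n_leukocyte, n_induced, n_repressed, n_housekeeping,
             n_control)
  if (any(sizes < 0) || sum(sizes) == 0) abort("catalog must be non-empty")
  check_positive(beta_induced, "beta_induced")
  check_positive(beta_repressed, "beta_repressed")
  if (beta_induced <= 1) abort("invalid value for 'beta_induced': must be > 1")
  if (beta_repressed >= 1) abort("invalid value for 'beta_repressed': must be < 1")

  withr::with_seed(seed, {
    mk_ids <- function(prefix, n) if (n) sprintf("%s_%04d", prefix, seq_len(n)) else character(0)
    rows <- list(
      tibble::tibble(
        gene_id = mk_ids("MUSC", n_muscle), class = "muscle_specific",
        mu_muscle = rlnorm(n_muscle, log(800), 0.6), mu_leukocyte = 0, beta = 1
      ),
      tibble::tibble(
        gene_id = mk_ids("LEUK", n_leukocyte), class = "leukocyte_specific",
        mu_muscle = 0, mu_leukocyte = rlnorm(n_leukocyte, log(800), 0.6), beta = 1
      ),
      {
        base <- rlnorm(n_induced, log(600), 0.6)
        tibble::tibble(
          gene_id = mk_ids("INDU", n_induced), class = "labour_induced",
          mu_muscle = base, mu_leukocyte = base, beta = beta_induced
        )
      },
      {
        base <- rlnorm(n_repressed, log(600), 0.6)
        tibble::tibble(
          gene_id = mk_ids("REPR", n_repressed), class = "labour_repressed",
          mu_muscle = base, mu_leukocyte = base, beta = beta_repressed
        )
      },
      {
        base <- rlnorm(n_housekeeping, log(400), 1.1)
        tibble::tibble(
          gene_id = mk_ids("HKG", n_housekeeping), class = "housekeeping",
          mu_muscle = base, mu_leukocyte = base, beta = 1
        )
      },
      tibble::tibble(
        gene_id = mk_ids("NEG", n_control), class = "negative_control",
        mu_muscle = 0, mu_leukocyte = 0, beta = 1
      )
    )
    out <- dplyr::bind_rows(rows)
    validate_catalog(out)
    out
  })
}

#' Check gene-catalog invariants
#'
#' Verifies class labels, non-negative baselines, the exclusive expression of
#' class-specific genes and that `beta != 1` only for labour-effect classes.
#'
#' @param catalog A catalog tibble as returned by [gene_catalog()].
#' @returns The catalog, invisibly; aborts with the offending field on failure.
#' @export
validate_catalog <- function(catalog) {
  need <- c("gene_id", "class", "mu_muscle", "mu_leukocyte", "beta")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) abort(paste0("catalog lacks columns: ", paste(miss, collapse = ", ")))
  classes <- c("muscle_specific", "leukocyte_specific", "labour_induced",
               "labour_repressed", "housekeeping", "negative_control")
  if (!all(catalog$class %in% classes)) abort("invalid value for 'class'")
  if (anyDuplicated(catalog$gene_id)) abort("duplicate gene_id in catalog")
  with(catalog, {
    if (any(!is.finite(mu_muscle)) || any(mu_muscle < 0)) {
      abort("invalid value for 'mu_muscle': must be finite and >= 0")
    }
    if (any(!is.finite(mu_leukocyte)) || any(mu_leukocyte < 0)) {
      abort("invalid value for 'mu_leukocyte': must be finite and >= 0")
    }
    if (any(!is.finite(beta)) || any(beta <= 0)) {
      abort("invalid value for 'beta': must be finite and > 0")
    }
    ms <- class == "muscle_specific"
    if (any(mu_muscle[ms] <= 0) || any(mu_leukocyte[ms] != 0)) {
      abort("muscle_specific genes must have mu_muscle > 0 and mu_leukocyte = 0")
    }
    ls <- class == "leukocyte_specific"
    if (any(mu_leukocyte[ls] <= 0) || any(mu_muscle[ls] != 0)) {
      abort("leukocyte_specific genes must have mu_leukocyte > 0 and mu_muscle = 0")
    }
    nc <- class == "negative_control"
    if (any(mu_muscle[nc] != 0) || any(mu_leukocyte[nc] != 0) || any(beta[nc] != 1)) {
      abort("negative_control genes must have mu = 0 and beta = 1")
    }
    if (any(beta[class == "labour_induced"] <= 1)) {
      abort("labour_induced genes must have beta > 1")
    }
    if (any(beta[class == "labour_repressed"] >= 1)) {
      abort("labour_repressed genes must have beta < 1")
    }
    if (any(beta[!(class %in% c("labour_induced", "labour_repressed"))] != 1)) {
      abort("beta must be 1 outside labour-effect classes")
    }
  })
  invisible(catalog)
}
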